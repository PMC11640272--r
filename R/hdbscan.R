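#' Hierarchical density-based clustering (HDBSCAN)
#'
#' Exact HDBSCAN for the moderate cell numbers this pipeline handles
#' (thousands of points): Euclidean core distances, the mutual-reachability
#' graph, its minimum spanning tree (Prim, O(n^2)), a single-linkage
#' hierarchy condensed at `min_cluster_size`, and excess-of-mass cluster
#' extraction. Points never absorbed by a selected cluster are labelled
#' noise (-1). A single homogeneous blob yields all noise (the root cluster
#' is never selected), matching standard HDBSCAN with
#' `allow_single_cluster = FALSE`.
#'
#' @param coords numeric matrix, points in rows.
#' @param min_cluster_size smallest group treated as a cluster (>= 2).
#' @param min_samples neighbourhood size for core distances; defaults to
#'   `min_cluster_size`. The point itself counts among its neighbours.
#' @return integer vector of cluster labels, `0 .. k-1`, with `-1` = noise.
#' @export
hdbscan_labels <- function(coords, min_cluster_size = 5,
                           min_samples = min_cluster_size) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(min_cluster_size >= 2, min_samples >= 1)
  if (n < min_cluster_size || n < min_samples) {
    warning(sprintf("fewer points (%d) than min_cluster_size: all noise", n),
            call. = FALSE)
    return(rep(-1L, n))
  }

  D <- as.matrix(stats::dist(coords))
  # core distance: k-th smallest distance, self (0) included
  core <- apply(D, 1L, function(r) sort.int(r, partial = min_samples)[min_samples])
  M <- pmax(D, matrix(core, n, n), matrix(core, n, n, byrow = TRUE))

  edges <- mst_prim(M)
  L <- single_linkage(edges, n)
  ct <- condense_tree(L, n, min_cluster_size)
  if (length(ct$parent) == 0 || all(ct$size == 1 & ct$parent == n + 1)) {
    # only the root cluster exists: nothing selectable
    return(rep(-1L, n))
  }
  stab <- tree_stability(ct, n)
  selected <- extract_eom(ct, stab, n)
  label_points(ct, selected, n)
}

# Prim's algorithm on a dense weight matrix; returns (from, to, weight) rows
mst_prim <- function(M) {
  n <- nrow(M)
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  best_w <- M[1L, ]
  best_from <- rep(1L, n)
  best_w[1L] <- Inf
  edges <- matrix(0, n - 1L, 3L)
  for (t in seq_len(n - 1L)) {
    w <- best_w
    w[in_tree] <- Inf
    j <- which.min(w)
    edges[t, ] <- c(best_from[j], j, best_w[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & M[j, ] < best_w
    best_w[upd] <- M[j, upd]
    best_from[upd] <- j
  }
  edges
}

# scipy-style single-linkage matrix from MST edges: columns left, right,
# distance, size; point nodes 1..n, cluster nodes n+1..2n-1 (children always
# have smaller ids than their parent)
single_linkage <- function(edges, n) {
  edges <- edges[order(edges[, 3L]), , drop = FALSE]
  parent <- seq_len(2L * n - 1L)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  size <- c(rep(1, n), rep(0, n - 1L))
  L <- matrix(0, n - 1L, 4L)
  nxt <- n
  for (k in seq_len(n - 1L)) {
    ra <- find(edges[k, 1L])
    rb <- find(edges[k, 2L])
    nxt <- nxt + 1L
    sz <- size[ra] + size[rb]
    L[k, ] <- c(ra, rb, edges[k, 3L], sz)
    parent[ra] <- nxt
    parent[rb] <- nxt
    size[nxt] <- sz
  }
  L
}

# all point ids under a dendrogram node
leaves_under <- function(L, n, node) {
  stack <- node
  pts <- integer(0)
  while (length(stack) > 0) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x <= n) pts <- c(pts, x)
    else stack <- c(stack, L[x - n, 1L], L[x - n, 2L])
  }
  pts
}

cluster_nodes_under <- function(L, n, node) {
  stack <- node
  out <- integer(0)
  while (length(stack) > 0) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x > n) {
      out <- c(out, x)
      stack <- c(stack, L[x - n, 1L], L[x - n, 2L])
    }
  }
  out
}

# Collapse the single-linkage hierarchy into the condensed tree: clusters
# persist until a split into two children of size >= min_cluster_size; points
# of sub-threshold branches fall out at the lambda (= 1/distance) of the
# split that sheds them. Condensed cluster labels start at n+1 (the root).
condense_tree <- function(L, n, min_cluster_size) {
  root <- 2L * n - 1L
  relabel <- integer(root)
  relabel[root] <- n + 1L
  next_label <- n + 2L
  ignore <- logical(root)
  p <- c_ <- integer(0)
  lam <- sz <- numeric(0)
  add <- function(parent, child, lambda, size) {
    p[length(p) + 1L] <<- parent
    c_[length(c_) + 1L] <<- child
    lam[length(lam) + 1L] <<- lambda
    sz[length(sz) + 1L] <<- size
  }
  shed <- function(child, cur, lambda) {
    for (pt in leaves_under(L, n, child)) add(cur, pt, lambda, 1)
    for (cn in cluster_nodes_under(L, n, child)) ignore[cn] <<- TRUE
  }
  for (node in seq(root, n + 1L)) {
    if (ignore[node]) next
    i <- node - n
    left <- L[i, 1L]; right <- L[i, 2L]; d <- L[i, 3L]
    lambda <- if (d > 0) 1 / d else Inf
    sl <- if (left <= n) 1 else L[left - n, 4L]
    sr <- if (right <= n) 1 else L[right - n, 4L]
    cur <- relabel[node]
    if (sl >= min_cluster_size && sr >= min_cluster_size) {
      relabel[left] <- next_label
      add(cur, next_label, lambda, sl)
      next_label <- next_label + 1L
      relabel[right] <- next_label
      add(cur, next_label, lambda, sr)
      next_label <- next_label + 1L
    } else if (sl < min_cluster_size && sr < min_cluster_size) {
      shed(left, cur, lambda)
      shed(right, cur, lambda)
    } else if (sl < min_cluster_size) {
      relabel[right] <- cur
      shed(left, cur, lambda)
    } else {
      relabel[left] <- cur
      shed(right, cur, lambda)
    }
  }
  list(parent = p, child = c_, lambda = lam, size = sz)
}

# stability(C) = sum over members of (lambda_exit - lambda_birth(C)),
# weighted by subtree size for cluster children
tree_stability <- function(ct, n) {
  clusters <- sort(unique(ct$parent))
  births <- stats::setNames(rep(0, length(clusters)), clusters)
  is_cl <- ct$child %in% clusters
  births[as.character(ct$child[is_cl])] <- ct$lambda[is_cl]
  stab <- stats::setNames(rep(0, length(clusters)), clusters)
  for (k in seq_along(ct$parent)) {
    pc <- as.character(ct$parent[k])
    stab[pc] <- stab[pc] + (ct$lambda[k] - births[pc]) * ct$size[k]
  }
  stab
}

# excess-of-mass: keep a cluster iff it is more stable than the sum of its
# selected descendants; the root is never selected
extract_eom <- function(ct, stab, n) {
  root <- n + 1L
  clusters <- sort(as.integer(names(stab)), decreasing = TRUE)
  clusters <- setdiff(clusters, root)
  is_cluster <- stats::setNames(rep(TRUE, length(clusters)), clusters)
  stab_work <- stab
  cl_parent <- ct$parent[ct$size > 1]
  cl_child <- ct$child[ct$size > 1]
  for (node in clusters) {
    kids <- cl_child[cl_parent == node]
    subtree <- sum(stab_work[as.character(kids)])
    if (length(kids) > 0 && subtree > stab_work[as.character(node)]) {
      is_cluster[as.character(node)] <- FALSE
      stab_work[as.character(node)] <- subtree
    } else if (is_cluster[as.character(node)]) {
      # deselect every descendant cluster
      stack <- kids
      while (length(stack) > 0) {
        x <- stack[length(stack)]
        stack <- stack[-length(stack)]
        is_cluster[as.character(x)] <- FALSE
        stack <- c(stack, cl_child[cl_parent == x])
      }
    }
  }
  as.integer(names(is_cluster))[is_cluster]
}

# each point is labelled by its nearest selected ancestor cluster, if any
label_points <- function(ct, selected, n) {
  labels <- rep(-1L, n)
  if (length(selected) == 0) return(labels)
  label_of <- stats::setNames(seq_along(sort(selected)) - 1L, sort(selected))
  parent_of <- stats::setNames(ct$parent, ct$child)
  for (pt in seq_len(n)) {
    cur <- parent_of[as.character(pt)]
    while (!is.na(cur)) {
      if (cur %in% selected) {
        labels[pt] <- label_of[as.character(cur)]
        break
      }
      cur <- parent_of[as.character(cur)]
    }
  }
  labels
}
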