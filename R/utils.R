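#' Round half away from zero
#'
#' Percentages in QC reports are rounded half-up to a fixed number of
#' decimals (so 27.65 prints as 27.7), unlike [base::round()] which rounds
#' half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Strip IMGT allele suffixes from V/J gene calls
#'
#' Clonotype identity is gene-level: `TRBV19*01` and `TRBV19*02` name the
#' same gene segment for pairing with gene-level binding predictors, so the
#' `*NN` allele designation is removed before keys are compared.
#'
#' @param calls character vector of V or J gene names.
#' @return character vector with any `*`-suffix removed.
#' @export
strip_allele <- function(calls) {
  sub("\\*.*$", "", calls)
}

# stop() with a class so callers can distinguish format errors from bugs
format_error <- function(msg, class = "tcrsift_format_error") {
  stop(errorCondition(msg, class = c(class, "tcrsift_error")))
}

validation_error <- function(msg) {
  format_error(msg, class = "tcrsift_validation_error")
}

# parse AIRR-style booleans: T/F/TRUE/FALSE, case-insensitive
parse_airr_bool <- function(x, column, path = "<input>") {
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(up))
  out[up %in% c("T", "TRUE")] <- TRUE
  out[up %in% c("F", "FALSE")] <- FALSE
  bad <- which(is.na(out) & !is.na(up) & nzchar(up))
  if (length(bad) > 0) {
    format_error(sprintf(
      "%s: unparseable boolean in column '%s' at data row %d (value '%s')",
      path, column, bad[1], x[bad[1]]
    ))
  }
  as.logical(out)
}
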