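#' Compare two differential-genus sets
#'
#' Partitions the two sets the way a two-set Venn diagram does:
#' \code{common} (screened by both methods), \code{a_only} (screened by the
#' first but not the second, i.e. "not detected" by the second method) and
#' \code{b_only} ("new" genera rescued by the second method).
#'
#' @param a,b character vectors of genus names (e.g. PA-DMA and IRMRA-DMA
#'   significant sets).
#' @return object of class \code{method_comparison}: list with sorted
#'   \code{common}, \code{a_only}, \code{b_only} and a \code{counts}
#'   vector.
#' @export
compare_sets <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  common <- sort(intersect(a, b))
  a_only <- sort(setdiff(a, b))
  b_only <- sort(setdiff(b, a))
  structure(list(
    common = common, a_only = a_only, b_only = b_only,
    counts = c(a = length(a), b = length(b), common = length(common),
               a_only = length(a_only), b_only = length(b_only))
  ), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Set comparison: |a| = %d, |b| = %d\n", x$counts["a"], x$counts["b"]))
  cat(sprintf("  common: %d | a only: %d | b only: %d\n",
              x$counts["common"], x$counts["a_only"], x$counts["b_only"]))
  invisible(x)
}

#' Fraction of upregulated differential genera
#'
#' \code{100 * n_up / (n_up + n_down)}. The raw percentage is returned;
#' round half-up to two decimals with \code{\link{round_half_up}} for
#' display.
#'
#' @param n_up,n_down non-negative counts of up- and downregulated genera.
#' @return the percentage as a plain number.
#' @export
upregulated_fraction <- function(n_up, n_down) {
  if (n_up < 0 || n_down < 0) stop_validation("counts must be non-negative")
  if (n_up + n_down == 0) {
    stop_degenerate("upregulated fraction undefined: no differential genera")
  }
  100 * n_up / (n_up + n_down)
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as opposed to the banker's rounding of
#' base \code{round}; used for reporting percentages to two decimals.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
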