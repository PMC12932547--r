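#' Compute IRM-normalized relative community quantities (RCQ)
#'
#' RCQ of a genus in a sample is its relative abundance divided by the
#' internal reference microorganism's (IRM) relative abundance, a
#' dimensionless, closure-free ratio. When the IRM denominator is zero a
#' pseudo-count of half the detection limit is substituted (with a detection
#' limit of 0.002 percent the pseudo-count is 0.001 percent). A genus whose
#' own abundance is zero keeps RCQ 0 regardless of the denominator.
#'
#' Two normalization modes are supported. \code{per_sample} (default)
#' divides each sample by that sample's IRM abundance, giving per-sample
#' values suitable for rank tests. \code{group_mean} divides every sample of
#' a group by the group-mean IRM abundance; the pseudo-count then applies
#' when the group mean is zero. RCQ values are deliberately not re-closed:
#' column sums are free, which is the point of the normalization.
#'
#' RCQ is invariant to the input unit: counts, fractions and percent give
#' identical ratios because the per-sample normalizer cancels.
#'
#' @param table an \code{abund_table}; converted to percent internally.
#' @param irm_genus name of the reference genus (must be a table row).
#' @param detection_limit smallest reliably observed relative abundance, in
#'   percent (default 0.002).
#' @param mode \code{"per_sample"} or \code{"group_mean"}.
#' @param design required for \code{group_mean} mode: a
#'   \code{study_design} mapping samples to groups.
#' @return an object of class \code{rcq_table}: list with \code{values}
#'   (taxa x samples ratio matrix), \code{irm_genus},
#'   \code{detection_limit}, \code{pseudo_count},
#'   \code{pseudo_count_applied} (logical per sample), \code{mode}, and
#'   \code{source} (the percent-scale input matrix, kept for the
#'   abundance filter of downstream screens).
#' @export
compute_rcq <- function(table, irm_genus, detection_limit = 0.002,
                        mode = c("per_sample", "group_mean"), design = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "abund_table"))
  if (!is.numeric(detection_limit) || detection_limit <= 0) {
    stop_config("detection_limit must be > 0 (percent)")
  }
  pct <- as_percent(table)$values
  if (!irm_genus %in% rownames(pct)) {
    stop_validation(sprintf("IRM genus '%s' is not in the table", irm_genus))
  }
  pseudo <- 0.5 * detection_limit
  irm_row <- pct[irm_genus, ]
  if (mode == "per_sample") {
    denom <- irm_row
    applied <- denom == 0
    denom[applied] <- pseudo
  } else {
    if (is.null(design)) stop_config("group_mean mode requires a design")
    stopifnot(inherits(design, "study_design"))
    miss <- setdiff(colnames(pct), design$sample)
    if (length(miss) > 0) {
      stop_validation(sprintf("sample '%s' missing from design", miss[1]))
    }
    grp <- design$group[match(colnames(pct), design$sample)]
    gm <- tapply(irm_row, grp, mean)
    denom <- as.numeric(gm[grp])
    applied <- denom == 0
    denom[applied] <- pseudo
    names(denom) <- names(applied) <- colnames(pct)
  }
  vals <- sweep(pct, 2, denom, "/")
  vals[pct == 0] <- 0  # zeros stay zeros whatever the denominator
  structure(list(
    values = vals,
    irm_genus = irm_genus,
    detection_limit = detection_limit,
    pseudo_count = pseudo,
    pseudo_count_applied = applied,
    mode = mode,
    source = pct
  ), class = "rcq_table")
}

#' @export
print.rcq_table <- function(x, ...) {
  cat(sprintf(
    "RCQ table: %d taxa x %d samples | IRM: %s | mode: %s | detection limit: %g%% (pseudo-count %g%%)\n",
    nrow(x$values), ncol(x$values), x$irm_genus, x$mode,
    x$detection_limit, x$pseudo_count
  ))
  n_ps <- sum(x$pseudo_count_applied)
  if (n_ps > 0) cat(sprintf("pseudo-count applied in %d sample(s)\n", n_ps))
  invisible(x)
}

#' Group means of per-sample RCQ column sums
#'
#' For each group, the mean over its samples of the per-sample sum of RCQ
#' values across taxa. Because RCQ is not re-closed these sums are free to
#' differ between groups; they are a diagnostic of how far the
#' normalization moves the community total away from the fixed 100 percent
#' of relative abundance, and are reported for inspection only.
#'
#' @param rcq an \code{rcq_table}.
#' @param design a \code{study_design} covering the RCQ samples.
#' @return named numeric vector of per-group mean sums.
#' @export
rcq_group_sums <- function(rcq, design) {
  stopifnot(inherits(rcq, "rcq_table"), inherits(design, "study_design"))
  miss <- setdiff(colnames(rcq$values), design$sample)
  if (length(miss) > 0) {
    stop_validation(sprintf("sample '%s' missing from design", miss[1]))
  }
  grp <- design$group[match(colnames(rcq$values), design$sample)]
  sums <- colSums(rcq$values)
  res <- tapply(sums, grp, mean)
  stats::setNames(as.numeric(res), names(res))
}
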