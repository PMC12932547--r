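#' Screen configuration for differential genus analysis
#'
#' @param alpha significance level for raw p values (default 0.05).
#' @param abundance_threshold percent relative-abundance filter: a genus is
#'   eligible only if its group-mean relative abundance exceeds this value
#'   in at least one tested group (default 0.005). The filter is always
#'   evaluated on the relative-abundance (percent) scale, also when the
#'   test itself runs on RCQ values, so the two methods screen the same
#'   genus universe.
#' @param mtc multiple-testing mode: \code{"none"} (raw p, the default) or
#'   \code{"BH"} (Benjamini-Hochberg adjusted p compared against alpha).
#' @param exact_cutoff largest group size for which the Wilcoxon test uses
#'   the exact rank-sum distribution (tie-free data only; default 8).
#' @return a list of class \code{screen_config}.
#' @export
screen_config <- function(alpha = 0.05, abundance_threshold = 0.005,
                          mtc = c("none", "BH"), exact_cutoff = 8L) {
  mtc <- match.arg(mtc)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_config("alpha must lie strictly between 0 and 1")
  }
  if (!is.numeric(abundance_threshold) || abundance_threshold < 0) {
    stop_config("abundance_threshold must be >= 0")
  }
  structure(list(alpha = alpha, abundance_threshold = abundance_threshold,
                 mtc = mtc, exact_cutoff = as.integer(exact_cutoff)),
            class = "screen_config")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p value from the rank-sum distribution when both groups are at or
#' below \code{exact_cutoff} and the pooled data are tie-free; otherwise the
#' normal approximation with tie correction and continuity correction. When
#' every pooled value is identical the test is degenerate and returns
#' statistic \code{NA}-free W with p = 1.
#'
#' @param a,b numeric vectors, each with at least 2 finite values.
#' @param exact_cutoff see \code{\link{screen_config}}.
#' @return list with \code{statistic} (W), \code{p.value}, \code{exact}.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_cutoff = 8L) {
  if (length(a) < 2 || length(b) < 2) {
    stop_validation("each group needs at least 2 observations")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop_validation("non-finite values in test input")
  }
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = length(a) * length(b) / 2, p.value = 1, exact = FALSE))
  }
  ties <- anyDuplicated(pooled) > 0
  use_exact <- !ties && length(a) <= exact_cutoff && length(b) <= exact_cutoff
  ht <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = "two.sided", exact = use_exact, correct = TRUE
  ))
  list(statistic = unname(ht$statistic), p.value = ht$p.value, exact = use_exact)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom. The degenerate case of all observations identical returns
#' H = 0, p = 1 rather than dividing by a zero tie correction.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with \code{statistic} (H), \code{p.value}, \code{df}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_validation("need at least 2 groups")
  }
  if (any(lengths(groups) < 2)) stop_validation("each group needs at least 2 observations")
  x <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(x))) stop_validation("non-finite values in test input")
  if (length(unique(x)) == 1L) {
    return(list(statistic = 0, p.value = 1, df = length(groups) - 1L))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(x, g)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter))
}

#' Spearman rank correlation with permutation p value
#'
#' Rho is the Pearson correlation of (midrank-tied) ranks. For n at most 9
#' the two-sided p value is exact, from full enumeration of all n!
#' permutations of one rank vector; for larger n the t approximation on
#' n - 2 degrees of freedom is used.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with \code{rho}, \code{p.value}, \code{method}.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop_validation("need at least 4 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_validation("non-finite values")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop_degenerate("correlation undefined for a constant input vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    # rho for every permutation of ry against fixed rx, vectorized
    ry_mat <- matrix(ry[perms], nrow = nrow(perms))
    cross <- as.numeric(ry_mat %*% rx)
    mx <- mean(rx); my <- mean(ry)
    sx <- sqrt(sum((rx - mx)^2)); sy <- sqrt(sum((ry - my)^2))
    rho_all <- (cross - n * mx * my) / (sx * sy)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    list(rho = rho, p.value = p, method = "exact_permutation")
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    list(rho = rho, p.value = min(1, p), method = "t_approximation")
  }
}

# All permutations of 1..n as an (n!) x n integer matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, 1] <- k
    rest <- seq_len(n)[-k]
    block[, -1] <- matrix(rest[sub], nrow(sub))
    out[[k]] <- block
  }
  do.call(rbind, out)
}

#' Run a differential microorganism analysis (DMA) screen
#'
#' Applies the rank-test screen to every genus: Wilcoxon rank-sum for two
#' groups, Kruskal-Wallis for three or more. The abundance filter is always
#' evaluated on the relative-abundance scale (group mean above the
#' threshold in at least one group); the test and the direction call run on
#' the supplied scale — relative abundance for \code{PA-DMA}, RCQ for
#' \code{IRMRA-DMA}. Direction is called against a declared reference
#' group: \code{up} when the reference mean exceeds every comparator mean,
#' \code{down} when it is below every comparator mean, \code{none}
#' otherwise (for two groups this reduces to the sign of the mean
#' difference, with exact ties mapped to \code{none}).
#'
#' @param x an \code{abund_table} (for \code{PA-DMA}) or an
#'   \code{rcq_table} (for \code{IRMRA-DMA}).
#' @param design a \code{study_design}.
#' @param groups character vector of group labels to compare (>= 2).
#' @param config a \code{\link{screen_config}}.
#' @param method \code{"PA-DMA"} or \code{"IRMRA-DMA"}. Defaults to the
#'   method matching the class of \code{x}.
#' @param reference reference group for the direction call (default: first
#'   element of \code{groups}).
#' @param pa_table optional \code{abund_table} supplying the percent scale
#'   for the abundance filter; defaults to \code{x} itself for
#'   \code{PA-DMA} and to the source matrix stored in the \code{rcq_table}
#'   for \code{IRMRA-DMA}.
#' @return a data frame of class \code{dma_result}, one row per genus,
#'   sorted by p value then genus name, with per-group means on the test
#'   scale, \code{statistic}, \code{p}, optional \code{p_adj},
#'   \code{direction}, \code{passed_abundance_filter}, \code{significant},
#'   and volcano-ready \code{log2fc} (two-group comparisons) and
#'   \code{neglog10p} columns.
#' @export
run_dma <- function(x, design, groups, config = screen_config(),
                    method = NULL, reference = groups[1], pa_table = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(config, "screen_config"))
  if (length(groups) < 2) stop_config("need at least 2 groups to compare")
  if (anyDuplicated(groups)) stop_config("duplicated group labels")
  if (!reference %in% groups) stop_config("reference must be one of the compared groups")

  if (inherits(x, "rcq_table")) {
    if (is.null(method)) method <- "IRMRA-DMA"
    test_mat <- x$values
    filter_mat <- if (is.null(pa_table)) x$source else as_percent(pa_table)$values
  } else if (inherits(x, "abund_table")) {
    if (is.null(method)) method <- "PA-DMA"
    test_mat <- as_percent(x)$values
    filter_mat <- if (is.null(pa_table)) test_mat else as_percent(pa_table)$values
  } else {
    stop_validation("x must be an abund_table or an rcq_table")
  }
  method <- match.arg(method, c("PA-DMA", "IRMRA-DMA"))
  if (!identical(sort(rownames(test_mat)), sort(rownames(filter_mat)))) {
    stop_validation("test table and abundance-filter table cover different genera")
  }
  filter_mat <- filter_mat[rownames(test_mat), , drop = FALSE]

  gsamp <- lapply(groups, function(g) group_samples(design, g))
  names(gsamp) <- groups
  if (anyDuplicated(unlist(gsamp))) stop_validation("groups share samples; they must be disjoint")
  for (g in groups) {
    miss <- setdiff(gsamp[[g]], colnames(test_mat))
    if (length(miss) > 0) stop_validation(sprintf("sample '%s' missing from table", miss[1]))
    if (length(gsamp[[g]]) < 2) stop_validation(sprintf("group '%s' has < 2 samples", g))
  }

  genera <- rownames(test_mat)
  k <- length(groups)
  comparison <- if (k == 2) paste(groups, collapse = " vs ") else
    sprintf("%d-group (%s)", k, paste(groups, collapse = ", "))

  means <- sapply(groups, function(g) rowMeans(test_mat[, gsamp[[g]], drop = FALSE]))
  means <- matrix(means, nrow = length(genera), dimnames = list(genera, groups))
  fmeans <- sapply(groups, function(g) rowMeans(filter_mat[, gsamp[[g]], drop = FALSE]))
  fmeans <- matrix(fmeans, nrow = length(genera), dimnames = list(genera, groups))
  passed <- apply(fmeans, 1, max) > config$abundance_threshold

  stat <- p <- numeric(length(genera))
  for (i in seq_along(genera)) {
    vals <- lapply(groups, function(g) test_mat[i, gsamp[[g]]])
    if (k == 2) {
      ht <- wilcoxon_rank_sum(vals[[1]], vals[[2]], config$exact_cutoff)
    } else {
      ht <- kruskal_wallis(vals)
    }
    stat[i] <- ht$statistic
    p[i] <- ht$p.value
  }

  ref_mean <- means[, reference]
  others <- means[, setdiff(groups, reference), drop = FALSE]
  direction <- rep("none", length(genera))
  up <- vapply(seq_along(genera), function(i) all(ref_mean[i] > others[i, ]), TRUE)
  down <- vapply(seq_along(genera), function(i) all(ref_mean[i] < others[i, ]), TRUE)
  direction[up] <- "up"
  direction[down] <- "down"

  p_eff <- if (config$mtc == "BH") stats::p.adjust(p, method = "BH") else p
  significant <- (p_eff < config$alpha) & passed

  out <- data.frame(genus = genera, method = method, comparison = comparison,
                    stringsAsFactors = FALSE)
  for (g in groups) out[[paste0("mean_", g)]] <- unname(means[, g])
  out$statistic <- stat
  out$p <- p
  if (config$mtc == "BH") out$p_adj <- p_eff
  out$direction <- direction
  out$passed_abundance_filter <- unname(passed)
  out$significant <- unname(significant)
  if (k == 2) {
    other <- setdiff(groups, reference)
    out$log2fc <- log2(ref_mean / means[, other])
  } else {
    out$log2fc <- NA_real_
  }
  out$neglog10p <- -log10(p)
  out <- out[order(out$p, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "groups") <- groups
  attr(out, "config") <- config
  class(out) <- c("dma_result", "data.frame")
  out
}

#' Wild-enriched (reference-enriched) genus set
#'
#' From a k-group screen, the genera that are significant and whose
#' target-group center strictly exceeds the center of every comparison
#' group, on the scale the test was run on. Centers are group means by
#' default; medians are available, in which case the values table the
#' screen was run on must be supplied.
#'
#' @param results a \code{dma_result} from a k-group \code{\link{run_dma}}.
#' @param target target (e.g., wild) group label.
#' @param comparison_groups labels the target must exceed.
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @param x,design required when \code{center = "median"}: the values
#'   object and design the screen used.
#' @return character vector of genus names.
#' @export
wild_enriched_set <- function(results, target, comparison_groups,
                              center = c("mean", "median"),
                              x = NULL, design = NULL) {
  center <- match.arg(center)
  stopifnot(inherits(results, "dma_result"))
  if (target %in% comparison_groups) {
    stop_config("target group must not be among the comparison groups")
  }
  need <- paste0("mean_", c(target, comparison_groups))
  if (!all(need %in% names(results))) {
    stop_validation("results do not cover target and comparison groups")
  }
  if (center == "mean") {
    cen <- as.matrix(results[need])
  } else {
    if (is.null(x) || is.null(design)) {
      stop_config("median centers need the values object and design")
    }
    mat <- if (inherits(x, "rcq_table")) x$values else as_percent(x)$values
    cen <- sapply(c(target, comparison_groups), function(g) {
      apply(mat[results$genus, group_samples(design, g), drop = FALSE], 1, stats::median)
    })
  }
  higher <- apply(cen, 1, function(v) all(v[1] > v[-1]))
  sort(results$genus[results$significant & higher])
}
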