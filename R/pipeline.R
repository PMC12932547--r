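#' Fit the internal-reference differential-abundance workflow
#'
#' The central fitting function of the package. Given a genus table and a
#' sample design it (1) screens host-specific internal reference
#' microorganism (IRM) candidates when asked to choose the reference
#' automatically, (2) normalizes every genus to the IRM as relative
#' community quantities (RCQ), (3) screens differential genera on both the
#' relative-abundance scale (PA-DMA) and the RCQ scale (IRMRA-DMA) —
#' pairwise Wilcoxon screens of the reference group against every other
#' group, plus a Kruskal-Wallis screen across all groups when three or
#' more are compared — and (4) compares the two methods' wild-enriched
#' genus sets.
#'
#' @param table an \code{abund_table} (any unit; percent is used
#'   internally).
#' @param design a \code{study_design} covering the table's samples.
#' @param groups group labels to analyze; default: all target-host groups
#'   in design order.
#' @param reference reference (e.g. wild) group for direction calls and
#'   pairwise screens; default: first of \code{groups}.
#' @param irm \code{"auto"} to adopt the top-ranked candidate from
#'   \code{\link{screen_irm}} (requires companion groups in the design),
#'   or a genus name.
#' @param detection_limit percent detection limit anchoring the RCQ
#'   pseudo-count (default 0.002; pseudo-count is half of it).
#' @param irm_threshold minimum group-mean percent abundance an IRM
#'   candidate must reach in every host group (default 0.005).
#' @param alpha significance level (default 0.05).
#' @param abundance_filter percent relative-abundance filter for the
#'   differential screens (default 0.005).
#' @param mode RCQ normalization mode, \code{"per_sample"} (default) or
#'   \code{"group_mean"}.
#' @param mtc multiple-testing mode, \code{"none"} (default) or
#'   \code{"BH"}.
#' @param presence_rule presence rule for the IRM screen (see
#'   \code{\link{presence_profile}}).
#' @return an object of class \code{irmdma} with components
#'   \code{irm} (chosen genus), \code{irm_screen} (ranked candidate table
#'   or \code{NULL}), \code{rcq} (the \code{rcq_table}),
#'   \code{pa_pairwise} / \code{irm_pairwise} (named lists of
#'   \code{dma_result}), \code{pa_kw} / \code{irm_kw} (k-group screens,
#'   \code{NULL} for two groups), \code{wild_pa} / \code{wild_irm}
#'   (wild-enriched genus sets), \code{comparison}
#'   (a \code{method_comparison}), \code{rcq_sums} (diagnostic per-group
#'   mean RCQ column sums), and the run parameters.
#' @seealso \code{\link{run_pipeline}} for the file-based front end.
#' @export
irmdma <- function(table, design, groups = NULL, reference = NULL,
                   irm = "auto", detection_limit = 0.002,
                   irm_threshold = 0.005, alpha = 0.05,
                   abundance_filter = 0.005,
                   mode = c("per_sample", "group_mean"),
                   mtc = c("none", "BH"), presence_rule = "any") {
  mode <- match.arg(mode)
  mtc <- match.arg(mtc)
  stopifnot(inherits(table, "abund_table"), inherits(design, "study_design"))
  if (is.null(groups)) {
    groups <- unique(design$group[design$host_role == "target"])
  }
  if (length(groups) < 2) stop_config("need at least 2 groups to analyze")
  if (is.null(reference)) reference <- groups[1]
  check_table_design(table, design, groups)

  irm_screen_tab <- NULL
  if (identical(irm, "auto")) {
    if (!any(design$host_role == "companion")) {
      stop_irmdma(
        "automatic IRM selection requires companion groups in the design",
        "irmdma_no_candidate"
      )
    }
    irm_screen_tab <- screen_irm(table, design, threshold = irm_threshold,
                                 presence_rule = presence_rule)
    passers <- irm_screen_tab$genus[irm_screen_tab$passes_threshold]
    if (length(passers) == 0) {
      stop_irmdma("IRM screen found no candidate passing the abundance threshold",
                  "irmdma_no_candidate")
    }
    irm <- passers[1]
  } else {
    if (!irm %in% taxa(table)) {
      stop_validation(sprintf("IRM genus '%s' is not in the table", irm))
    }
    if (any(design$host_role == "companion")) {
      irm_screen_tab <- tryCatch(
        screen_irm(table, design, threshold = irm_threshold,
                   presence_rule = presence_rule),
        irmdma_error = function(e) NULL
      )
    }
  }

  pct <- as_percent(table)
  irm_means <- vapply(groups, function(g) {
    mean(pct$values[irm, group_samples(design, g)])
  }, 0)
  low <- irm_means < 2 * detection_limit
  if (any(low)) {
    warn_irmdma(sprintf(
      "IRM '%s' mean abundance in group(s) %s is within 2x of the detection limit; normalization may be unstable",
      irm, paste(groups[low], collapse = ", ")
    ), class = "irmdma_low_irm_warning")
  }

  config <- screen_config(alpha = alpha, abundance_threshold = abundance_filter,
                          mtc = mtc)
  rcq <- compute_rcq(pct, irm, detection_limit, mode = mode, design = design)

  others <- setdiff(groups, reference)
  pa_pairwise <- irm_pairwise <- stats::setNames(vector("list", length(others)), others)
  for (g in others) {
    pa_pairwise[[g]] <- run_dma(pct, design, c(reference, g), config,
                                method = "PA-DMA", reference = reference)
    irm_pairwise[[g]] <- run_dma(rcq, design, c(reference, g), config,
                                 method = "IRMRA-DMA", reference = reference)
  }

  pa_kw <- irm_kw <- NULL
  if (length(groups) >= 3) {
    pa_kw <- run_dma(pct, design, groups, config, method = "PA-DMA",
                     reference = reference)
    irm_kw <- run_dma(rcq, design, groups, config, method = "IRMRA-DMA",
                      reference = reference)
    wild_pa <- wild_enriched_set(pa_kw, reference, others)
    wild_irm <- wild_enriched_set(irm_kw, reference, others)
  } else {
    wild_pa <- sort(pa_pairwise[[others]]$genus[
      pa_pairwise[[others]]$significant & pa_pairwise[[others]]$direction == "up"])
    wild_irm <- sort(irm_pairwise[[others]]$genus[
      irm_pairwise[[others]]$significant & irm_pairwise[[others]]$direction == "up"])
  }
  comparison <- compare_sets(wild_pa, wild_irm)
  design_sub <- design[design$group %in% groups, , drop = FALSE]
  rcq_sub <- rcq
  rcq_sub$values <- rcq$values[, design_sub$sample, drop = FALSE]
  rcq_sums <- rcq_group_sums(rcq_sub, design_sub)

  structure(list(
    call = match.call(),
    groups = groups, reference = reference,
    irm = irm, irm_screen = irm_screen_tab, irm_group_means = irm_means,
    detection_limit = detection_limit, irm_threshold = irm_threshold,
    mode = mode, config = config,
    rcq = rcq, rcq_sums = rcq_sums,
    pa_pairwise = pa_pairwise, irm_pairwise = irm_pairwise,
    pa_kw = pa_kw, irm_kw = irm_kw,
    wild_pa = wild_pa, wild_irm = wild_irm,
    comparison = comparison
  ), class = "irmdma")
}

#' @export
print.irmdma <- function(x, ...) {
  cat("Internal-reference differential-abundance analysis (IRMRA-DMA)\n")
  cat(sprintf("  groups: %s (reference: %s)\n",
              paste(x$groups, collapse = ", "), x$reference))
  cat(sprintf("  IRM: %s | detection limit %g%% (pseudo-count %g%%) | mode %s\n",
              x$irm, x$detection_limit, x$rcq$pseudo_count, x$mode))
  cat(sprintf("  wild-enriched genera: PA-DMA %d | IRMRA-DMA %d | common %d\n",
              length(x$wild_pa), length(x$wild_irm),
              length(x$comparison$common)))
  invisible(x)
}

#' @export
summary.irmdma <- function(object, ...) {
  pair_summary <- function(lst, method) {
    do.call(rbind, lapply(names(lst), function(g) {
      r <- lst[[g]]
      up <- sum(r$significant & r$direction == "up")
      down <- sum(r$significant & r$direction == "down")
      data.frame(method = method, comparison = r$comparison[1],
                 n_up = up, n_down = down,
                 up_fraction = if (up + down > 0)
                   round_half_up(upregulated_fraction(up, down), 2) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list(
    irm = object$irm,
    irm_group_means = object$irm_group_means,
    rcq_sums = object$rcq_sums,
    pairwise = rbind(pair_summary(object$pa_pairwise, "PA-DMA"),
                     pair_summary(object$irm_pairwise, "IRMRA-DMA")),
    wild_pa = object$wild_pa,
    wild_irm = object$wild_irm,
    comparison = object$comparison
  )
  class(out) <- "summary.irmdma"
  out
}

#' @export
print.summary.irmdma <- function(x, ...) {
  cat(sprintf("IRM: %s | group means (%%): %s\n", x$irm,
              paste(sprintf("%s=%.4g", names(x$irm_group_means),
                            x$irm_group_means), collapse = ", ")))
  cat(sprintf("Mean RCQ column sums: %s\n",
              paste(sprintf("%s=%.2f", names(x$rcq_sums), x$rcq_sums),
                    collapse = ", ")))
  cat("\nPairwise screens (significant genera):\n")
  print(x$pairwise, row.names = FALSE)
  cat(sprintf("\nWild-enriched sets: PA-DMA %d, IRMRA-DMA %d (common %d, PA-only %d, IRM-only %d)\n",
              x$comparison$counts["a"], x$comparison$counts["b"],
              x$comparison$counts["common"], x$comparison$counts["a_only"],
              x$comparison$counts["b_only"]))
  invisible(x)
}

#' Volcano plot of a pairwise screen
#'
#' Plots log2 fold change of group means against -log10 p for one pairwise
#' comparison of a fitted \code{\link{irmdma}} object. Genera passing the
#' abundance filter and the significance level are highlighted.
#'
#' @param x an \code{irmdma} object.
#' @param method \code{"IRMRA-DMA"} (default) or \code{"PA-DMA"}.
#' @param pair which comparison group (default: the first).
#' @param ... passed to \code{plot}.
#' @return the plotted \code{dma_result}, invisibly.
#' @export
plot.irmdma <- function(x, method = c("IRMRA-DMA", "PA-DMA"), pair = NULL, ...) {
  method <- match.arg(method)
  lst <- if (method == "IRMRA-DMA") x$irm_pairwise else x$pa_pairwise
  if (is.null(pair)) pair <- names(lst)[1]
  r <- lst[[pair]]
  fc <- r$log2fc
  fin <- is.finite(fc)
  col <- ifelse(!r$significant, "grey60",
                ifelse(r$direction == "up", "firebrick", "steelblue"))
  graphics::plot(fc[fin], r$neglog10p[fin], col = col[fin], pch = 19,
                 xlab = sprintf("log2 fold change (%s / %s)", x$reference, pair),
                 ylab = "-log10 p", main = sprintf("%s: %s", method, r$comparison[1]),
                 ...)
  graphics::abline(h = -log10(x$config$alpha), lty = 2, col = "grey40")
  graphics::abline(v = 0, lty = 3, col = "grey40")
  invisible(r)
}

#' Run the full pipeline from files to files
#'
#' File-based front end over \code{\link{irmdma}}: reads the genus table
#' and design, fits the workflow, and writes a deterministic result bundle
#' (\code{irm_candidates.tsv}, \code{rcq.tsv}, \code{diff_pa.tsv},
#' \code{diff_irm.tsv}, \code{comparison.json}, \code{run_manifest.json})
#' into the output directory. The manifest records every parameter, the
#' chosen IRM, the normalization mode and the pseudo-count events, so no
#' result file is emitted without its provenance.
#'
#' @param config a named list, or the path of a YAML file, with fields
#'   \code{table}, \code{design}, \code{out_dir}, and optionally
#'   \code{unit} (default \code{"percent"}), \code{irm} (default
#'   \code{"auto"}), \code{groups}, \code{reference},
#'   \code{detection_limit}, \code{irm_threshold}, \code{alpha},
#'   \code{abundance_filter}, \code{mode}, \code{mtc}, \code{seed}.
#' @return the fitted \code{irmdma} object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or a YAML file path")
  for (f in c("table", "design", "out_dir")) {
    if (is.null(config[[f]])) stop_config(sprintf("config is missing '%s'", f))
  }
  get_or <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  table <- read_abundance_table(config$table, unit = get_or("unit", "percent"))
  design <- read_design(config$design)
  fit <- irmdma(
    table, design,
    groups = get_or("groups", NULL), reference = get_or("reference", NULL),
    irm = get_or("irm", "auto"),
    detection_limit = get_or("detection_limit", 0.002),
    irm_threshold = get_or("irm_threshold", 0.005),
    alpha = get_or("alpha", 0.05),
    abundance_filter = get_or("abundance_filter", 0.005),
    mode = get_or("mode", "per_sample"),
    mtc = get_or("mtc", "none")
  )
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$irm_screen)) {
    write_tsv(fit$irm_screen, file.path(out, "irm_candidates.tsv"))
  }
  rcq_df <- data.frame(taxon = rownames(fit$rcq$values),
                       fit$rcq$values, check.names = FALSE,
                       stringsAsFactors = FALSE)
  write_tsv(rcq_df, file.path(out, "rcq.tsv"))
  pa_out <- if (!is.null(fit$pa_kw)) fit$pa_kw else fit$pa_pairwise[[1]]
  irm_out <- if (!is.null(fit$irm_kw)) fit$irm_kw else fit$irm_pairwise[[1]]
  write_tsv(pa_out, file.path(out, "diff_pa.tsv"))
  write_tsv(irm_out, file.path(out, "diff_irm.tsv"))
  jsonlite::write_json(
    list(common = fit$comparison$common, a_only = fit$comparison$a_only,
         b_only = fit$comparison$b_only,
         counts = as.list(fit$comparison$counts)),
    file.path(out, "comparison.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  manifest <- list(
    package = "irmdma",
    version = as.character(utils::packageVersion("irmdma")),
    table = config$table, design = config$design,
    unit = get_or("unit", "percent"),
    groups = fit$groups, reference = fit$reference,
    irm_requested = get_or("irm", "auto"), irm = fit$irm,
    detection_limit = fit$detection_limit,
    pseudo_count = fit$rcq$pseudo_count,
    pseudo_count_samples = names(which(fit$rcq$pseudo_count_applied)),
    irm_threshold = fit$irm_threshold,
    alpha = fit$config$alpha,
    abundance_filter = fit$config$abundance_threshold,
    mode = fit$mode, mtc = fit$config$mtc,
    seed = get_or("seed", NULL),
    wild_enriched = list(pa = fit$wild_pa, irm = fit$wild_irm)
  )
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(fit)
}
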