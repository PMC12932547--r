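#' Scenario configuration for the community simulator
#'
#' Describes a synthetic rhizosphere community on the absolute-abundance
#' scale, from which relative abundances arise only through compositional
#' closure and multinomial sequencing. Per-taxon baselines are log-normal
#' across taxa; every sample multiplies its group's expected abundance by
#' independent log-normal noise. Group-level structure is injected as fold
#' changes on the absolute scale:
#' \itemize{
#'   \item \code{differential}: planted signal taxa (fold change in a group);
#'   \item \code{bloomer}: a taxon whose surge shifts the group's total
#'     microbial load, distorting every other taxon's relative abundance
#'     without touching their absolute abundance;
#'   \item \code{irm_taxon}: a host-specific reference taxon held at a
#'     stable absolute level in every target-host group and absent (zero)
#'     from companion groups.
#' }
#'
#' @param n_taxa number of genera.
#' @param layout data frame with columns \code{group}, \code{site},
#'   \code{host_role} (\code{target}/\code{companion}), \code{n}
#'   (samples per group).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   across-taxon baseline abundances (defaults 0 and 1).
#' @param noise_sdlog per-sample log-normal noise sd (default 0.3).
#' @param differential \code{NULL} or data frame with columns
#'   \code{taxon} (index), \code{group}, \code{fold} (> 0).
#' @param bloomer \code{NULL} or list with \code{taxon} (index),
#'   \code{groups} (labels), \code{fold} (> 0), \code{base_frac}
#'   (baseline as a fraction of the remaining community baseline total,
#'   default 0.05).
#' @param irm_taxon \code{NULL} or a taxon index.
#' @param irm_base_frac IRM baseline as a fraction of the remaining
#'   community baseline total (default 0.005, about half a percent of the
#'   community).
#' @param depth sequencing depth per sample (default 5e4).
#' @param label scenario name carried into outputs.
#' @return validated list of class \code{scenario_config}.
#' @export
scenario_config <- function(n_taxa, layout,
                            baseline_meanlog = 0, baseline_sdlog = 1,
                            noise_sdlog = 0.3,
                            differential = NULL, bloomer = NULL,
                            irm_taxon = NULL, irm_base_frac = 0.005,
                            depth = 5e4, label = "custom") {
  if (n_taxa < 2) stop_config("need at least 2 taxa")
  if (!is.data.frame(layout) ||
      !all(c("group", "site", "host_role", "n") %in% names(layout))) {
    stop_config("layout needs columns group, site, host_role, n")
  }
  if (any(layout$n < 1)) stop_config("every group needs at least 1 sample")
  if (anyDuplicated(layout$group)) stop_config("duplicate group in layout")
  if (!all(layout$host_role %in% c("target", "companion"))) {
    stop_config("host_role must be target or companion")
  }
  if (depth <= 0) stop_config("sequencing depth must be positive")
  if (!is.null(differential)) {
    stopifnot(all(c("taxon", "group", "fold") %in% names(differential)))
    if (any(differential$fold <= 0)) stop_config("fold changes must be > 0")
    if (any(!differential$group %in% layout$group)) stop_config("differential group not in layout")
    if (any(differential$taxon < 1 | differential$taxon > n_taxa)) {
      stop_config("differential taxon index out of range")
    }
  }
  if (!is.null(bloomer)) {
    stopifnot(all(c("taxon", "groups", "fold") %in% names(bloomer)))
    if (bloomer$fold <= 0) stop_config("bloomer fold must be > 0")
    if (is.null(bloomer$base_frac)) bloomer$base_frac <- 0.05
    if (any(!bloomer$groups %in% layout$group)) stop_config("bloomer group not in layout")
  }
  if (!is.null(irm_taxon) && (irm_taxon < 1 || irm_taxon > n_taxa)) {
    stop_config("irm_taxon index out of range")
  }
  structure(list(
    n_taxa = as.integer(n_taxa), layout = layout,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    noise_sdlog = noise_sdlog, differential = differential,
    bloomer = bloomer, irm_taxon = irm_taxon, irm_base_frac = irm_base_frac,
    depth = depth, label = label
  ), class = "scenario_config")
}

# Per-taxon x per-group expected fold factors implied by a config; the
# ground-truth flags are derived from this matrix alone, so truth is a pure
# function of the configuration.
scenario_fold_matrix <- function(config) {
  groups <- config$layout$group
  fold <- matrix(1, config$n_taxa, length(groups),
                 dimnames = list(NULL, groups))
  if (!is.null(config$differential)) {
    for (i in seq_len(nrow(config$differential))) {
      d <- config$differential[i, ]
      fold[d$taxon, d$group] <- fold[d$taxon, d$group] * d$fold
    }
  }
  if (!is.null(config$bloomer)) {
    fold[config$bloomer$taxon, config$bloomer$groups] <-
      fold[config$bloomer$taxon, config$bloomer$groups] * config$bloomer$fold
  }
  if (!is.null(config$irm_taxon)) {
    companion <- groups[config$layout$host_role == "companion"]
    fold[config$irm_taxon, companion] <- 0
  }
  fold
}

#' Simulate a synthetic community
#'
#' Draws per-sample absolute abundances, converts them to proportions
#' (compositional closure), samples sequencing counts multinomially at the
#' configured depth, and derives the percent table from the counts. Output
#' is fully reproducible from \code{(config, seed)}.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param seed integer seed for all randomness in the draw.
#' @return object of class \code{synthetic_community}: list with
#'   \code{absolute} (taxa x samples matrix, arbitrary units),
#'   \code{load} (per-sample totals), \code{counts}, \code{percent}
#'   (an \code{abund_table}), \code{design} (a \code{study_design}),
#'   \code{fold} (expected per-group fold matrix), \code{config},
#'   \code{seed}.
#' @export
simulate_community <- function(config, seed) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(as.integer(seed))
  n <- config$n_taxa
  taxa_names <- sprintf("g%03d", seq_len(n))
  if (!is.null(config$irm_taxon)) taxa_names[config$irm_taxon] <- "IRM_ref"
  if (!is.null(config$bloomer)) taxa_names[config$bloomer$taxon] <- "bloomer"

  base <- exp(stats::rnorm(n, config$baseline_meanlog, config$baseline_sdlog))
  special <- c(config$irm_taxon, config$bloomer$taxon)
  rest_total <- sum(base[setdiff(seq_len(n), special)])
  if (!is.null(config$irm_taxon)) {
    base[config$irm_taxon] <- config$irm_base_frac * rest_total
  }
  if (!is.null(config$bloomer)) {
    base[config$bloomer$taxon] <- config$bloomer$base_frac * rest_total
  }

  layout <- config$layout
  fold <- scenario_fold_matrix(config)
  sample_names <- unlist(lapply(seq_len(nrow(layout)), function(i) {
    paste0(layout$group[i], "_", seq_len(layout$n[i]))
  }))
  grp_of <- rep(layout$group, layout$n)
  absolute <- matrix(0, n, length(sample_names),
                     dimnames = list(taxa_names, sample_names))
  for (j in seq_along(sample_names)) {
    noise <- exp(stats::rnorm(n, 0, config$noise_sdlog))
    absolute[, j] <- base * fold[, grp_of[j]] * noise
  }
  load <- colSums(absolute)
  prop <- sweep(absolute, 2, load, "/")
  counts <- matrix(0L, n, length(sample_names),
                   dimnames = dimnames(absolute))
  for (j in seq_along(sample_names)) {
    counts[, j] <- stats::rmultinom(1, size = config$depth, prob = prop[, j])
  }
  percent <- abundance_table(counts / config$depth * 100, unit = "percent")
  design <- study_design(data.frame(
    sample = sample_names,
    site = rep(layout$site, layout$n),
    host_role = rep(layout$host_role, layout$n),
    group = grp_of,
    replicate = unlist(lapply(layout$n, seq_len)),
    stringsAsFactors = FALSE
  ))
  structure(list(
    absolute = absolute, load = load, counts = counts, percent = percent,
    design = design, fold = fold, config = config, seed = as.integer(seed)
  ), class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "Synthetic community '%s': %d taxa x %d samples, depth %g, seed %d\n",
    x$config$label, nrow(x$counts), ncol(x$counts), x$config$depth, x$seed
  ))
  invisible(x)
}

#' Ground-truth differential flags for a group contrast
#'
#' A taxon is truly differential between two groups when its expected
#' absolute abundance differs, i.e. its configured fold factors differ
#' (planted signal, bloomer surge, or IRM presence/absence).
#'
#' @param community a \code{synthetic_community}.
#' @param group_a,group_b group labels.
#' @return named logical vector over taxa.
#' @export
truth_differential <- function(community, group_a, group_b) {
  stopifnot(inherits(community, "synthetic_community"))
  f <- community$fold
  for (g in c(group_a, group_b)) {
    if (!g %in% colnames(f)) stop_validation(sprintf("unknown group '%s'", g))
  }
  stats::setNames(f[, group_a] != f[, group_b], rownames(community$counts))
}

#' Built-in scenario: load-shift null
#'
#' Three target-host groups of six samples, 200 genera, no planted signal.
#' A single bloomer surges twentyfold in the two cultivated-analog groups,
#' roughly doubling their total microbial load; every other taxon is
#' unchanged on the absolute scale yet systematically compressed in
#' relative abundance. A stable reference taxon (about 0.5 percent of the
#' community) anchors the ratio normalization. Any genus flagged
#' significant between the wild-analog and a cultivated-analog group —
#' other than the bloomer itself — is a compositional false positive.
#'
#' @param n_per_group samples per group (default 6).
#' @return a \code{\link{scenario_config}}.
#' @export
scenario_null_load_shift <- function(n_per_group = 6) {
  layout <- data.frame(
    group = c("WFt", "HFt", "PFt"),
    site = c("wild", "cult1", "cult2"),
    host_role = "target",
    n = n_per_group,
    stringsAsFactors = FALSE
  )
  scenario_config(
    n_taxa = 200, layout = layout,
    baseline_meanlog = 0, baseline_sdlog = 1, noise_sdlog = 0.3,
    differential = NULL,
    bloomer = list(taxon = 2L, groups = c("HFt", "PFt"), fold = 20,
                   base_frac = 0.05),
    irm_taxon = 1L, irm_base_frac = 0.005,
    depth = 5e4, label = "null_load_shift"
  )
}

#' Built-in scenario: planted signal
#'
#' Three sites, each with a target-host group and a companion group of six
#' samples. A host-specific reference taxon is present in every target
#' group and absent from every companion group, and ten planted taxa are
#' fourfold enriched (absolute scale) in the wild-analog group, forming a
#' known wild-enriched truth set. No bloomer, so both screening methods
#' operate free of load-shift bias and recovery can be judged cleanly.
#' The default community holds 100 genera: with the raw-p screen at
#' alpha = 0.05 and the reference-highest direction rule, the expected
#' contamination of the wild-enriched set by null taxa is about
#' alpha/3 x n_null, so ~90 null genera keeps the expected
#' false-discovery fraction of a 10-taxon truth set near 13 percent.
#'
#' @param n_per_group samples per group (default 6).
#' @param n_signal number of planted fourfold taxa (default 10).
#' @param fold enrichment fold change (default 4).
#' @param n_taxa community size (default 100).
#' @return a \code{\link{scenario_config}}.
#' @export
scenario_planted_signal <- function(n_per_group = 6, n_signal = 10, fold = 4,
                                    n_taxa = 100) {
  layout <- data.frame(
    group = c("WFt", "Lr", "HFt", "HBp", "PFt", "PBp"),
    site = c("wild", "wild", "cult1", "cult1", "cult2", "cult2"),
    host_role = rep(c("target", "companion"), 3),
    n = n_per_group,
    stringsAsFactors = FALSE
  )
  scenario_config(
    n_taxa = n_taxa, layout = layout,
    baseline_meanlog = 0, baseline_sdlog = 1, noise_sdlog = 0.3,
    differential = data.frame(taxon = 1L + seq_len(n_signal), group = "WFt",
                              fold = fold),
    bloomer = NULL,
    irm_taxon = 1L, irm_base_frac = 0.005,
    depth = 5e4, label = "planted_signal"
  )
}

#' Benchmark PA-DMA against IRMRA-DMA on a scenario
#'
#' Repeatedly simulates the scenario, screens one two-group contrast with
#' both methods, and scores each call against the generator's ground truth.
#' The false-positive rate is the fraction of truly-null taxa called
#' significant; the true-positive rate is the fraction of planted
#' differential taxa recovered. Per-replicate seeds are
#' \code{master_seed + replicate index}.
#'
#' @param config a \code{\link{scenario_config}} with an IRM taxon.
#' @param contrast two group labels to compare (default: first two target
#'   groups of the layout).
#' @param n_reps number of replicates (default 100).
#' @param alpha significance level (default 0.05).
#' @param master_seed integer master seed (default 42).
#' @param detection_limit percent detection limit for the RCQ pseudo-count
#'   (default 0.002).
#' @return object of class \code{dma_benchmark}: list with \code{per_rep}
#'   (data frame of per-replicate FPR/TPR for both methods),
#'   \code{summary} (means over replicates), counts of null and
#'   differential taxa, and the run parameters.
#' @export
run_benchmark <- function(config, contrast = NULL, n_reps = 100, alpha = 0.05,
                          master_seed = 42, detection_limit = 0.002) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(config$irm_taxon)) {
    stop_config("benchmark needs a scenario with a designated IRM taxon")
  }
  if (n_reps < 1) stop_config("n_reps must be >= 1")
  targets <- config$layout$group[config$layout$host_role == "target"]
  if (is.null(contrast)) contrast <- targets[1:2]
  if (length(contrast) != 2) stop_config("contrast must name exactly 2 groups")
  cfg <- screen_config(alpha = alpha)
  per <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    com <- simulate_community(config, seed = master_seed + r)
    irm_name <- rownames(com$counts)[config$irm_taxon]
    truth <- truth_differential(com, contrast[1], contrast[2])
    pa <- run_dma(com$percent, com$design, contrast, cfg, method = "PA-DMA")
    rcq <- compute_rcq(com$percent, irm_name, detection_limit, mode = "per_sample")
    ir <- run_dma(rcq, com$design, contrast, cfg, method = "IRMRA-DMA")
    sig_pa <- pa$genus[pa$significant]
    sig_ir <- ir$genus[ir$significant]
    nulls <- names(truth)[!truth]
    pos <- names(truth)[truth]
    per[[r]] <- data.frame(
      rep = r,
      fpr_pa = length(intersect(sig_pa, nulls)) / length(nulls),
      fpr_irm = length(intersect(sig_ir, nulls)) / length(nulls),
      tpr_pa = if (length(pos)) length(intersect(sig_pa, pos)) / length(pos) else NA_real_,
      tpr_irm = if (length(pos)) length(intersect(sig_ir, pos)) / length(pos) else NA_real_
    )
  }
  per <- do.call(rbind, per)
  structure(list(
    per_rep = per,
    summary = colMeans(per[, -1, drop = FALSE], na.rm = TRUE),
    n_null = sum(!truth), n_differential = sum(truth),
    contrast = contrast, alpha = alpha, n_reps = n_reps,
    master_seed = master_seed, scenario = config$label
  ), class = "dma_benchmark")
}

#' @export
print.dma_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark '%s': %s vs %s, %d reps, alpha = %g\n",
              x$scenario, x$contrast[1], x$contrast[2], x$n_reps, x$alpha))
  cat(sprintf("  null taxa: %d | differential taxa: %d\n",
              x$n_null, x$n_differential))
  s <- x$summary
  cat(sprintf("  FPR  PA-DMA: %.4f | IRMRA-DMA: %.4f\n", s["fpr_pa"], s["fpr_irm"]))
  if (!is.na(s["tpr_pa"])) {
    cat(sprintf("  TPR  PA-DMA: %.4f | IRMRA-DMA: %.4f\n", s["tpr_pa"], s["tpr_irm"]))
  }
  cat(sprintf("  reps with FPR_PA > FPR_IRM: %d / %d\n",
              sum(x$per_rep$fpr_pa > x$per_rep$fpr_irm), x$n_reps))
  invisible(x)
}

#' Write a simulated community to disk
#'
#' Emits the percent table, count table, design and per-contrast truth
#' flags as plain TSV files.
#'
#' @param community a \code{synthetic_community}.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "synthetic_community"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance_table(community$percent, file.path(dir, "table.tsv"))
  write_abundance_table(abundance_table(community$counts + 0, unit = "counts"),
                        file.path(dir, "counts.tsv"))
  utils::write.table(community$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  groups <- community$config$layout$group
  pairs <- utils::combn(groups, 2)
  truth <- data.frame(taxon = rownames(community$counts), stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    nm <- paste0(pairs[1, k], "_vs_", pairs[2, k])
    truth[[nm]] <- unname(truth_differential(community, pairs[1, k], pairs[2, k]))
  }
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
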