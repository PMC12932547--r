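# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the package implementation: the Wilcoxon
# oracle enumerates every assignment of pooled ranks to the first group and
# reads the two-sided p off the resulting exact distribution; the Spearman
# oracle loops over explicit permutations with stats::cor.

# Exact two-sided rank-sum p for tie-free samples, by full enumeration of
# all choose(na+nb, na) rank splits. W is the Mann-Whitney count
# sum_{ij} 1[a_i > b_j].
oracle_wilcoxon_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(na + nb, na)
  w_all <- colSums(matrix(sort(r)[splits], nrow = na)) - na * (na + 1) / 2
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Distribution-based variant reused by the exhaustive sweep: returns the
# vector of W values over all rank splits for group sizes (na, nb).
oracle_w_distribution <- function(na, nb) {
  splits <- utils::combn(na + nb, na)
  colSums(matrix(seq_len(na + nb)[splits], nrow = na)) - na * (na + 1) / 2
}

oracle_p_from_distribution <- function(w_all, w_obs) {
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Exact two-sided Spearman p by looping over all n! permutations of y.
# Recursion kept distinct from the package's vectorized enumeration.
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perm_list <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(perm_list(ry), function(p) stats::cor(rx, p), 0)
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# --- fixture builders -------------------------------------------------------

# Percent table from a named list of taxon rows; a Filler row is appended so
# every column sums to exactly 100.
make_percent_table <- function(rows, samples) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- samples
  filler <- 100 - colSums(m)
  stopifnot(all(filler >= 0))
  m <- rbind(m, Filler = filler)
  abundance_table(m, unit = "percent")
}

make_design <- function(groups, n_per_group = 2, sites = NULL, roles = NULL) {
  k <- length(groups)
  if (is.null(sites)) sites <- rep("S1", k)
  if (is.null(roles)) roles <- rep("target", k)
  study_design(data.frame(
    sample = unlist(lapply(seq_len(k), function(i) {
      paste0(groups[i], "_", seq_len(n_per_group))
    })),
    site = rep(sites, each = n_per_group),
    host_role = rep(roles, each = n_per_group),
    group = rep(groups, each = n_per_group),
    replicate = rep(seq_len(n_per_group), k),
    stringsAsFactors = FALSE
  ))
}

# A design/table pair where each group's samples hold prescribed values for
# one focal genus, plus filler. values_by_group: named list group -> numeric.
make_one_genus_fixture <- function(values_by_group, genus = "Focal",
                                   sites = NULL, roles = NULL) {
  groups <- names(values_by_group)
  n <- lengths(values_by_group)
  stopifnot(length(unique(n)) == 1)
  design <- make_design(groups, n_per_group = n[1], sites = sites, roles = roles)
  vals <- unlist(values_by_group, use.names = FALSE)
  tab <- make_percent_table(stats::setNames(list(vals), genus), design$sample)
  list(table = tab, design = design)
}
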