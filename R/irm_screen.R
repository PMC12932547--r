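#' Presence profile of every genus in one group
#'
#' A genus is "present" in a group either when it is detected (abundance
#' greater than zero) in at least one sample of the group (the default
#' rule), or, with a numeric rule, when the fraction of detected samples
#' reaches a prevalence threshold. Mean abundance is reported on the percent
#' scale.
#'
#' @param table an \code{abund_table}; converted to percent internally.
#' @param design a \code{study_design} covering the group's samples.
#' @param group group label to profile.
#' @param rule \code{"any"} (default: detected in >= 1 sample) or a number
#'   in (0, 1]: present iff prevalence >= that threshold.
#' @return data frame with columns \code{genus}, \code{group},
#'   \code{present}, \code{prevalence}, \code{mean_abundance}.
#' @export
presence_profile <- function(table, design, group, rule = "any") {
  stopifnot(inherits(table, "abund_table"), inherits(design, "study_design"))
  samp <- group_samples(design, group)
  miss <- setdiff(samp, colnames(table$values))
  if (length(miss) > 0) {
    stop_validation(sprintf("sample '%s' of group '%s' missing from table", miss[1], group))
  }
  pct <- as_percent(table)$values[, samp, drop = FALSE]
  prev <- rowMeans(pct > 0)
  present <- if (identical(rule, "any")) {
    prev > 0
  } else {
    thr <- as.numeric(rule)
    if (!is.finite(thr) || thr <= 0 || thr > 1) {
      stop_config("presence rule must be \"any\" or a prevalence threshold in (0, 1]")
    }
    prev >= thr
  }
  data.frame(
    genus = rownames(pct),
    group = group,
    present = unname(present),
    prevalence = unname(prev),
    mean_abundance = unname(rowMeans(pct)),
    stringsAsFactors = FALSE
  )
}

#' Host-unique genera at one site
#'
#' Genera present in the host profile and absent from the companion profile.
#' With several companion groups at a site, pass each profile separately and
#' intersect the results (absence is evaluated per companion group, not on a
#' pooled companion sample).
#'
#' @param host_profile presence profile of the host (target) group.
#' @param companion_profile presence profile of one companion group.
#' @return character vector of genus names.
#' @export
site_unique_genera <- function(host_profile, companion_profile) {
  if (!setequal(host_profile$genus, companion_profile$genus)) {
    stop_validation("host and companion profiles cover different taxon universes")
  }
  comp_present <- companion_profile$genus[companion_profile$present]
  host_present <- host_profile$genus[host_profile$present]
  setdiff(host_present, comp_present)
}

#' Intersect per-site host-unique genus sets
#'
#' Candidate internal reference microorganisms are genera host-unique at
#' every screened site; at least two sites are required.
#'
#' @param site_sets list of character vectors, one per site.
#' @return character vector: the intersection.
#' @export
irm_candidates <- function(site_sets) {
  if (!is.list(site_sets) || length(site_sets) < 2) {
    stop_config("IRM screening needs host-unique sets from at least 2 sites")
  }
  Reduce(intersect, site_sets)
}

#' Abundance-threshold filter for IRM candidates
#'
#' A candidate passes when its group-mean percent abundance is at or above
#' the threshold in every host group (inclusive comparison). Candidates are
#' ranked by their minimum across-group mean, descending, ties broken
#' alphabetically; all passers are reported, never a silent single pick.
#'
#' @param candidates character vector of candidate genera.
#' @param table an \code{abund_table}.
#' @param design a \code{study_design}.
#' @param host_groups labels of the target-host groups to check.
#' @param threshold minimum group-mean abundance, percent (default 0.005).
#' @return data frame with one row per candidate: per-group means,
#'   \code{min_mean}, \code{passes_threshold}.
#' @export
apply_irm_threshold <- function(candidates, table, design, host_groups,
                                threshold = 0.005) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop_config("threshold must be a positive percent abundance")
  }
  unknown <- setdiff(candidates, taxa(table))
  if (length(unknown) > 0) {
    stop_validation(sprintf("candidate '%s' is not in the table", unknown[1]))
  }
  pct <- as_percent(table)$values
  means <- sapply(host_groups, function(g) {
    rowMeans(pct[candidates, group_samples(design, g), drop = FALSE])
  })
  means <- matrix(means, nrow = length(candidates),
                  dimnames = list(candidates, host_groups))
  min_mean <- apply(means, 1, min)
  out <- data.frame(genus = candidates, stringsAsFactors = FALSE)
  for (g in host_groups) out[[paste0("mean_", g)]] <- unname(means[, g])
  out$min_mean <- unname(min_mean)
  out$passes_threshold <- unname(min_mean >= threshold)
  out[order(-out$min_mean, out$genus), , drop = FALSE]
}

#' Screen internal reference microorganism candidates
#'
#' Full screen: at every site having both a target and at least one
#' companion group, compute host-unique genera (present in the target group,
#' absent from every companion group of that site), intersect across sites,
#' then apply the abundance threshold over all target-host groups.
#'
#' @inheritParams apply_irm_threshold
#' @param presence_rule passed to \code{\link{presence_profile}}.
#' @return the ranked candidate data frame from
#'   \code{\link{apply_irm_threshold}}, with attribute \code{"sites"}.
#' @export
screen_irm <- function(table, design, threshold = 0.005, presence_rule = "any") {
  stopifnot(inherits(table, "abund_table"), inherits(design, "study_design"))
  sites <- unique(design$site)
  usable <- character(0)
  site_sets <- list()
  for (s in sites) {
    d <- design[design$site == s, , drop = FALSE]
    tg <- unique(d$group[d$host_role == "target"])
    cg <- unique(d$group[d$host_role == "companion"])
    if (length(tg) == 0 || length(cg) == 0) next
    sets <- list()
    for (t in tg) {
      hp <- presence_profile(table, design, t, rule = presence_rule)
      per_comp <- lapply(cg, function(cc) {
        site_unique_genera(hp, presence_profile(table, design, cc, rule = presence_rule))
      })
      sets[[t]] <- Reduce(intersect, per_comp)
    }
    site_sets[[s]] <- Reduce(intersect, sets)
    usable <- c(usable, s)
  }
  if (length(site_sets) < 2) {
    stop_config("IRM screening requires >= 2 sites with both target and companion groups")
  }
  cand <- irm_candidates(site_sets)
  host_groups <- unique(design$group[design$host_role == "target" &
                                       design$site %in% usable])
  res <- apply_irm_threshold(cand, table, design, host_groups, threshold)
  attr(res, "sites") <- usable
  attr(res, "threshold") <- threshold
  res
}
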