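test_that("presence profiles follow the detection and prevalence rules", {
  fx <- make_one_genus_fixture(list(G1 = c(0, 0, 0.01)))
  p <- presence_profile(fx$table, fx$design, "G1")
  g <- p[p$genus == "Focal", ]
  expect_true(g$present)
  expect_equal(g$prevalence, 1 / 3)
  expect_equal(g$mean_abundance, 0.01 / 3)

  fx0 <- make_one_genus_fixture(list(G1 = c(0, 0, 0)))
  p0 <- presence_profile(fx0$table, fx0$design, "G1")
  expect_false(p0$present[p0$genus == "Focal"])
  expect_equal(p0$prevalence[p0$genus == "Focal"], 0)

  p5 <- presence_profile(fx$table, fx$design, "G1", rule = 0.5)
  expect_false(p5$present[p5$genus == "Focal"])

  expect_error(presence_profile(fx$table, fx$design, "nope"),
               class = "irmdma_validation_error")
})

test_that("host-unique genera are present in host and absent in companion", {
  design <- make_design(c("WFt", "Lr"), n_per_group = 3,
                        roles = c("target", "companion"))
  m <- rbind(
    A = c(1, 2, 1, 0, 0, 0),
    B = c(5, 5, 5, 4, 4, 4),
    C = c(0, 3, 3, 0, 0, 0),
    G = c(2, 0, 1, 0, 0, 0)
  )
  colnames(m) <- design$sample
  tab <- total_sum_scale(abundance_table(m, unit = "counts"))
  hp <- presence_profile(tab, design, "WFt")
  cp <- presence_profile(tab, design, "Lr")
  expect_setequal(site_unique_genera(hp, cp), c("A", "C", "G"))

  # host set a subset of companion set -> empty
  hp_sub <- hp; hp_sub$present <- hp_sub$genus == "B"
  expect_length(site_unique_genera(hp_sub, cp), 0)

  cp_bad <- cp[cp$genus != "G", ]
  expect_error(site_unique_genera(hp, cp_bad), class = "irmdma_validation_error")
})

test_that("candidates are the intersection of per-site unique sets", {
  expect_equal(irm_candidates(list(c("X", "Y"), c("Y", "Z"), "Y")), "Y")
  expect_length(irm_candidates(list(c("A"), c("B"), c("C"))), 0)
  expect_error(irm_candidates(list(c("A", "B"))), class = "irmdma_config_error")
})

test_that("threshold filter reproduces the reference-genus eligibility calls", {
  # group means of two archetypal all-site host-unique genera:
  # the first passes 0.005% in every host group, the second fails at the
  # two cultivated sites.
  fx <- list(
    Clavatospora = c(0.1147, 0.1147, 0.0196, 0.0196, 0.0087, 0.0087),
    Pestalotiopsis = c(0.14834, 0.14834, 0.00106, 0.00106, 0.00042, 0.00042),
    Borderline = rep(0.005, 6)
  )
  design <- make_design(c("WFt", "HFt", "PFt"), n_per_group = 2,
                        sites = c("wild", "cult1", "cult2"))
  tab <- make_percent_table(fx, design$sample)
  res <- apply_irm_threshold(names(fx), tab, design,
                             host_groups = c("WFt", "HFt", "PFt"),
                             threshold = 0.005)
  expect_true(res$passes_threshold[res$genus == "Clavatospora"])
  expect_false(res$passes_threshold[res$genus == "Pestalotiopsis"])
  expect_true(res$passes_threshold[res$genus == "Borderline"])  # inclusive >=
  expect_equal(res$mean_WFt[res$genus == "Clavatospora"], 0.1147)
  expect_equal(res$min_mean[res$genus == "Pestalotiopsis"], 0.00042)
  # ranked by minimum across-group mean, descending
  expect_equal(res$genus[1], "Clavatospora")
  expect_error(apply_irm_threshold("Ghost", tab, design, "WFt"),
               class = "irmdma_validation_error")
  expect_error(apply_irm_threshold("Clavatospora", tab, design, "WFt",
                                   threshold = 0), class = "irmdma_config_error")
})

test_that("full screen keeps only genera host-unique at every site", {
  groups <- c("WFt", "Lr", "HFt", "HBp", "PFt", "PBp")
  design <- make_design(groups, n_per_group = 2,
                        sites = rep(c("wild", "cult1", "cult2"), each = 2),
                        roles = rep(c("target", "companion"), 3))
  # Sample order: WFt, Lr, HFt, HBp, PFt, PBp (2 each).
  # A, B: present at all hosts, absent in all companions, abundant.
  # C: leaks into one companion (HBp). D: missing at one host site (HFt).
  rows <- list(
    A = c(1, 1, 0, 0, 1, 1, 0, 0, 2, 2, 0, 0),
    B = c(3, 3, 0, 0, 1, 1, 0, 0, 1, 1, 0, 0),
    C = c(1, 1, 0, 0, 1, 1, 0.2, 0, 1, 1, 0, 0),
    D = c(1, 1, 0, 0, 0, 0, 0, 0, 1, 1, 0, 0)
  )
  tab <- make_percent_table(rows, design$sample)
  scr <- screen_irm(tab, design, threshold = 0.005)
  expect_setequal(scr$genus, c("A", "B"))
  expect_true(all(scr$passes_threshold))

  # order invariance: permuting samples and design rows changes nothing
  set.seed(7)
  perm <- sample(ncol(tab$values))
  tab2 <- abundance_table(tab$values[, perm], unit = "percent")
  design2 <- design[sample(nrow(design)), ]
  class(design2) <- class(design)
  scr2 <- screen_irm(tab2, design2, threshold = 0.005)
  expect_equal(scr2$genus, scr$genus)
  expect_equal(scr2$min_mean, scr$min_mean)
})

test_that("screen recovers the planted reference taxon from a synthetic community", {
  com <- simulate_community(scenario_planted_signal(), seed = 7)
  scr <- screen_irm(com$percent, com$design, threshold = 0.005)
  passers <- scr$genus[scr$passes_threshold]
  expect_equal(passers, "IRM_ref")
})
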