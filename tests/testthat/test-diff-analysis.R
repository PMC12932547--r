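test_that("Wilcoxon wrapper matches frozen exact values and the enumeration oracle", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # fully separated groups: smallest attainable two-sided exact p
  expect_equal(wilcoxon_rank_sum(1:6, 7:12)$p.value, 2 / 924, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p.value, 2 / 20, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    x <- sample(100, na + nb)  # tie-free
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(wilcoxon_rank_sum(a, b)$p.value, oracle_wilcoxon_p(a, b),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(1, 2:4), class = "irmdma_validation_error")
  expect_error(wilcoxon_rank_sum(c(1, NA), 2:4), class = "irmdma_validation_error")
})

test_that("ties and large groups fall back to the corrected normal approximation", {
  a <- c(1, 1, 2, 5); b <- c(2, 3, 3, 8)
  res <- wilcoxon_rank_sum(a, b)
  expect_false(res$exact)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(res$p.value, ref$p.value)
  res2 <- wilcoxon_rank_sum(1:9, 10:18)  # above the exact cutoff of 8
  expect_false(res2$exact)
})

test_that("Kruskal-Wallis matches the hand-computed H and chi-square p", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-12)  # rank sums 3, 7, 11
  expect_equal(res$p.value, pchisq(32 / 7, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p.value, 0.1017013, tolerance = 1e-6)
  expect_equal(res$df, 2)

  degen <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p.value, 1)

  expect_error(kruskal_wallis(list(1:3)), class = "irmdma_validation_error")
  expect_error(kruskal_wallis(list(1:3, 2)), class = "irmdma_validation_error")
})

test_that("two-group Kruskal-Wallis equals the squared normal-approximation Wilcoxon", {
  set.seed(22)
  for (i in 1:15) {
    x <- sample(200, 11)
    a <- x[1:5]; b <- x[6:11]
    kw <- kruskal_wallis(list(a, b))
    wz <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(kw$p.value, wz$p.value, tolerance = 1e-9)
  }
})

test_that("Spearman rho handles perfect monotone pairs and matches the permutation oracle", {
  expect_equal(spearman_rho(1:4, c(2, 4, 6, 8))$rho, 1)
  expect_equal(spearman_rho(1:4, c(8, 6, 4, 2))$rho, -1)
  set.seed(23)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    res <- spearman_rho(x, y)
    expect_equal(res$p.value, oracle_spearman_p(x, y), tolerance = 1e-12)
    expect_equal(res$rho, cor(x, y, method = "spearman"))
  }
  # tie-free case agrees with the classical exact distribution
  x <- c(3, 1, 4, 9, 2, 6); y <- c(8, 2, 7, 9, 1, 5)
  expect_equal(spearman_rho(x, y)$p.value,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value,
               tolerance = 1e-12)
  # large n: t approximation
  set.seed(24)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman_rho(x, y)$method, "t_approximation")
  expect_error(spearman_rho(rep(1, 5), 1:5), class = "irmdma_degenerate_error")
  expect_error(spearman_rho(1:3, 1:3), class = "irmdma_validation_error")
})

test_that("the DMA screen applies the relative-abundance filter and direction rules", {
  design <- make_design(c("WFt", "HFt"), n_per_group = 6)
  set.seed(25)
  # Rare: clearly shifted but below 0.005% everywhere -> filtered out.
  # Flat: identical in both groups -> direction none.
  # Shifted: planted 8-fold change -> significant, direction up.
  rows <- list(
    Rare = c(runif(6, 0.0030, 0.0045), runif(6, 0.0001, 0.0010)),
    Flat = rep(c(1.0, 1.1, 0.9, 1.05, 0.95, 1.0), 2),
    Shifted = c(runif(6, 7, 9), runif(6, 0.9, 1.1))
  )
  tab <- make_percent_table(rows, design$sample)
  res <- run_dma(tab, design, c("WFt", "HFt"), screen_config())

  rare <- res[res$genus == "Rare", ]
  expect_false(rare$passed_abundance_filter)
  expect_false(rare$significant)
  expect_lt(rare$p, 0.05)  # filtered despite a small p

  flat <- res[res$genus == "Flat", ]
  expect_identical(flat$direction, "none")
  expect_false(flat$significant)

  sh <- res[res$genus == "Shifted", ]
  expect_true(sh$significant)
  expect_identical(sh$direction, "up")
  expect_equal(sh$log2fc, log2(sh$mean_WFt / sh$mean_HFt))
  expect_identical(res$method[1], "PA-DMA")
  expect_equal(res$p, sort(res$p))  # sorted by p
})

test_that("the screen is invariant to sample-column permutation", {
  com <- simulate_community(scenario_null_load_shift(), seed = 5)
  cfg <- screen_config()
  res1 <- run_dma(com$percent, com$design, c("WFt", "HFt"), cfg)
  set.seed(26)
  perm <- sample(ncol(com$percent$values))
  tab2 <- abundance_table(com$percent$values[, perm], unit = "percent")
  res2 <- run_dma(tab2, com$design, c("WFt", "HFt"), cfg)
  expect_equal(res1, res2, ignore_attr = TRUE)
})

test_that("IRMRA-DMA screening uses the RCQ scale but the relative-abundance filter", {
  com <- simulate_community(scenario_null_load_shift(), seed = 6)
  rcq <- compute_rcq(com$percent, "IRM_ref", 0.002)
  res <- run_dma(rcq, com$design, c("WFt", "HFt"), screen_config())
  expect_identical(res$method[1], "IRMRA-DMA")
  # the reference genus itself is constant 1 on the RCQ scale: never significant
  expect_false(res$significant[res$genus == "IRM_ref"])
  # filter flags equal the PA-scale flags for the same genera
  pa <- run_dma(com$percent, com$design, c("WFt", "HFt"), screen_config())
  expect_equal(res$passed_abundance_filter[match(pa$genus, res$genus)],
               pa$passed_abundance_filter)

  expect_error(run_dma(rcq, com$design, c("WFt", "WFt"), screen_config()),
               class = "irmdma_config_error")
})

test_that("wild-enriched sets require significance and a strictly highest target", {
  design <- make_design(c("WFt", "HFt", "PFt"), n_per_group = 4)
  set.seed(27)
  rows <- list(
    # significant across groups but WFt below PFt -> excluded
    NotHighest = c(runif(4, 1.0, 1.2), runif(4, 0.2, 0.3), runif(4, 2.0, 2.2)),
    # WFt highest but groups overlap heavily -> not significant -> excluded
    NotSig = c(runif(4, 1.0, 1.4), runif(4, 0.9, 1.3), runif(4, 0.95, 1.35)),
    # planted: WFt clearly above both -> included
    Planted = c(runif(4, 4.0, 4.4), runif(4, 0.9, 1.1), runif(4, 0.9, 1.1))
  )
  tab <- make_percent_table(rows, design$sample)
  res <- run_dma(tab, design, c("WFt", "HFt", "PFt"), screen_config())
  ws <- wild_enriched_set(res, "WFt", c("HFt", "PFt"))
  expect_false("NotHighest" %in% ws)
  expect_false("NotSig" %in% ws)
  expect_true("Planted" %in% ws)
  expect_error(wild_enriched_set(res, "WFt", c("WFt", "HFt")),
               class = "irmdma_config_error")
  # median centers are available as an option
  ws_med <- wild_enriched_set(res, "WFt", c("HFt", "PFt"), center = "median",
                              x = tab, design = design)
  expect_true("Planted" %in% ws_med)
})

test_that("Benjamini-Hochberg mode adjusts the significance calls", {
  com <- simulate_community(scenario_null_load_shift(), seed = 8)
  raw <- run_dma(com$percent, com$design, c("WFt", "HFt"), screen_config())
  bh <- run_dma(com$percent, com$design, c("WFt", "HFt"),
                screen_config(mtc = "BH"))
  expect_true("p_adj" %in% names(bh))
  expect_equal(bh$p_adj, p.adjust(bh$p, "BH"))
  expect_lte(sum(bh$significant), sum(raw$significant))
})
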