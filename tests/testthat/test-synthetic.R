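test_that("simulation is deterministic given config and seed", {
  cfg <- scenario_null_load_shift()
  c1 <- simulate_community(cfg, seed = 42)
  c2 <- simulate_community(cfg, seed = 42)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$absolute, c2$absolute)
  c3 <- simulate_community(cfg, seed = 43)
  expect_false(identical(c1$counts, c3$counts))
})

test_that("count and percent tables respect depth and closure", {
  com <- simulate_community(scenario_planted_signal(), seed = 3)
  expect_true(all(colSums(com$counts) == com$config$depth))
  expect_equal(colSums(com$percent$values),
               setNames(rep(100, ncol(com$counts)), colnames(com$counts)),
               tolerance = 1e-6)
})

test_that("ground-truth flags are a pure function of the configuration", {
  cfg <- scenario_null_load_shift()
  com <- simulate_community(cfg, seed = 9)
  tr <- truth_differential(com, "WFt", "HFt")
  expect_true(tr[["bloomer"]])           # load-shift taxon is truly differential
  expect_false(any(tr[names(tr) != "bloomer"]))
  # bloomer surges in both cultivated groups, so that contrast is null
  tr2 <- truth_differential(com, "HFt", "PFt")
  expect_false(any(tr2))

  cfg0 <- scenario_config(
    n_taxa = 20,
    layout = data.frame(group = c("A", "B"), site = c("s1", "s2"),
                        host_role = "target", n = 3),
    depth = 1e3, label = "null")
  com0 <- simulate_community(cfg0, seed = 1)
  expect_false(any(truth_differential(com0, "A", "B")))
})

test_that("the bloomer shifts total load and compresses others only in percent", {
  cfg <- scenario_null_load_shift()
  com <- simulate_community(cfg, seed = 10)
  grp <- com$design$group
  load_ratio <- mean(com$load[grp == "HFt"]) / mean(com$load[grp == "WFt"])
  expect_gt(load_ratio, 1.5)  # twentyfold bloom of a ~5% taxon about doubles load
  expect_lt(load_ratio, 2.5)

  plain <- setdiff(rownames(com$counts), c("bloomer", "IRM_ref"))
  abs_ratio <- rowMeans(com$absolute[plain, grp == "HFt"]) /
    rowMeans(com$absolute[plain, grp == "WFt"])
  expect_equal(mean(abs_ratio), 1, tolerance = 0.1)  # absolute scale unchanged
  pct_ratio <- rowMeans(com$percent$values[plain, grp == "HFt"]) /
    rowMeans(com$percent$values[plain, grp == "WFt"])
  expect_lt(stats::median(pct_ratio), 0.75)  # relative scale compressed
})

test_that("the IRM taxon is present in hosts and absent in companions", {
  com <- simulate_community(scenario_planted_signal(), seed = 4)
  role <- com$design$host_role
  expect_true(all(com$counts["IRM_ref", role == "target"] > 0))
  expect_true(all(com$counts["IRM_ref", role == "companion"] == 0))
})

test_that("benchmark seeds derive from the master seed and alpha ~ 0 silences calls", {
  cfg <- scenario_null_load_shift()
  b1 <- run_benchmark(cfg, n_reps = 2, master_seed = 42)
  b2 <- run_benchmark(cfg, n_reps = 2, master_seed = 42)
  expect_identical(b1$per_rep, b2$per_rep)

  tiny <- run_benchmark(cfg, n_reps = 1, alpha = 1e-12, master_seed = 42)
  expect_equal(tiny$per_rep$fpr_pa, 0)
  expect_equal(tiny$per_rep$fpr_irm, 0)
  expect_equal(tiny$per_rep$tpr_irm, 0)

  no_irm <- scenario_config(
    n_taxa = 10,
    layout = data.frame(group = c("A", "B"), site = c("s1", "s2"),
                        host_role = "target", n = 3),
    depth = 1e3)
  expect_error(run_benchmark(no_irm), class = "irmdma_config_error")
})

test_that("parameter recovery without load shift is method-agnostic", {
  cfg <- scenario_planted_signal()
  com <- simulate_community(cfg, seed = 11)
  cfgs <- screen_config()
  pa <- run_dma(com$percent, com$design, c("WFt", "HFt"), cfgs)
  rcq <- compute_rcq(com$percent, "IRM_ref", 0.002)
  ir <- run_dma(rcq, com$design, c("WFt", "HFt"), cfgs)
  truth <- truth_differential(com, "WFt", "HFt")
  planted <- names(truth)[truth]
  rec_pa <- intersect(pa$genus[pa$significant], planted)
  rec_ir <- intersect(ir$genus[ir$significant], planted)
  expect_gt(length(intersect(rec_pa, rec_ir)), 0.5 * length(planted))
})

test_that("a simulated community writes and reads back as plain TSV", {
  com <- simulate_community(scenario_planted_signal(n_per_group = 3, n_taxa = 30),
                            seed = 12)
  dir <- withr::local_tempdir()
  write_community(com, dir)
  expect_true(all(file.exists(file.path(
    dir, c("table.tsv", "counts.tsv", "design.tsv", "truth.tsv")))))
  back <- read_abundance_table(file.path(dir, "table.tsv"), unit = "percent")
  expect_equal(back$values, com$percent$values)
  d <- read_design(file.path(dir, "design.tsv"))
  expect_equal(nrow(d), ncol(com$counts))
})
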