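test_that("sim_config validates its invariants", {
  expect_error(sim_config(target_prevalence = c(tumor = 0.5, lung = 0.4)),
               "sum to 1")
  expect_error(sim_config(target_prevalence = c(tumor = 1.5, lung = -0.5)),
               "nonnegative")
  expect_error(sim_config(grid_rows = 2), ">= 3")
  expect_error(sim_config(grid_rows = 5, background_border = 3), "border")
  expect_error(sim_config(censor_frac = 1.2), "censor_frac")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("label grids honor border, prevalence targets and determinism", {
  # degenerate distribution: all interior tumor
  cfg <- sim_config(seed = 1, grid_rows = 10, grid_cols = 10,
                    target_prevalence = c(tumor = 1))
  g <- gen_label_grid(cfg)
  inner <- g[3:8, 3:8]
  expect_true(all(inner == 0L))
  expect_equal(unname(tissue_prevalence(g)[["t_tumor"]]), 1)
  # border ring is BACKGROUND
  expect_true(all(g[1:2, ] == 8L) && all(g[, 1:2] == 8L))

  # uniform target on a 100x100 grid: realized fractions near 1/8
  cfg2 <- sim_config(seed = 7, grid_rows = 100, grid_cols = 100)
  g2 <- gen_label_grid(cfg2)
  tip <- tissue_prevalence(g2)
  expect_true(all(tip >= 0.075 & tip <= 0.175))
  expect_true(all(abs(tip - 0.125) <= 0.05))

  # byte-identical under the same config
  expect_identical(g2, gen_label_grid(cfg2))
})

test_that("contiguity controls connected-component size", {
  bigger <- 0L
  for (seed in 1:20) {
    make <- function(cont) gen_label_grid(
      sim_config(seed = seed, grid_rows = 30, grid_cols = 30,
                 contiguity = cont))
    hi <- mean(oracle_component_sizes(make(10)))
    lo <- mean(oracle_component_sizes(make(0.05)))
    if (hi > lo) bigger <- bigger + 1L
  }
  expect_equal(bigger, 20L)
})

test_that("prevalence control tightens as the grid grows", {
  err <- function(rows) {
    mean(vapply(1:10, function(s) {
      cfg <- sim_config(seed = s, grid_rows = rows, grid_cols = rows)
      mean(abs(tissue_prevalence(gen_label_grid(cfg)) - 0.125))
    }, numeric(1)))
  }
  expect_lt(err(300), err(50))
})

test_that("probability tables put the stated confidence on the true class", {
  g <- random_grid(3, 10, 10)
  expect_error(gen_probability_table(g, confidence = 0.1, seed = 1),
               "confidence")
  # confidence 1: one-hot rows, argmax recovers the grid exactly
  pt1 <- gen_probability_table(g, confidence = 1, seed = 1)
  p <- as.matrix(pt1[probability_columns()])
  expect_true(all(p %in% c(0, 1)))
  expect_equal(assign_labels(pt1), pt1$label)

  # confidence 0.6 at scale: argmax accuracy >= 0.99
  cfg <- sim_config(seed = 2, grid_rows = 102, grid_cols = 102,
                    background_border = 1)
  gbig <- gen_label_grid(cfg)
  pt <- gen_probability_table(gbig, confidence = 0.6, seed = 4)
  expect_gte(mean(assign_labels(pt) == pt$label), 0.99)
  expect_gte(nrow(pt), 10000)

  # near-uniform confidence: mean predictive entropy within 5% of ln 9
  pt_u <- gen_probability_table(g, confidence = 0.12, seed = 5)
  ent <- apply(as.matrix(pt_u[probability_columns()]), 1,
               predictive_entropy)
  expect_gt(mean(ent), 0.95 * log(9))
  expect_lte(mean(ent), log(9))

  # determinism
  expect_identical(pt_u, gen_probability_table(g, 0.12, seed = 5))
})

test_that("patch images satisfy the luma-filter contracts", {
  blank <- gen_patch_image("blank", side_px = 172, seed = 1)
  expect_gte(mean(luma(blank) >= 200), 0.99)
  expect_false(is_relevant_patch(blank))

  tissue <- gen_patch_image("tissue", side_px = 172, seed = 2)
  expect_gte(mean(luma(tissue) < 200), 0.2)
  expect_true(is_relevant_patch(tissue))

  # relevance flips exactly where the black/white pixel ratio crosses 0.05
  side <- 20; n <- side^2
  flips <- vapply(seq(0, 0.2, by = 0.005), function(d) {
    img <- gen_patch_image("mixed", side_px = side, seed = 3, dark_frac = d)
    k <- round(d * n)
    expected <- k / (n - k) > 0.05
    identical(is_relevant_patch(img), expected)
  }, logical(1))
  expect_true(all(flips))
})

test_that("cohorts are reproducible with calibrated censoring and valid
           outcome columns", {
  cfg <- sim_config(seed = 13, n_patients = 400)
  d <- gen_cohort(cfg)
  expect_identical(d, gen_cohort(cfg))
  expect_equal(nrow(d), 400L)
  expect_false(anyNA(d))
  expect_true(all(d$time > 0))
  expect_true(all(d$event %in% 0:1))
  expect_true(all(unlist(d[c("EGFR", "STK11", "TP53")]) %in% 0:1))
  expect_lte(abs(mean(d$event == 0) - cfg$censor_frac), 0.05)
  # TIP rows sum to one per patient
  tip_cols <- paste0("t_", tolower(tissue_class_names()))
  expect_equal(rowSums(d[tip_cols]), rep(1, 400), tolerance = 1e-9)
  expect_error(
    gen_cohort(sim_config(cox_betas = c(bogus_col = 1), n_patients = 5)),
    "unknown beta")
})

test_that("null cohorts give calibrated downstream log-rank tests", {
  hits <- 0L
  for (s in 1:200) {
    cfg <- sim_config(seed = 5000 + s, n_patients = 40, grid_rows = 10,
                      grid_cols = 10, background_border = 1)
    d <- gen_cohort(cfg)
    hi <- d$t_immune > median(d$t_immune)
    if (length(unique(hi)) < 2) next
    p <- logrank_test(hi, d$time, d$event)$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.01)
  expect_lte(hits / 200, 0.10)
})

test_that("cohort tables and configs round-trip through disk", {
  cfg <- sim_config(seed = 3, n_patients = 15, grid_rows = 10,
                    grid_cols = 10, cox_betas = c(t_necrosis = 0.5))
  d <- gen_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(d, dir)
  tabs <- read_cohort(dir)
  expect_equal(nrow(tabs$features), 15L)
  expect_equal(tabs$survival$time, d$time)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  cfg2 <- read_sim_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$target_prevalence, cfg$target_prevalence)
  expect_equal(cfg2$cox_betas$t_necrosis, 0.5)
  # the re-read config regenerates the same grids
  expect_identical(gen_label_grid(cfg2), gen_label_grid(cfg))
})
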