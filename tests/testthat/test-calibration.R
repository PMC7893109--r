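test_that("thresholds are class-median midpoints, robust to direction", {
  panel <- gene_panel("demo", c("up", "down"), directions = c(1, -1))
  x <- rbind(
    up = c(8.2, 8.0, 7.8, 4.1, 4.0, 3.9),
    down = c(4.2, 4.0, 3.8, 8.1, 8.0, 7.9)
  )
  colnames(x) <- sprintf("s%d", 1:6)
  labels <- setNames(rep(c("active", "inactive"), each = 3), colnames(x))
  th <- derive_thresholds(x, labels, panel)
  expect_equal(unname(th["up"]), 6.0)
  expect_equal(unname(th["down"]), 6.0)

  # identical class medians: threshold equals that value
  x2 <- rbind(up = rep(5, 6), down = rep(5, 6))
  colnames(x2) <- colnames(x)
  th2 <- derive_thresholds(x2, labels, panel)
  expect_equal(unname(th2), c(5, 5))

  # repressed gene: "up" class is the inactive-labeled class, so the
  # downstream evidence weight of a high reading flips sign vs a +1 gene
  m <- calibrate(panel, x, labels)
  r <- infer_activity(m, c(up = 8, down = 8))
  contrib <- attr(r, "contributions")
  expect_gt(contrib["up", 1], 0)
  expect_lt(contrib["down", 1], 0)
  expect_equal(contrib["up", 1], -contrib["down", 1], tolerance = 1e-12)
})

test_that("threshold derivation errors are specific", {
  panel <- make_panel(2)
  x <- matrix(rnorm(8), 2, 4, dimnames = list(c("G01", "G03"), sprintf("s%d", 1:4)))
  labels <- setNames(rep(c("active", "inactive"), 2), colnames(x))
  expect_error(derive_thresholds(x, labels, panel), "G02",
               class = "pathsig_config_error")

  x_ok <- matrix(rnorm(8), 2, 4, dimnames = list(c("G01", "G02"), colnames(x)))
  one_class <- setNames(rep("active", 4), colnames(x))
  expect_error(derive_thresholds(x_ok, one_class, panel),
               class = "pathsig_calibration_error")
})

test_that("emission fitting uses Laplace-smoothed counts", {
  panel <- make_panel(2)
  # G01: 90 of 100 active samples above t = 0, 0 of 10 inactive above
  n_a <- 100; n_i <- 10
  samples <- sprintf("s%03d", seq_len(n_a + n_i))
  labels <- setNames(rep(c("active", "inactive"), c(n_a, n_i)), samples)
  g1 <- c(rep(1, 90), rep(-1, 10), rep(-1, n_i))
  g2 <- c(rep(1, n_a), rep(-1, n_i))
  x <- rbind(G01 = g1, G02 = g2)
  colnames(x) <- samples
  em <- fit_emissions(x, labels, panel, thresholds = c(G01 = 0, G02 = 0))
  expect_equal(em$p_high_given_up[em$probe == "G01"], 91 / 102)
  expect_equal(em$p_high_given_down[em$probe == "G01"], 1 / 12)

  # smoothing floor: fitted probabilities never exactly 0 or 1
  expect_true(all(em$p_high_given_up > 0 & em$p_high_given_up < 1))
  expect_true(all(em$p_high_given_down > 0 & em$p_high_given_down < 1))

  # alpha must be positive, classes must be large enough
  expect_error(fit_emissions(x, labels, panel, c(G01 = 0, G02 = 0), alpha = 0),
               class = "pathsig_config_error")
  tiny <- labels[c(1, n_a + 1)]
  expect_error(fit_emissions(x[, names(tiny)], tiny, panel, c(G01 = 0, G02 = 0)),
               class = "pathsig_calibration_error")
  expect_error(calibrate(panel, x[, names(tiny)], tiny),
               class = "pathsig_calibration_error")
})

test_that("calibration separates a synthetic cohort and records provenance", {
  panel <- make_panel(12)
  sim <- simulate_cohort(panel, 50, 50, seed = 11)
  m <- calibrate(panel, sim$expression, sim$labels)
  expect_equal(m$calibration$n_active, 50)
  expect_equal(m$calibration$threshold_rule, "class-median-midpoint")

  held <- simulate_cohort(panel, 50, 50, seed = 12)
  sc <- predict(m, held$expression)
  expect_gte(auc_score(sc$score, held$labels[sc$sample_id]), 0.99)
})

test_that("shuffled labels destroy the evidence weights (permutation control)", {
  panel <- make_panel(12)
  sim <- simulate_cohort(panel, 50, 50, seed = 21)
  held <- simulate_cohort(panel, 50, 50, seed = 22)
  m_true <- calibrate(panel, sim$expression, sim$labels)

  set.seed(23)
  aucs <- replicate(20, {
    perm <- setNames(sample(sim$labels), names(sim$labels))
    m0 <- calibrate(panel, sim$expression, perm)
    sc <- predict(m0, held$expression)
    auc_score(sc$score, held$labels[sc$sample_id])
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)

  # per-gene evidence weights near zero relative to the true calibration
  perm <- setNames(sample(sim$labels), names(sim$labels))
  m0 <- calibrate(panel, sim$expression, perm)
  expect_lt(m0$l_max, 0.2 * m_true$l_max)
})

test_that("recalibration recovers generating emission parameters (n = 500/class)", {
  set.seed(31)
  panel <- make_panel(12)
  ph_up <- runif(12, 0.7, 0.95)
  th <- runif(12, 5, 8)
  # symmetric within-state noise: the class-median-midpoint rule is unbiased
  gen <- pathway_model(panel, default_priors(panel),
                       emission_parameters(unlist(panel$probes), th,
                                           ph_up, 1 - ph_up))
  sim <- simulate(gen, nsim = 500, seed = 32)
  fit <- calibrate(panel, sim$expression, sim$labels)
  expect_lt(max(abs(fit$emissions$p_high_given_up - ph_up)), 0.05)
  expect_lt(max(abs(fit$emissions$p_high_given_down - (1 - ph_up))), 0.05)
  # generating class-median midpoint = (mu_up + mu_down)/2 = threshold here
  expect_lt(max(abs(fit$emissions$threshold - th)), 0.2)
})

test_that("platform port keeps priors, re-fits emissions, preserves ranking", {
  panel <- make_panel(12, reference_genes = c("REF1", "REF2"))
  sim <- simulate_cohort(panel, 50, 50, seed = 41)
  m_int <- calibrate(panel, sim$expression, sim$labels)

  cq <- simulate_cq(sim$expression, panel, seed = 42)
  xq <- normalize_cq(cq)
  m_cq <- port_platform(m_int, xq, sim$labels)
  expect_equal(m_cq$platform, "cq")
  expect_identical(m_cq$priors, m_int$priors)

  held <- simulate_cohort(panel, 40, 40, seed = 43)
  sc_int <- predict(m_int, held$expression)
  sc_cq <- predict(m_cq, normalize_cq(simulate_cq(held$expression, panel, seed = 44)))
  rho <- cor(sc_int$score, sc_cq$score, method = "spearman")
  expect_gte(rho, 0.9)

  # reduced panel port works; genes missing from the new matrix error
  reduced <- gene_panel("Wnt", panel$genes$gene[1:6])
  m_red <- port_platform(m_int, xq, sim$labels, panel = reduced)
  expect_equal(nrow(m_red$panel$genes), 6)
  xq_missing <- xq[-1, , drop = FALSE]
  expect_error(port_platform(m_int, xq_missing, sim$labels),
               class = "pathsig_config_error")
  expect_error(port_platform(m_int, xq[, 0], sim$labels),
               class = "pathsig_config_error")
})

test_that("porting onto label-shuffled (pure-noise) data collapses the model", {
  panel <- make_panel(12, reference_genes = "REF1")
  sim <- simulate_cohort(panel, 50, 50, seed = 51)
  m_int <- calibrate(panel, sim$expression, sim$labels)
  xq <- normalize_cq(simulate_cq(sim$expression, panel, seed = 52))
  set.seed(53)
  perm <- setNames(sample(sim$labels), names(sim$labels))
  m_noise <- port_platform(m_int, xq, perm)
  expect_lt(m_noise$l_max, 0.2 * m_int$l_max)
})
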