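test_that("cohort simulation is fully reproducible and leaves global RNG alone", {
  panel <- make_panel(6)
  a <- simulate_cohort(panel, 10, 10, seed = 1)
  b <- simulate_cohort(panel, 10, 10, seed = 1)
  expect_identical(a, b)
  c2 <- simulate_cohort(panel, 10, 10, seed = 2)
  expect_false(identical(a$expression, c2$expression))

  # seed is mandatory and global RNG state is untouched
  expect_error(simulate_cohort(panel, 2, 2), class = "pathsig_config_error")
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_cohort(panel, 5, 5, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate cohort shapes work", {
  panel <- make_panel(3)
  sim <- simulate_cohort(panel, 0, 4, seed = 3)
  expect_equal(unname(sim$labels), rep("inactive", 4))
  expect_equal(ncol(sim$expression), 4)
  expect_error(simulate_cohort(panel, -1, 4, seed = 3),
               class = "pathsig_config_error")
  expect_error(simulate_cohort(panel, 4, 4, sd = 0, seed = 3),
               class = "pathsig_config_error")
})

test_that("class-conditional structure matches the generator's description", {
  panel <- make_panel(8, directions = c(rep(1, 6), -1, -1))
  sim <- simulate_cohort(panel, 400, 400, seed = 4, sd = 0.5)
  act <- names(sim$labels)[sim$labels == "active"]
  ina <- names(sim$labels)[sim$labels == "inactive"]
  # induced gene high in active; repressed gene high in inactive
  expect_gt(mean(sim$expression["G01", act]), mean(sim$expression["G01", ina]))
  expect_lt(mean(sim$expression["G07", act]), mean(sim$expression["G07", ina]))
  # latent state frequency ~ 0.95 for the label-consistent class
  expect_equal(mean(sim$states["G01", act]), 0.95, tolerance = 0.03)
  expect_equal(mean(sim$states["G07", ina]), 0.95, tolerance = 0.03)
})

test_that("low-input degradation composes as documented", {
  panel <- make_panel(5)
  sim <- simulate_cohort(panel, 10, 10, seed = 5)

  # dropout 0 + extra_sd 0 is the identity
  same <- degrade_low_input(sim$expression, 0, 0, seed = 6)
  expect_equal(same, sim$expression, tolerance = 1e-15)

  # dropout 1 removes everything; scoring then errors per sample
  gone <- degrade_low_input(sim$expression, 1, 0, seed = 6)
  expect_true(all(is.na(gone)))
  m <- calibrate(panel, sim$expression, sim$labels)
  sc <- infer_activity(m, gone)
  expect_true(all(!is.na(sc$error)))
  expect_true(all(grepl("no evidence", sc$error)))
  expect_true(all(is.na(sc$score)))
  expect_error(infer_activity(m, gone[, 1]), class = "pathsig_no_evidence_error")

  # intermediate dropout removes the expected fraction
  part <- degrade_low_input(sim$expression, 0.3, 0.1, seed = 7)
  expect_equal(mean(is.na(part)), 0.3, tolerance = 0.1)
  expect_identical(part, degrade_low_input(sim$expression, 0.3, 0.1, seed = 7))
})

test_that("simulated Cq tables invert through delta-Cq normalization", {
  panel <- make_panel(4, reference_genes = c("REF1", "REF2"))
  sim <- simulate_cohort(panel, 5, 5, seed = 8)

  # zero noise: exact algebraic round trip (equal base Cq)
  cq0 <- simulate_cq(sim$expression, panel, ref_base_cq = 28,
                     target_base_cq = 28, sd_cq = 1e-12, seed = 9)
  x0 <- normalize_cq(cq0)
  expect_equal(x0[rownames(sim$expression), colnames(sim$expression)],
               sim$expression, tolerance = 1e-6, ignore_attr = TRUE)

  # the documented single-value example: expression 3 at target base 28
  one <- matrix(3, 1, 1, dimnames = list("G01", "s1"))
  two <- rbind(one, G02 = 0)
  cq1 <- simulate_cq(two, panel, ref_base_cq = 28, target_base_cq = 28,
                     sd_cq = 1e-12, seed = 1)
  expect_equal(unname(unclass(cq1)["G01", "s1"]), 25, tolerance = 1e-6)
  expect_equal(unname(normalize_cq(cq1)["G01", "s1"]), 3, tolerance = 1e-6)

  # realistic noise: recovered expression correlates >= 0.98 at n = 100
  sim2 <- simulate_cohort(panel, 50, 50, seed = 10)
  cq2 <- simulate_cq(sim2$expression, panel, sd_cq = 0.2, seed = 11)
  x2 <- normalize_cq(cq2)
  expect_gte(cor(as.vector(sim2$expression),
                 as.vector(x2[rownames(sim2$expression), ])), 0.98)

  # the diluted regime (reference Cq 32-35.5) still normalizes, with
  # missingness per the cq_max convention for weak targets
  lowx <- sim$expression - 8  # weak targets near the amplification limit
  cq3 <- simulate_cq(lowx, panel, ref_base_cq = 33, target_base_cq = 36,
                     sd_cq = 0.2, seed = 12)
  x3 <- normalize_cq(cq3, cq_max = 40)
  expect_true(any(is.na(x3)))
  expect_true(any(!is.na(x3)))

  expect_error(simulate_cq(sim$expression, make_panel(4), seed = 1),
               class = "pathsig_config_error")
})

test_that("model-consistent simulation recovers the generating parameters", {
  set.seed(97)
  panel <- make_panel(6)
  ph_up <- runif(6, 0.75, 0.92)
  gen <- pathway_model(panel, default_priors(panel),
                       emission_parameters(unlist(panel$probes),
                                           runif(6, 5, 8), ph_up, 1 - ph_up))
  sim <- simulate(gen, nsim = 500, seed = 98)
  refit <- calibrate(panel, sim$expression, sim$labels)
  expect_lt(max(abs(refit$emissions$p_high_given_up -
                    gen$emissions$p_high_given_up)), 0.05)
  expect_lt(max(abs(refit$emissions$threshold - gen$emissions$threshold)), 0.2)

  # stochastic latent states: label-conditional mixture, lower coupling
  sim2 <- simulate(gen, nsim = 500, seed = 99, latent = "stochastic")
  refit2 <- calibrate(panel, sim2$expression, sim2$labels)
  mix <- 0.95 * gen$emissions$p_high_given_up +
    0.05 * gen$emissions$p_high_given_down
  expect_lt(max(abs(refit2$emissions$p_high_given_up - mix)), 0.05)
})

test_that("conflicting genes degrade separation gracefully and monotonically", {
  panel <- make_panel(12)
  gap <- vapply(c(0, 0.2, 0.4), function(frac) {
    sim <- simulate_cohort(panel, 100, 100, frac_conflicting = frac, seed = 100)
    held <- simulate_cohort(panel, 100, 100, frac_conflicting = frac, seed = 101)
    m <- calibrate(panel, sim$expression, sim$labels)
    sc <- predict(m, held$expression)
    lab <- held$labels[sc$sample_id]
    mean(sc$score[lab == "active"]) - mean(sc$score[lab == "inactive"])
  }, 1)
  expect_true(all(diff(gap) < 0))  # separation shrinks with conflict
  expect_gt(gap[2], 0.5 * gap[1])  # but degrades gracefully at 20%
})
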