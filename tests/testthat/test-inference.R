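test_that("analytic anchors hold to machine precision", {
  m <- default_model(2)

  # single default gene read high: log2(0.86/0.14)
  expect_equal(gene_log2_lr("G01", 1, m), DEFAULT_LR, tolerance = 1e-15)
  expect_equal(gene_log2_lr("G01", NA, m), 0)

  # repressed gene read high: exact sign flip
  m_rep <- default_model(2, directions = c(1, -1))
  expect_equal(gene_log2_lr("G02", 1, m_rep), -DEFAULT_LR, tolerance = 1e-15)

  # both probes high: L = l_max, S = 100
  r <- infer_activity(m, c(G01 = 8, G02 = 8))
  expect_equal(r$log2_odds, m$l_max, tolerance = 1e-12)
  expect_equal(r$score, 100)

  # one high, one low: symmetric cancellation at the uniform prior
  r0 <- infer_activity(m, c(G01 = 8, G02 = 2))
  expect_equal(r0$log2_odds, 0, tolerance = 1e-12)
  expect_equal(r0$score, 50)

  # two symmetric opposing genes (one induced, one repressed, both high)
  r_op <- infer_activity(m_rep, c(G01 = 8, G02 = 8))
  expect_equal(r_op$log2_odds, 0, tolerance = 1e-12)
})

test_that("empty evidence returns the prior log2 odds exactly (oracle path)", {
  m <- default_model(3)
  r <- brute_force_infer(m, c(OTHER = 5))
  expect_identical(r$log2_odds, 0)
  expect_equal(r$n_missing_genes, 3L)

  pr <- pathway_priors(0.8, sprintf("G%02d", 1:3), 0.95, 0.05)
  m8 <- pathway_model(make_panel(3), pr, default_emissions(make_panel(3)))
  r8 <- brute_force_infer(m8, c(OTHER = 5))
  expect_equal(r8$log2_odds, log2(0.8 / 0.2), tolerance = 1e-15)

  # the factorized path refuses evidence-free samples instead
  expect_error(infer_activity(m, c(OTHER = 5)), "no evidence",
               class = "pathsig_no_evidence_error")
})

test_that("factorized inference matches joint enumeration on random models", {
  set.seed(61)
  for (trial in 1:60) {
    m <- random_model(n_genes = sample(2:8, 1), max_probes = 2)
    v <- random_values(m, p_missing = 0.25)
    if (all(is.na(v))) v[1] <- m$emissions$threshold[1] + 1
    expect_lt(abs(infer_activity(m, v)$log2_odds - brute_force_infer(m, v)$log2_odds),
              1e-9)
  }
})

test_that("brute force refuses panels above the enumeration limit", {
  m <- default_model(17)
  expect_error(brute_force_infer(m, c(G01 = 8)), class = "pathsig_size_error")
})

test_that("missing measurements are neutral evidence", {
  m <- default_model(3)
  r_full <- infer_activity(m, c(G01 = 8, G02 = 8, G03 = 2))
  r_miss <- infer_activity(m, c(G01 = 8, G02 = 8, G03 = NA))
  contrib <- attr(r_full, "contributions")

  # removing a gene changes L by exactly its contribution
  expect_equal(r_miss$log2_odds, r_full$log2_odds - contrib["G03", 1],
               tolerance = 1e-12)
  expect_equal(r_miss$n_missing_genes, 1L)

  # deleting a zero-contribution gene leaves L unchanged
  m_un <- pathway_model(make_panel(2), default_priors(make_panel(2)),
                        emission_parameters(c("G01", "G02"), 6.5,
                                            c(0.9, 0.5), c(0.1, 0.5)))
  r_a <- infer_activity(m_un, c(G01 = 8, G02 = 8))
  r_b <- infer_activity(m_un, c(G01 = 8, G02 = NA))
  expect_equal(r_a$log2_odds, r_b$log2_odds, tolerance = 1e-12)
})

test_that("batch scoring preserves order, collects errors, handles edge cases", {
  m <- default_model(2)
  x <- cbind(s1 = c(8, 8), s2 = c(2, 2), s3 = c(NA, NA))
  rownames(x) <- c("G01", "G02")
  sc <- infer_activity(m, x)
  expect_equal(sc$sample_id, c("s1", "s2", "s3"))
  expect_equal(sc$score[1], 100)
  expect_equal(sc$score[2], 0)
  expect_true(is.na(sc$score[3]))
  expect_match(sc$error[3], "no evidence")
  expect_true(all(is.na(sc$error[1:2])))

  # duplicated sample values give identical results
  x2 <- cbind(a = c(8, 2), b = c(8, 2))
  rownames(x2) <- c("G01", "G02")
  sc2 <- infer_activity(m, x2)
  expect_identical(sc2$score[1], sc2$score[2])
  expect_identical(sc2$log2_odds[1], sc2$log2_odds[2])

  # permutation invariance across columns
  x3 <- x[, c(2, 1, 3)]
  sc3 <- infer_activity(m, x3)
  expect_equal(sc3$score, sc$score[c(2, 1, 3)])

  # empty matrix: empty result, not an error
  sc0 <- infer_activity(m, x[, 0, drop = FALSE])
  expect_s3_class(sc0, "pathway_scores")
  expect_equal(nrow(sc0), 0)
})

test_that("scores stay in [0, 100] and sit at 50 for L = 0 and degenerate models", {
  set.seed(71)
  for (trial in 1:20) {
    m <- random_model(n_genes = sample(2:6, 1))
    sc <- infer_activity(m, random_values(m, p_missing = 0.3))
    if (is.na(sc$score)) next
    expect_gte(sc$score, 0)
    expect_lte(sc$score, 100)
  }
  # all-uninformative model: zero-width bounds map every sample to 50
  panel <- make_panel(2)
  m0 <- pathway_model(panel, default_priors(panel),
                      default_emissions(panel, p_high_up = 0.5, p_high_down = 0.5))
  expect_equal(infer_activity(m0, c(G01 = 8, G02 = 2))$score, 50)
})

test_that("flipping evidence toward activation never decreases the score", {
  set.seed(81)
  for (trial in 1:100) {
    m <- random_model(n_genes = sample(2:8, 1), max_probes = 2)
    em <- m$emissions
    v <- random_values(m, p_missing = 0.15)
    pp_dir <- setNames(rep(m$panel$genes$direction,
                           vapply(m$panel$probes[m$panel$genes$gene], length, 1L)),
                       em$probe)
    if (all(is.na(v))) v[1] <- em$threshold[1] - 1
    base <- infer_activity(m, v)
    # flip every flippable probe toward activation, one at a time
    for (p in em$probe) {
      t <- em$threshold[em$probe == p]
      cur <- v[p]
      toward_high <- pp_dir[p] == 1L
      flippable <- !is.na(cur) && ((toward_high && cur < t) || (!toward_high && cur >= t))
      if (!flippable) next
      v2 <- v
      v2[p] <- if (toward_high) t + 1 else t - 1
      flipped <- infer_activity(m, v2)
      expect_gte(flipped$log2_odds, base$log2_odds - 1e-12)
      expect_gte(flipped$score, base$score - 1e-12)
    }
  }
})

test_that("the FOXO-style inverse readout annotation is carried, never inverted", {
  panel <- gene_panel("FOXO", c("A", "B"), inverse_of = "PI3K")
  m <- pathway_model(panel, default_priors(panel),
                     emission_parameters(c("A", "B"), 6.5, 0.9, 0.1))
  r <- infer_activity(m, c(A = 8, B = 8))
  expect_equal(attr(r, "inverse_of"), "PI3K")
  expect_equal(r$score, 100)  # the measured FOXO score itself is unchanged
  expect_output(print(r), "PI3K")
})
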