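test_that("joint fit recovers true effects at large n", {
  panel <- make_test_panel(2)
  cfg <- simulation_config(panel, control_freqs = c(0.3, 0.5),
                           or_per_allele = c(2, 3),
                           target_prevalence = 0.2,
                           n_cases = 9000, n_controls = 9000)
  st <- simulate_cohort(cfg, seed = 21)
  m <- fit_joint_model(st, panel)
  ors <- m$coefficients$or
  expect_gt(ors[1], 1.9); expect_lt(ors[1], 2.1)
  expect_gt(ors[2], 2.85); expect_lt(ors[2], 3.15)
  expect_true(m$converged)
})

test_that("rank deficiency and separation are reported as fit errors", {
  panel <- make_test_panel(2)
  st <- simulate_from_group_freqs(c(0.6, 0.6), c(0.4, 0.4), 50, 50,
                                  seed = 4, panel = panel)
  dup <- as.data.frame(st)
  dup$snp2 <- dup$snp1
  dup_study <- case_control_study(dup, panel)
  expect_error(fit_joint_model(dup_study, panel), "rank deficient")
})

test_that("the GRS is affine with the fitted coefficients as increments", {
  sim <- default_sim_objects()
  m <- sim$model
  panel <- sim$config$panel
  base <- as.data.frame(sim$study)[1, ]
  scored <- compute_grs(m, base)
  # all-zero dosages score exactly the intercept
  zero <- base
  zero[panel$snp_id] <- 0L
  expect_equal(unname(compute_grs(m, zero)$grs), m$intercept)
  # +1 on any single dosage moves the score by exactly that SNP's beta
  for (id in panel$snp_id[c(1, 7, 13)]) {
    bump <- base
    bump[[id]] <- bump[[id]] + 1L
    expect_equal(unname(compute_grs(m, bump)$grs - scored$grs),
                 m$coefficients$beta[m$coefficients$snp_id == id])
  }
})

test_that("GRS arithmetic matches a hand-computed example", {
  panel <- make_test_panel(2)
  fake <- structure(
    list(intercept = 0,
         coefficients = tibble::tibble(
           snp_id = c("snp1", "snp2"), gene_label = c("GENE1", "GENE2"),
           locus_group = c("L1", "L2"), beta = c(log(2), log(3)),
           se = c(0.1, 0.1), or = c(2, 3), ci_low = c(1, 1),
           ci_high = c(4, 9), p_value = c(0.01, 0.01)),
         k = 2L),
    class = "grs_model"
  )
  d <- tibble::tibble(snp1 = 1L, snp2 = 2L)
  expect_equal(compute_grs(fake, d)$grs, 0.69315 + 2 * 1.09861, tolerance = 1e-5)
})

test_that("McFadden R2 equals an independent log-likelihood computation", {
  sim <- default_sim_objects()
  m <- sim$model
  st <- sim$study
  # direct computation from the scored probabilities
  y <- as.integer(st$status == "case")
  eta <- compute_grs(m, st)$grs
  ll <- sum(y * log(plogis(eta)) + (1 - y) * log(1 - plogis(eta)))
  p0 <- mean(y)
  ll0 <- sum(y) * log(p0) + sum(1 - y) * log(1 - p0)
  expect_equal(mcfadden_r2(m), 1 - ll / ll0, tolerance = 1e-10)
  expect_gt(mcfadden_r2(m), 0)
  expect_lt(mcfadden_r2(m), 1)
})

test_that("McFadden R2 is invariant to subject and SNP order", {
  sim <- default_sim_objects()
  panel <- sim$config$panel
  st <- sim$study
  shuffled <- as.data.frame(st)[rev(seq_len(nrow(st))), ]
  m1 <- fit_joint_model(case_control_study(shuffled, panel), panel)
  reordered_panel <- snp_panel(as.data.frame(panel)[c(13:1), ])
  m2 <- fit_joint_model(st, reordered_panel)
  expect_equal(mcfadden_r2(m1), mcfadden_r2(sim$model), tolerance = 1e-9)
  expect_equal(mcfadden_r2(m2), mcfadden_r2(sim$model), tolerance = 1e-9)
})

test_that("in-sample OR per GRS unit is exactly e; rescaling reparameterizes", {
  sim <- default_sim_objects()
  scored <- compute_grs(sim$model, sim$study)
  res <- or_per_grs_unit(scored)
  expect_equal(res$slope, 1, tolerance = 1e-6)
  expect_equal(res$or, exp(1), tolerance = 1e-4)
  halved <- scored
  halved$grs <- halved$grs / 2
  expect_equal(or_per_grs_unit(halved)$or, exp(2), tolerance = 1e-3)
  # out-of-sample scores on a fresh cohort: slope near 1 but attenuated
  # towards 0 by the estimation noise in the training weights
  fresh <- simulate_cohort(sim$config, seed = 314, alpha = sim$alpha)
  out <- or_per_grs_unit(compute_grs(sim$model, fresh))
  expect_gt(out$slope, 0.75)
  expect_lt(out$slope, 1.1)
})

test_that("Welch comparison matches closed-form arithmetic and flags", {
  same <- compare_grs_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  res <- compare_grs_groups(c(1, 2), c(3, 4), alpha = 0.05)
  expect_equal(res$t, -2.8284, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.105573, tolerance = 1e-4)
  expect_false(res$significant)
  expect_error(compare_grs_groups(c(1, 1), c(2, 3)), "Zero-variance")
})

test_that("a mean GRS shift of 0.4 is detected with high power at 0.05/3", {
  set.seed(23)
  hits <- vapply(1:500, function(i) {
    a <- rnorm(300, mean = 0.4, sd = 1.3)
    b <- rnorm(600, mean = 0.0, sd = 1.3)
    compare_grs_groups(a, b)$significant
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("model export round-trips and scores identically", {
  sim <- default_sim_objects()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_model_export(sim$model, sim$config$panel, f)
  wp <- read_model_export(f)
  expect_equal(attr(wp, "intercept"), sim$model$intercept, tolerance = 1e-12)
  s1 <- compute_grs(sim$model, sim$study)$grs
  s2 <- compute_grs(wp, sim$study)$grs
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("tidy and glance return broom-shaped summaries", {
  sim <- default_sim_objects()
  td <- generics::tidy(sim$model)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_equal(nrow(td), 13)
  gl <- generics::glance(sim$model)
  expect_equal(gl$k, 13)
  expect_equal(gl$mcfadden_r2, mcfadden_r2(sim$model))
})
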