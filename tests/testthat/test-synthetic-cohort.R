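test_that("intercept calibration matches closed forms and a brute-force grid", {
  # no genetic effect: alpha is the plain logit of the prevalence
  expect_equal(calibrate_intercept(0.5, 0, 0.1), qlogis(0.1), tolerance = 1e-8)
  expect_equal(calibrate_intercept(0.3, 0, 0.01), qlogis(0.01), tolerance = 1e-8)

  # one SNP, freq 0.5, beta = ln 2, prevalence 0.10: compare against a
  # dense grid search over the 3-term HWE enumeration
  target <- 0.10
  f_grid <- function(a) 0.25 * plogis(a) + 0.5 * plogis(a + log(2)) +
    0.25 * plogis(a + 2 * log(2))
  grid <- seq(-6, 0, by = 1e-6)
  a_grid <- grid[which.min(abs(f_grid(grid) - target))]
  a_pkg <- calibrate_intercept(0.5, log(2), target)
  expect_equal(a_pkg, a_grid, tolerance = 1e-5)
  expect_equal(f_grid(a_pkg), target, tolerance = 1e-10)
})

test_that("13-SNP calibration hits the target prevalence under Monte Carlo", {
  sim <- default_sim_objects()
  cfg <- sim$config
  n <- 4e5
  set.seed(31)
  g <- vapply(cfg$freqs, function(p) rbinom(n, 2, p), integer(n))
  prev_hat <- mean(plogis(sim$alpha + drop(g %*% cfg$betas)))
  se <- sqrt(0.15 * 0.85 / n)
  expect_lt(abs(prev_hat - cfg$target_prevalence), 4 * se)
})

test_that("simulation is deterministic given a seed and requires one", {
  cfg <- simulation_config(make_test_panel(3),
                           control_freqs = c(0.2, 0.5, 0.8),
                           or_per_allele = c(1.5, 2, 1),
                           target_prevalence = 0.2,
                           n_cases = 80, n_controls = 70)
  a <- calibrate_intercept(cfg)
  s1 <- simulate_cohort(cfg, seed = 11, alpha = a)
  s2 <- simulate_cohort(cfg, seed = 11, alpha = a)
  s3 <- simulate_cohort(cfg, seed = 12, alpha = a)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_false(identical(as.data.frame(s1), as.data.frame(s3)))
  expect_error(simulate_cohort(cfg), "seed")
  expect_equal(sum(s1$status == "case"), 80)
  expect_equal(sum(s1$status == "control"), 70)
})

test_that("null model gives equal case/control allele frequencies", {
  cfg <- simulation_config(make_test_panel(4),
                           control_freqs = c(0.1, 0.3, 0.5, 0.7),
                           or_per_allele = rep(1, 4),
                           target_prevalence = 0.3,
                           n_cases = 1500, n_controls = 1500)
  st <- simulate_cohort(cfg, seed = 5)
  for (j in seq_len(4)) {
    g <- st[[paste0("snp", j)]]
    f_ca <- mean(g[st$status == "case"]) / 2
    f_co <- mean(g[st$status == "control"]) / 2
    se <- sqrt(2 * cfg$freqs[j] * (1 - cfg$freqs[j]) / (2 * 1500))
    expect_lt(abs(f_ca - f_co), 3 * se * sqrt(2))
  }
})

test_that("expected case allele frequency enumeration is exact", {
  # a null SNP leaves the case frequency at the population value
  expect_equal(expected_case_allele_freq(0.37, 1, -2), 0.37)
  # rare-disease limit, strong risk allele
  # frozen from the 3-term enumeration: HWE weights (0.811^2, 2*0.811*0.189,
  # 0.189^2) times 3.13^g give (0.479764 + 0.349956) / 1.96723 / ... = 0.421776
  expect_equal(expected_case_allele_freq(0.189, 3.13, -Inf), 0.421776,
               tolerance = 1e-5)
  # monotone in the odds ratio, saturating towards 1
  ors <- c(1, 2, 5, 20, 1000)
  freqs <- vapply(ors, function(o) expected_case_allele_freq(0.5, o, -Inf),
                  numeric(1))
  expect_true(all(diff(freqs) > 0))
  expect_gt(freqs[length(freqs)], 0.99)
})

test_that("simulated case genotype frequencies match an exact enumeration oracle", {
  # 3-SNP disease model; oracle enumerates the full 27-cell genotype grid
  # independently of the package's convolution machinery
  panel <- make_test_panel(3)
  freqs <- c(0.365, 0.189, 0.6)
  ors <- c(2.74, 3.13, 1.5)
  cfg <- simulation_config(panel, control_freqs = freqs, or_per_allele = ors,
                           target_prevalence = 0.05,
                           n_cases = 2000, n_controls = 1000)
  alpha <- calibrate_intercept(cfg)
  st <- simulate_cohort(cfg, seed = 99, alpha = alpha)
  for (j in 1:3) {
    dist <- oracle_case_geno_dist(freqs, log(ors), alpha, j)
    expected_freq <- sum(0:2 * dist) / 2
    g <- st[[paste0("snp", j)]][st$status == "case"]
    se <- sqrt(expected_freq * (1 - expected_freq) / (2 * 2000))
    expect_lt(abs(mean(g) / 2 - expected_freq), 3.5 * se)
  }
})

test_that("control genotypes stay in HWE across replicate null simulations", {
  cfg <- simulation_config(make_test_panel(5),
                           control_freqs = c(0.1, 0.25, 0.4, 0.6, 0.9),
                           or_per_allele = rep(1, 5),
                           target_prevalence = 0.2,
                           n_cases = 50, n_controls = 400)
  alpha <- calibrate_intercept(cfg)
  ps <- unlist(lapply(1:30, function(s) {
    st <- simulate_cohort(cfg, seed = 1000 + s, alpha = alpha)
    vapply(paste0("snp", 1:5), function(id) {
      g <- st[[id]][st$status == "control"]
      hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    }, numeric(1))
  }))
  expect_gte(mean(ps > 0.001), 0.99)
})

test_that("group-frequency simulation reproduces its target frequencies", {
  st <- simulate_from_group_freqs(case_freqs = c(0.6, 0.3),
                                  control_freqs = c(0.365, 0.3),
                                  n_cases = 3000, n_controls = 3000, seed = 2)
  f_ca <- mean(st$snp1[st$status == "case"]) / 2
  expect_lt(abs(f_ca - 0.6), 3 * sqrt(0.6 * 0.4 / 6000))
  expect_error(
    simulate_from_group_freqs(0.5, 0.5, n_cases = 0, n_controls = 10, seed = 1),
    "positive"
  )
})

test_that("LD mode couples within-locus SNPs at the requested r2", {
  panel <- snp_panel(tibble::tibble(
    snp_id = c("a1", "a2"), gene_label = "G", locus_group = "L",
    risk_allele = "A", other_allele = "G",
    control_freq = c(0.4, 0.3), or_per_allele = c(1, 1),
    ld_r2_with_first = c(NA, 0.5)
  ))
  cfg <- simulation_config(panel, target_prevalence = 0.2,
                           n_cases = 100, n_controls = 4000, use_ld = TRUE)
  st <- simulate_cohort(cfg, seed = 8)
  r2_hat <- cor(st$a1, st$a2)^2
  expect_lt(abs(r2_hat - 0.5), 0.06)
})
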