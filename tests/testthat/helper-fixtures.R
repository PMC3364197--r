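# Shared fixtures and independent oracles for the test suite.

# small generic panel of k unlinked SNPs
make_test_panel <- function(k, prefix = "snp") {
  snp_panel(tibble::tibble(
    snp_id = paste0(prefix, seq_len(k)),
    gene_label = paste0("GENE", seq_len(k)),
    locus_group = paste0("L", seq_len(k)),
    risk_allele = "A",
    other_allele = "G"
  ))
}

# build a study from explicit genotype counts per class:
# counts are length-3 vectors over dosages 0,1,2
study_from_counts <- function(case_counts, control_counts, panel = make_test_panel(1)) {
  g <- c(rep(0:2, times = case_counts), rep(0:2, times = control_counts))
  status <- rep(c("case", "control"), c(sum(case_counts), sum(control_counts)))
  d <- tibble::tibble(
    subject_id = paste0("s", seq_along(g)),
    status = status
  )
  d[[panel$snp_id[1]]] <- g
  case_control_study(d, panel)
}

# default published-conditions cohort, simulated once and reused
default_sim_objects <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config()
      alpha <- calibrate_intercept(cfg)
      study <- simulate_cohort(cfg, seed = 20260901, alpha = alpha)
      model <- fit_joint_model(study, cfg$panel)
      cache <<- list(config = cfg, alpha = alpha, study = study, model = model)
    }
    cache
  }
})

hwe_dist_vec <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

# --- independent oracles -----------------------------------------------

# all-pairs concordance AUC (ties 0.5), quadratic loop
oracle_pairs_auc <- function(case_scores, control_scores) {
  tot <- 0
  for (x in case_scores) {
    tot <- tot + sum(x > control_scores) + 0.5 * sum(x == control_scores)
  }
  tot / (length(case_scores) * length(control_scores))
}

# HWE exact p via the conditioned multinomial route: P(table) under HWE with
# p = allele fraction, divided by the sum over tables with the same allele count
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nb <- 2 * n_bb + n_ab
  p <- nb / (2 * n)
  probs_of <- function(ab) {
    bb <- (nb - ab) / 2
    aa <- n - ab - bb
    stats::dmultinom(c(aa, ab, bb), prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }
  ab_all <- seq(nb %% 2, min(nb, 2 * n - nb), by = 2)
  pr <- vapply(ab_all, probs_of, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[ab_all == n_ab]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# conditional (noncentral hypergeometric) likelihood of a 2x2 table given
# margins, and the MLE of the odds ratio by direct likelihood scan
oracle_cmle_or <- function(a, b, c, d) {
  # table: rows (exposed, reference), cols (cases, controls)
  m1 <- a + b            # row 1 total
  n1 <- a + c            # cases column total
  n <- a + b + c + d
  lo <- max(0, n1 - (n - m1)); hi <- min(m1, n1)
  support <- lo:hi
  loglik <- function(logpsi) {
    lw <- lchoose(m1, support) + lchoose(n - m1, n1 - support) + support * logpsi
    lw_obs <- lchoose(m1, a) + lchoose(n - m1, n1 - a) + a * logpsi
    lw_obs - matrixStats_logsumexp(lw)
  }
  opt <- stats::optimize(function(lp) -loglik(lp), interval = c(-15, 15))
  exp(opt$minimum)
}

matrixStats_logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# exact case genotype distribution for one SNP embedded in a multi-SNP
# logistic disease model with independent HWE loci (direct enumeration,
# independent of the package's convolution code)
oracle_case_geno_dist <- function(freqs, betas, alpha, snp_index) {
  k <- length(freqs)
  grid <- as.matrix(expand.grid(rep(list(0:2), k)))
  hwe <- function(g, p) c((1 - p)^2, 2 * p * (1 - p), p^2)[g + 1]
  pg <- apply(grid, 1, function(g) prod(vapply(seq_len(k), function(j) hwe(g[j], freqs[j]), numeric(1))))
  pcase <- plogis(alpha + drop(grid %*% betas))
  joint <- pg * pcase
  dist <- vapply(0:2, function(v) sum(joint[grid[, snp_index] == v]), numeric(1))
  dist / sum(dist)
}
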