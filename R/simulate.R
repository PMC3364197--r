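#' Configure a synthetic case-control simulation
#'
#' The generator draws genotypes under Hardy-Weinberg equilibrium at given
#' population risk-allele frequencies, assigns disease through a logistic
#' model whose intercept is calibrated so the population prevalence hits a
#' target, and rejection-samples subjects until exact case/control counts
#' are reached — emulating a retrospective case-control design.
#'
#' Defaults are the published study conditions: the 13-SNP panel with its
#' control risk-allele frequencies as population frequencies, single-SNP
#' per-allele odds ratios as true effects, 986 cases / 796 controls, and a
#' target prevalence of 15% (late-stage AMD in the over-85 population).
#' Loci are independent by default; `use_ld = TRUE` couples each
#' non-anchor SNP to the first SNP of its locus group at the published
#' r-squared, with positive risk-allele phase.
#'
#' @param panel A [snp_panel()]; needs `control_freq` and `or_per_allele`
#'   columns unless `control_freqs`/`or_per_allele` are supplied.
#' @param control_freqs,or_per_allele Optional numeric overrides, one per
#'   panel SNP.
#' @param target_prevalence Population disease prevalence in (0,1).
#' @param n_cases,n_controls Target sample sizes.
#' @param use_ld Couple SNPs within a locus group (see Details).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(panel = amd_panel(),
                              control_freqs = NULL,
                              or_per_allele = NULL,
                              target_prevalence = 0.15,
                              n_cases = 986,
                              n_controls = 796,
                              use_ld = FALSE) {
  freqs <- control_freqs %||% panel$control_freq
  ors <- or_per_allele %||% panel$or_per_allele
  k <- nrow(panel)
  if (length(freqs) != k || length(ors) != k || anyNA(freqs) || anyNA(ors)) {
    abort("Need one frequency and one odds ratio per panel SNP.")
  }
  if (any(ors <= 0)) abort("Per-allele odds ratios must be positive.")
  nonnull <- ors != 1
  if (any(freqs[nonnull] <= 0 | freqs[nonnull] >= 1)) {
    abort("Frequencies must lie strictly in (0,1) for SNPs with an effect.")
  }
  if (any(freqs < 0 | freqs > 1)) abort("Frequencies must lie in [0,1].")
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    abort("target_prevalence must lie in (0,1).")
  }
  if (n_cases < 1 || n_controls < 1) {
    abort("n_cases and n_controls must be positive.")
  }
  structure(
    list(panel = panel, freqs = freqs, betas = log(ors),
         target_prevalence = target_prevalence,
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         use_ld = isTRUE(use_ld)),
    class = "sim_config"
  )
}

# Feasible positive-coupling disequilibrium D for target r^2 between two
# allele indicators with frequencies p1, p2.
ld_coupling_D <- function(p1, p2, r2) {
  D <- sqrt(max(r2, 0)) * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  D_max <- min(p1 * (1 - p2), p2 * (1 - p1))
  min(D, D_max)
}

# Per-locus haplotype model: list of loci, each with snp indices, haplotype
# allele matrix (haplotypes x snps) and haplotype probabilities. Non-anchor
# SNPs are conditionally independent given the anchor allele.
build_locus_models <- function(config) {
  panel <- config$panel
  freqs <- config$freqs
  groups <- split(seq_len(nrow(panel)), factor(panel$locus_group,
                                               levels = unique(panel$locus_group)))
  map(groups, function(ix) {
    m <- length(ix)
    if (!config$use_ld || m == 1) {
      # independent SNPs: haplotype alleles independent Bernoulli
      hap <- as.matrix(expand.grid(rep(list(0:1), m)))
      p <- apply(hap, 1, function(h) prod(ifelse(h == 1, freqs[ix], 1 - freqs[ix])))
      return(list(snps = ix, hap = hap, prob = p))
    }
    p1 <- freqs[ix[1]]
    r2 <- panel$ld_r2_with_first[ix[-1]]
    r2[is.na(r2)] <- 0
    hap <- as.matrix(expand.grid(rep(list(0:1), m)))
    p <- apply(hap, 1, function(h) {
      pr <- if (h[1] == 1) p1 else 1 - p1
      for (j in seq_along(r2)) {
        pj <- freqs[ix[1 + j]]
        D <- ld_coupling_D(p1, pj, r2[j])
        cond1 <- pj + D * (1 / p1)        # P(aj=1 | anchor=1)
        cond0 <- pj - D / (1 - p1)        # P(aj=1 | anchor=0)
        pc <- if (h[1] == 1) cond1 else cond0
        pc <- min(max(pc, 0), 1)
        pr <- pr * if (h[1 + j] == 1) pc else 1 - pc
      }
      pr
    })
    list(snps = ix, hap = hap, prob = p / sum(p))
  })
}

# Exact distribution of the genetic linear predictor sum(beta_i * g_i):
# per-locus genotype atoms (value, prob) from two independent haplotypes,
# convolved across independent loci.
linear_predictor_atoms <- function(config) {
  loci <- build_locus_models(config)
  betas <- config$betas
  locus_atoms <- map(loci, function(lc) {
    hb <- drop(lc$hap %*% betas[lc$snps])       # haplotype contribution
    v <- outer(hb, hb, `+`)
    p <- outer(lc$prob, lc$prob, `*`)
    val <- as.vector(v); pr <- as.vector(p)
    agg <- rowsum(pr, group = round(val, 12))
    tibble(value = as.numeric(rownames(agg)), prob = agg[, 1])
  })
  acc <- locus_atoms[[1]]
  for (la in locus_atoms[-1]) {
    v <- outer(acc$value, la$value, `+`)
    p <- outer(acc$prob, la$prob, `*`)
    acc <- tibble(value = as.vector(v), prob = as.vector(p))
  }
  acc
}

#' Calibrate the disease-model intercept to a target prevalence
#'
#' Finds the intercept `alpha` such that the population mean of
#' `plogis(alpha + sum(beta_i * g_i))`, with genotypes drawn under HWE at
#' the given frequencies (independent loci unless the config couples
#' them), equals `target_prevalence`. The genotype distribution of the
#' linear predictor is enumerated exactly by convolution across loci, and
#' the intercept is found by monotone root finding to within 1e-10 on the
#' prevalence scale.
#'
#' @param freqs Per-SNP population risk-allele frequencies, or a
#'   `sim_config` (in which case the other arguments are ignored).
#' @param betas Per-SNP log odds ratios.
#' @param target_prevalence Target population prevalence in (0,1).
#' @return The intercept, a single log-odds value.
#' @examples
#' calibrate_intercept(0.5, 0, 0.1)  # qlogis(0.1)
#' @export
calibrate_intercept <- function(freqs, betas = NULL, target_prevalence = NULL) {
  config <- if (inherits(freqs, "sim_config")) {
    freqs
  } else {
    k <- length(freqs)
    panel <- snp_panel(tibble(
      snp_id = paste0("snp", seq_len(k)),
      gene_label = paste0("G", seq_len(k)),
      locus_group = paste0("L", seq_len(k)),
      risk_allele = "A", other_allele = "B"
    ))
    simulation_config(panel, control_freqs = freqs,
                      or_per_allele = exp(betas),
                      target_prevalence = target_prevalence)
  }
  atoms <- linear_predictor_atoms(config)
  target <- config$target_prevalence
  f <- function(a) sum(atoms$prob * plogis(a + atoms$value)) - target
  lo <- -60; hi <- 60
  if (f(lo) > 0 || f(hi) < 0) abort("Intercept calibration failed: root not bracketable.")
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

draw_genotypes <- function(n, loci, k) {
  g <- matrix(0L, nrow = n, ncol = k)
  for (lc in loci) {
    nh <- length(lc$prob)
    h1 <- sample.int(nh, n, replace = TRUE, prob = lc$prob)
    h2 <- sample.int(nh, n, replace = TRUE, prob = lc$prob)
    g[, lc$snps] <- lc$hap[h1, , drop = FALSE] + lc$hap[h2, , drop = FALSE]
  }
  g
}

#' Simulate a retrospective case-control cohort
#'
#' Draws subjects from the calibrated population model and keeps sampling
#' until exactly `n_cases` cases and `n_controls` controls are collected
#' (surplus subjects of a completed class are discarded). Deterministic
#' given `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; required — no global RNG state is consumed.
#' @param max_batches Safety cap on sampling rounds before a simulation
#'   error is raised (prevents an unreachable target, e.g. near-zero
#'   prevalence with many cases requested, from looping forever).
#' @param alpha Optional precomputed intercept from
#'   [calibrate_intercept()]; avoids recalibrating when drawing many
#'   replicate cohorts from one config.
#' @return A `cc_study`.
#' @export
simulate_cohort <- function(config, seed, max_batches = 400, alpha = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) abort("simulate_cohort requires an explicit seed.")
  alpha <- alpha %||% calibrate_intercept(config)
  loci <- build_locus_models(config)
  k <- nrow(config$panel)
  prev <- config$target_prevalence
  batch <- ceiling(1.2 * max(config$n_cases / prev,
                             config$n_controls / (1 - prev)) / 4) + 100
  with_seed(seed, {
    cases <- matrix(integer(0), ncol = k)
    controls <- matrix(integer(0), ncol = k)
    b <- 0
    while ((nrow(cases) < config$n_cases || nrow(controls) < config$n_controls)) {
      b <- b + 1
      if (b > max_batches) {
        abort("Simulation error: case/control targets not reached within the sampling cap.")
      }
      g <- draw_genotypes(batch, loci, k)
      pr <- plogis(alpha + drop(g %*% config$betas))
      y <- rbinom(batch, 1, pr)
      if (nrow(cases) < config$n_cases) {
        cases <- rbind(cases, g[y == 1, , drop = FALSE])
      }
      if (nrow(controls) < config$n_controls) {
        controls <- rbind(controls, g[y == 0, , drop = FALSE])
      }
    }
    cases <- cases[seq_len(config$n_cases), , drop = FALSE]
    controls <- controls[seq_len(config$n_controls), , drop = FALSE]
    assemble_study(cases, controls, config$panel)
  })
}

assemble_study <- function(case_g, control_g, panel) {
  n_ca <- nrow(case_g); n_co <- nrow(control_g)
  dos <- rbind(case_g, control_g)
  colnames(dos) <- panel$snp_id
  case_control_study(
    bind_cols(
      tibble(
        subject_id = sprintf("S%05d", seq_len(n_ca + n_co)),
        status = rep(c("case", "control"), c(n_ca, n_co))
      ),
      as_tibble(dos)
    ),
    panel
  )
}

# run expr with a locally-seeded RNG, restoring any prior global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Expected risk-allele frequency among cases
#'
#' Analytic three-term enumeration: with genotype `g` in 0:2 drawn under
#' HWE at the population frequency, `P(g | case)` is proportional to
#' `HWE(g) * plogis(intercept + log(or) * g)`, and the case allele
#' frequency is `sum(g * P(g | case)) / 2`. With `intercept = -Inf` the
#' rare-disease limit `P(g | case) proportional to HWE(g) * or^g` is used.
#'
#' @param pop_freq Population risk-allele frequency.
#' @param or Per-allele odds ratio.
#' @param intercept Disease-model intercept (log-odds); `-Inf` gives the
#'   rare-disease limit.
#' @return Expected case risk-allele frequency.
#' @examples
#' expected_case_allele_freq(0.189, 3.13, -Inf)  # ~0.4217
#' @export
expected_case_allele_freq <- function(pop_freq, or, intercept = -Inf) {
  stopifnot(pop_freq >= 0, pop_freq <= 1, or > 0)
  g <- 0:2
  hwe <- c((1 - pop_freq)^2, 2 * pop_freq * (1 - pop_freq), pop_freq^2)
  lik <- if (is.infinite(intercept) && intercept < 0) {
    or^g
  } else {
    plogis(intercept + log(or) * g)
  }
  w <- hwe * lik
  sum(g * w / sum(w)) / 2
}

#' Simulate a cohort directly from group-specific allele frequencies
#'
#' Draws case and control genotypes independently per SNP under HWE at
#' the group-specific risk-allele frequency — the sampling model implied
#' by a published table of case and control allele frequencies. Useful
#' for checking empirical discrimination against enumeration oracles.
#'
#' @param case_freqs,control_freqs Per-SNP risk-allele frequencies.
#' @param n_cases,n_controls Positive sample sizes.
#' @param seed Integer seed.
#' @param panel Optional [snp_panel()] supplying SNP ids; a generic panel
#'   is built when omitted.
#' @return A `cc_study`.
#' @export
simulate_from_group_freqs <- function(case_freqs, control_freqs,
                                      n_cases, n_controls, seed,
                                      panel = NULL) {
  if (length(case_freqs) != length(control_freqs)) {
    abort("case_freqs and control_freqs must have equal length.")
  }
  if (any(c(case_freqs, control_freqs) < 0 | c(case_freqs, control_freqs) > 1)) {
    abort("Frequencies must lie in [0,1].")
  }
  if (n_cases < 1 || n_controls < 1) {
    abort("n_cases and n_controls must be positive.")
  }
  k <- length(case_freqs)
  if (is.null(panel)) {
    panel <- snp_panel(tibble(
      snp_id = paste0("snp", seq_len(k)),
      gene_label = paste0("G", seq_len(k)),
      locus_group = paste0("L", seq_len(k)),
      risk_allele = "A", other_allele = "B"
    ))
  }
  stopifnot(nrow(panel) == k)
  with_seed(seed, {
    case_g <- vapply(seq_len(k),
                     function(j) rbinom(n_cases, 2, case_freqs[j]),
                     integer(n_cases))
    control_g <- vapply(seq_len(k),
                        function(j) rbinom(n_controls, 2, control_freqs[j]),
                        integer(n_controls))
    assemble_study(matrix(case_g, nrow = n_cases),
                   matrix(control_g, nrow = n_controls), panel)
  })
}
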