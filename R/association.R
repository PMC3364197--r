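#' Single-SNP additive logistic association
#'
#' Fits `status ~ dosage` by maximum likelihood and reports the per-allele
#' odds ratio `exp(beta)`, its Wald 95% confidence interval
#' `exp(beta +/- 1.96 * SE)` and the two-sided Wald p-value. A
#' likelihood-ratio p-value is available via `p_method = "lrt"`; optional
#' age/sex adjustment supports sensitivity analyses, leaving the default
#' model unadjusted.
#'
#' @param study A `cc_study`.
#' @param snp_id One panel SNP id present in the study.
#' @param adjust Character vector of covariates to adjust for, a subset of
#'   `c("age_years", "sex")`; empty (default) for the unadjusted model.
#' @param p_method `"wald"` (default) or `"lrt"`.
#' @return A one-row tibble: `snp_id`, `or_per_allele`, `ci_low`,
#'   `ci_high`, `p_value`, `beta`, `se`.
#' @export
fit_single_snp <- function(study, snp_id, adjust = character(), p_method = "wald") {
  check_two_classes(study)
  if (!snp_id %in% snp_ids_of(study)) {
    abort(paste0("Unknown SNP id: ", snp_id))
  }
  g <- study[[snp_id]]
  if (length(unique(g)) < 2) {
    abort(paste0("Zero-variance dosage for ", snp_id, "; cannot fit."))
  }
  df <- tibble(y = as.integer(study$status == "case"), g = g)
  rhs <- "g"
  for (cv in adjust) {
    if (!cv %in% names(study)) abort(paste0("Covariate not in study: ", cv))
    df[[cv]] <- study[[cv]]
    rhs <- paste(rhs, "+", cv)
  }
  fit <- glm(stats::as.formula(paste("y ~", rhs)), data = df,
             family = binomial(), control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) abort(paste0("Logistic fit failed to converge for ", snp_id))
  beta <- coef(fit)[["g"]]
  se <- sqrt(vcov(fit)["g", "g"])
  if (abs(beta) > 15 || se > 100) {
    abort(paste0("Separation suspected for ", snp_id, " (|beta| or SE diverged)."))
  }
  p <- if (identical(p_method, "lrt")) {
    null_rhs <- if (length(adjust)) paste(adjust, collapse = " + ") else "1"
    fit0 <- glm(stats::as.formula(paste("y ~", null_rhs)), data = df,
                family = binomial())
    stats::pchisq(2 * (as.numeric(logLik(fit)) - as.numeric(logLik(fit0))),
                  df = 1, lower.tail = FALSE)
  } else {
    2 * pnorm(-abs(beta / se))
  }
  tibble(
    snp_id = snp_id,
    or_per_allele = exp(beta),
    ci_low = exp(beta - qnorm(0.975) * se),
    ci_high = exp(beta + qnorm(0.975) * se),
    p_value = p,
    beta = beta,
    se = se
  )
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test of HWE for a biallelic marker: given the allele
#' counts, the p-value is the sum of probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the
#' observed table (the standard SNP exact test). The conditional
#' distribution of the heterozygote count n_AB given n individuals and
#' n_A copies of the rarer allele is
#' `P(n_AB) = C(n, n_AB) C(n - n_AB, (n_A - n_AB)/2) 2^n_AB / C(2n, n_A)`
#' over n_AB with the parity of n_A.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)  # modal table: p = 1
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Genotype counts must be non-negative integers.")
  }
  n <- sum(counts)
  if (n < 1) abort("Total genotype count must be at least 1.")
  n_a <- 2 * n_hom_alt + n_het                  # copies of the alt allele
  n_minor <- min(n_a, 2 * n - n_a)
  hets <- seq(n_minor %% 2, n_minor, by = 2)    # feasible heterozygote counts
  # log conditional probabilities, normalized below
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_min + 1) - lgamma(hom_maj + 1) +
      h * log(2) +
      lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_het)
  if (length(obs) != 1) abort("Observed heterozygote count inconsistent with allele counts.")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Exact single-SNP AUC from genotype distributions
#'
#' The AUC of a single dosage as a classifier, enumerated exactly over the
#' 3x3 grid of case/control genotype pairs with ties credited 0.5 (the
#' Mann-Whitney convention):
#' `sum_{i,j} case(i) control(j) ([i > j] + 0.5 [i == j])`.
#'
#' @param case_dist,control_dist Probability 3-vectors over dosages 0,1,2.
#' @return The AUC in `[0, 1]`.
#' @examples
#' snp_auc_from_genotype_distributions(c(0, 0, 1), c(1, 0, 0))  # 1
#' @export
snp_auc_from_genotype_distributions <- function(case_dist, control_dist) {
  for (d in list(case_dist, control_dist)) {
    if (length(d) != 3 || any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      abort("Each distribution must be a non-negative 3-vector summing to 1.")
    }
  }
  cmp <- outer(0:2, 0:2, function(i, j) (i > j) + 0.5 * (i == j))
  as.numeric(case_dist %*% cmp %*% control_dist)
}

hwe_dist <- function(freq) c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)

# midrank (Mann-Whitney) AUC of a score against binary case status
midrank_auc <- function(scores, is_case) {
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) abort("AUC requires at least one case and one control.")
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-SNP association table
#'
#' One row per panel SNP: case/control risk-allele frequencies, additive
#' per-allele odds ratio with Wald 95% CI and p-value, empirical
#' single-SNP AUC (midrank ties), and the HWE exact-test p-value in
#' controls. HWE violations are reported, never used to drop a SNP. A SNP
#' whose fit fails (e.g. separation) yields a flagged row rather than an
#' error.
#'
#' @param study A `cc_study`.
#' @param panel A [snp_panel()].
#' @param subset Optional logical vector (length `nrow(study)`) or
#'   predicate function on the study rows selecting a sub-study, e.g.
#'   cases of one AMD subtype plus all controls. Must retain both classes.
#' @inheritParams fit_single_snp
#' @return A tibble with one row per SNP: `snp_id`, `gene_label`,
#'   `or_per_allele`, `ci_low`, `ci_high`, `p_value`, `freq_cases`,
#'   `freq_controls`, `auc`, `hwe_p_controls`, `fit_ok`.
#' @export
association_table <- function(study, panel, subset = NULL,
                              adjust = character(), p_method = "wald") {
  if (!is.null(subset)) {
    keep <- if (is.function(subset)) subset(study) else subset
    if (!is.logical(keep) || length(keep) != nrow(study)) {
      abort("subset must select rows of the study (logical of full length).")
    }
    study_df <- as_tibble(as.data.frame(study))[keep, , drop = FALSE]
    study <- case_control_study(study_df, panel)
  }
  check_two_classes(study)
  is_case <- study$status == "case"
  rows <- map(panel$snp_id, function(id) {
    g <- study[[id]]
    freq_ca <- mean(g[is_case]) / 2
    freq_co <- mean(g[!is_case]) / 2
    gco <- g[!is_case]
    hwe_p <- hwe_exact_test(sum(gco == 0), sum(gco == 1), sum(gco == 2))
    auc <- midrank_auc(g, is_case)
    fit <- tryCatch(fit_single_snp(study, id, adjust = adjust, p_method = p_method),
                    error = function(e) NULL)
    tibble(
      snp_id = id,
      or_per_allele = if (is.null(fit)) NA_real_ else fit$or_per_allele,
      ci_low = if (is.null(fit)) NA_real_ else fit$ci_low,
      ci_high = if (is.null(fit)) NA_real_ else fit$ci_high,
      p_value = if (is.null(fit)) NA_real_ else fit$p_value,
      freq_cases = freq_ca,
      freq_controls = freq_co,
      auc = auc,
      hwe_p_controls = hwe_p,
      fit_ok = !is.null(fit)
    )
  })
  out <- bind_rows(rows)
  meta <- as_tibble(as.data.frame(panel))[, c("snp_id", "gene_label", "locus_group")]
  left_join(meta, out, by = "snp_id")
}
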