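#' Fit the joint multi-SNP logistic risk model
#'
#' Maximum-likelihood logistic regression of case status on all panel
#' dosages at once. The fitted intercept `a` and per-SNP log odds ratios
#' `b_i` define the genetic risk score
#' `GRS = a + sum_i b_i x_i` with `x_i` the risk-allele dosage of SNP `i`;
#' the per-SNP odds ratio in the joint model is `exp(b_i)`.
#'
#' @param study A `cc_study` with both classes present.
#' @param panel A [snp_panel()]; its SNPs form the design matrix columns.
#' @return An object of class `grs_model`: list with `intercept`,
#'   `coefficients` (tibble: `snp_id`, `gene_label`, `locus_group`,
#'   `beta`, `se`, `or`, `ci_low`, `ci_high`, `p_value`), `k`,
#'   `log_lik`, `null_log_lik`, `n_cases`, `n_controls`, `iterations`,
#'   `converged`.
#' @export
fit_joint_model <- function(study, panel) {
  check_two_classes(study)
  X <- dosage_matrix(study)[, panel$snp_id, drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1L]
    abort(paste0("Design matrix is rank deficient; offending column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  y <- as.integer(study$status == "case")
  df <- bind_cols(tibble(.y = y), as_tibble(X))
  fit <- glm(.y ~ ., data = df, family = binomial(),
             control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) abort("Joint logistic fit failed to converge.")
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  betas <- cf[-1]
  if (any(abs(betas) > 15)) {
    abort(paste0("Separation suspected; diverging column(s): ",
                 paste(names(betas)[abs(betas) > 15], collapse = ", ")))
  }
  names(betas) <- colnames(X)
  se_b <- se[-1]
  coefs <- tibble(
    snp_id = panel$snp_id,
    gene_label = panel$gene_label,
    locus_group = panel$locus_group,
    beta = unname(betas[panel$snp_id]),
    se = unname(se_b)
  ) |>
    mutate(
      or = exp(.data$beta),
      ci_low = exp(.data$beta - qnorm(0.975) * .data$se),
      ci_high = exp(.data$beta + qnorm(0.975) * .data$se),
      p_value = 2 * pnorm(-abs(.data$beta / .data$se))
    )
  structure(
    list(
      intercept = unname(cf[1]),
      coefficients = coefs,
      k = ncol(X),
      log_lik = as.numeric(logLik(fit)),
      null_log_lik = null_binomial_loglik(y),
      n_cases = sum(y), n_controls = sum(1 - y),
      iterations = fit$iter, converged = fit$converged
    ),
    class = "grs_model"
  )
}

null_binomial_loglik <- function(y) {
  p <- mean(y)
  sum(y) * log(p) + sum(1 - y) * log(1 - p)
}

#' @export
print.grs_model <- function(x, ...) {
  cat(sprintf("<grs_model> %d SNPs, intercept a = %.4f (n = %d cases / %d controls)\n",
              x$k, x$intercept, x$n_cases, x$n_controls))
  print(x$coefficients)
  invisible(x)
}

#' @describeIn fit_joint_model Per-SNP coefficients as a tidy tibble
#'   (broom convention: `term`, `estimate` on the log-odds scale,
#'   `std.error`, `p.value`, plus `or`, `ci_low`, `ci_high`).
#' @param x A `grs_model`.
#' @param ... Unused.
#' @export
tidy.grs_model <- function(x, ...) {
  x$coefficients |>
    mutate(term = .data$snp_id, estimate = .data$beta,
           std.error = .data$se, p.value = .data$p_value) |>
    select("term", "estimate", "std.error", "p.value",
           "or", "ci_low", "ci_high", "gene_label", "locus_group")
}

#' @describeIn fit_joint_model One-row model summary: `k`, `intercept`,
#'   `log_lik`, `mcfadden_r2`, `n_cases`, `n_controls`, `converged`.
#' @export
glance.grs_model <- function(x, ...) {
  tibble(
    k = x$k,
    intercept = x$intercept,
    log_lik = x$log_lik,
    mcfadden_r2 = 1 - x$log_lik / x$null_log_lik,
    n_cases = x$n_cases,
    n_controls = x$n_controls,
    converged = x$converged
  )
}

model_betas <- function(model) {
  setNames(model$coefficients$beta, model$coefficients$snp_id)
}

#' Compute genetic risk scores
#'
#' `GRS = a + sum_i b_i x_i`: the model's fitted linear predictor (its
#' intercept is the centering constant; no further standardization is
#' applied). Affine and order-preserving in every dosage: raising one
#' dosage by 1 moves the score by exactly that SNP's `b_i`.
#'
#' @param model A `grs_model`, or a [snp_panel()] carrying `fixed_weight`
#'   values plus an `intercept` attribute for scoring without refitting.
#' @param data A `cc_study` or any data frame with the model's dosage
#'   columns.
#' @return The input data with a `grs` column appended, as a tibble.
#' @export
compute_grs <- function(model, data) {
  if (inherits(model, "grs_model")) {
    a <- model$intercept
    b <- model_betas(model)
  } else if (inherits(model, "snp_panel")) {
    if (anyNA(model$fixed_weight)) {
      abort("Panel has no complete fixed_weight column; fit a model or fill the weights.")
    }
    a <- attr(model, "intercept") %||% 0
    b <- setNames(model$fixed_weight, model$snp_id)
  } else {
    abort("model must be a grs_model or a weighted snp_panel.")
  }
  missing_cols <- setdiff(names(b), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Data lacks dosage column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(data)[, names(b), drop = FALSE])
  out <- as_tibble(as.data.frame(data))
  out$grs <- a + drop(X %*% b)
  out
}

#' McFadden pseudo R-squared
#'
#' `1 - lnL(model) / lnL(intercept-only)` for the fitted joint model on
#' its own study. Zero when the SNPs carry no information; approaches 1
#' as the model nears perfect separation. Invariant to subject order and
#' SNP column order.
#'
#' @param model A `grs_model`.
#' @return A single value in `[0, 1)`.
#' @export
mcfadden_r2 <- function(model) {
  stopifnot(inherits(model, "grs_model"))
  if (model$null_log_lik == 0) {
    abort("Null log-likelihood is zero (single-class data); R2 undefined.")
  }
  1 - model$log_lik / model$null_log_lik
}

#' Odds ratio per GRS unit
#'
#' Univariate logistic refit of case status on the score. When the scores
#' are the model's own in-sample linear predictor, the refitted slope is
#' exactly 1 (the joint fit's score equations are already satisfied), so
#' the OR per GRS unit equals `e` (2.718..., printed as 2.72).
#'
#' @param data A data frame with `status` and a score column.
#' @param score Name of the score column (default `"grs"`).
#' @return One-row tibble: `or`, `ci_low`, `ci_high`, `slope`, `se`.
#' @export
or_per_grs_unit <- function(data, score = "grs") {
  if (!score %in% names(data)) abort(paste0("No score column '", score, "'."))
  s <- data[[score]]
  if (length(unique(s)) < 2) abort("Scores are constant; cannot fit.")
  y <- as.integer(data$status == "case")
  fit <- glm(y ~ s, family = binomial(),
             control = list(epsilon = 1e-12, maxit = 100))
  slope <- coef(fit)[["s"]]
  se <- sqrt(vcov(fit)["s", "s"])
  tibble(
    or = exp(slope),
    ci_low = exp(slope - qnorm(0.975) * se),
    ci_high = exp(slope + qnorm(0.975) * se),
    slope = slope,
    se = se
  )
}

#' Compare mean GRS between two groups
#'
#' Welch two-sample t-test (the unequal-variance default; set
#' `pooled = TRUE` for the classical equal-variance test) with
#' normal-approximation 95% CIs for each group mean. When used for the
#' three planned subgroup contrasts (age bands, sex, AMD subtype), the
#' Bonferroni-adjusted level 0.05/3 applies; pass `alpha = 0.05/3` to set
#' the significance flag accordingly.
#'
#' @param scores_a,scores_b Numeric score vectors (each length >= 2,
#'   nonzero variance).
#' @param alpha Significance level for the `significant` flag.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return One-row tibble: group means with CIs, `t`, `df`, `p_value`,
#'   `significant`.
#' @export
compare_grs_groups <- function(scores_a, scores_b, alpha = 0.05 / 3,
                               pooled = FALSE) {
  for (s in list(scores_a, scores_b)) {
    if (length(s) < 2) abort("Each group needs at least 2 observations.")
    if (stats::var(s) == 0) abort("Zero-variance group; t-test undefined.")
  }
  tt <- t.test(scores_a, scores_b, var.equal = pooled)
  ci <- function(s) {
    m <- mean(s); half <- qnorm(0.975) * stats::sd(s) / sqrt(length(s))
    c(m - half, m + half)
  }
  ca <- ci(scores_a); cb <- ci(scores_b)
  tibble(
    mean_a = mean(scores_a), ci_low_a = ca[1], ci_high_a = ca[2],
    mean_b = mean(scores_b), ci_low_b = cb[1], ci_high_b = cb[2],
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < alpha
  )
}

#' Export / import a fitted risk model as a weighted panel file
#'
#' Writes a plain-text TSV carrying the intercept and per-SNP log-odds
#' weights so a new cohort can be scored on the training scale without
#' refitting; `read_model_export()` restores a weighted [snp_panel()]
#' (with the intercept as an attribute) accepted by [compute_grs()].
#'
#' @param model A `grs_model`.
#' @param panel The [snp_panel()] the model was fitted on.
#' @param path Output TSV path.
#' @return `path` invisibly; for the reader, a weighted `snp_panel`.
#' @export
write_model_export <- function(model, panel, path) {
  out <- as_tibble(as.data.frame(panel))[, c("snp_id", "gene_label", "locus_group",
                                             "risk_allele", "other_allele")]
  out$fixed_weight <- model_betas(model)[out$snp_id]
  header <- sprintf("# grs_model_export\tintercept=%.15g\tk=%d", model$intercept, model$k)
  writeLines(header, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_model_export
#' @export
read_model_export <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# grs_model_export", header)) {
    abort(paste0("Not a model export file: ", path))
  }
  intercept <- as.numeric(sub(".*intercept=([-0-9.eE+]+).*", "\\1", header))
  tab <- readr::read_tsv(path, skip = 1, show_col_types = FALSE, progress = FALSE)
  panel <- snp_panel(tab)
  attr(panel, "intercept") <- intercept
  panel
}
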