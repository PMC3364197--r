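#' ROC AUC of a score
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a
#' random case outscores a random control, ties credited 0.5. Equals the
#' trapezoidal area under the empirical ROC curve and is invariant under
#' any strictly increasing transform of the scores.
#'
#' @param data A data frame with `status` and a score column, or a
#'   numeric score vector (then `status` must be given).
#' @param score Name of the score column.
#' @param status Case/control flags when `data` is a bare vector.
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(data, score = "grs", status = NULL) {
  if (is.numeric(data) && is.null(dim(data))) {
    s <- data
    st <- status
  } else {
    s <- data[[score]]
    if (is.null(s)) abort(paste0("No score column '", score, "'."))
    st <- data$status
  }
  midrank_auc(s, st == "case")
}

#' Repeated random-subsampling cross-validation of the GRS model
#'
#' Each repeat assigns a random `train_fraction` of subjects to model
#' building (refitting the joint logistic model from scratch) and the
#' remainder to testing, where the test AUC of the training-model GRS is
#' computed. Splits are simple random subsamples; set
#' `stratified = TRUE` to sample cases and controls separately. The mean
#' test AUC estimates out-of-sample discrimination free of the in-sample
#' optimism from estimating the weights on the scored data.
#'
#' @param study A `cc_study`.
#' @param panel A [snp_panel()].
#' @param n_repeats Number of random splits (published analysis: 2000).
#' @param train_fraction Fraction assigned to training (default 2/3).
#' @param seed Integer seed; the per-repeat AUC sequence is reproducible
#'   bit for bit.
#' @param stratified Sample within status classes.
#' @param ci_method `"normal"` (mean +/- 1.96 SD/sqrt(R), default) or
#'   `"percentile"`.
#' @return A `grs_cv` object: list with `repeats` (tibble of per-repeat
#'   test AUCs), `mean_auc`, `ci_low`, `ci_high`, `n_skipped`, `seed`.
#' @export
cross_validate <- function(study, panel, n_repeats = 2000,
                           train_fraction = 2 / 3, seed,
                           stratified = FALSE, ci_method = "normal") {
  check_two_classes(study)
  if (missing(seed)) abort("cross_validate requires an explicit seed.")
  n <- nrow(study)
  n_train <- round(train_fraction * n)
  if (n_train < 2 || n_train >= n) abort("train_fraction leaves an unusable split.")
  is_case <- study$status == "case"
  aucs <- with_seed(seed, {
    vapply(seq_len(n_repeats), function(r) {
      train_idx <- if (stratified) {
        c(sample(which(is_case), round(train_fraction * sum(is_case))),
          sample(which(!is_case), round(train_fraction * sum(!is_case))))
      } else {
        sample.int(n, n_train)
      }
      test_idx <- setdiff(seq_len(n), train_idx)
      tr <- as_tibble(as.data.frame(study))[train_idx, , drop = FALSE]
      te <- as_tibble(as.data.frame(study))[test_idx, , drop = FALSE]
      if (length(unique(tr$status)) < 2 || length(unique(te$status)) < 2) {
        return(NA_real_)
      }
      fit <- tryCatch(
        fit_joint_model(case_control_study(tr, panel), panel),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NA_real_)
      roc_auc(compute_grs(fit, te))
    }, numeric(1))
  })
  n_skipped <- sum(is.na(aucs))
  if (n_skipped > 0.05 * n_repeats) {
    abort(sprintf("Cross-validation failed: %d of %d repeats unfittable.",
                  n_skipped, n_repeats))
  }
  ok <- aucs[!is.na(aucs)]
  m <- mean(ok)
  ci <- if (identical(ci_method, "percentile")) {
    unname(stats::quantile(ok, c(0.025, 0.975)))
  } else {
    m + c(-1, 1) * qnorm(0.975) * stats::sd(ok) / sqrt(length(ok))
  }
  structure(
    list(
      repeats = tibble(repeat_id = seq_len(n_repeats), test_auc = aucs),
      mean_auc = m, ci_low = ci[1], ci_high = ci[2],
      n_repeats = n_repeats, n_skipped = n_skipped,
      train_fraction = train_fraction, seed = seed
    ),
    class = "grs_cv"
  )
}

#' @export
print.grs_cv <- function(x, ...) {
  cat(sprintf("<grs_cv> %d repeats (train %.2f): mean test AUC %.4f (95%% CI %.4f-%.4f)\n",
              x$n_repeats, x$train_fraction, x$mean_auc, x$ci_low, x$ci_high))
  invisible(x)
}

#' @describeIn cross_validate Per-repeat test AUCs as a tibble.
#' @param x A `grs_cv`.
#' @param ... Unused.
#' @export
tidy.grs_cv <- function(x, ...) x$repeats

#' @describeIn cross_validate One-row summary of the CV run.
#' @export
glance.grs_cv <- function(x, ...) {
  tibble(mean_auc = x$mean_auc, ci_low = x$ci_low, ci_high = x$ci_high,
         n_repeats = x$n_repeats, n_skipped = x$n_skipped,
         train_fraction = x$train_fraction, seed = x$seed)
}

locus_auc <- function(study, panel, locus) {
  sub_panel <- snp_panel(as_tibble(as.data.frame(panel))[panel$locus_group == locus, ])
  fit <- fit_joint_model(study, sub_panel)
  roc_auc(compute_grs(fit, study))
}

#' Backward parsimonious model search over locus groups
#'
#' Ranks locus groups by their single-locus discriminative ability
#' (in-sample AUC of a model restricted to that locus) and greedily
#' removes the weakest locus first, refitting the joint model and
#' recording its AUC and McFadden R-squared at every step — the
#' trajectory from the full model down to a single locus. The smallest
#' model whose AUC stays within `tol` of the full model is flagged.
#' An exhaustive leave-one-locus-out comparison at the full model is
#' returned alongside, since strict greedy order need not be the only
#' defensible path.
#'
#' @param study A `cc_study`.
#' @param panel A [snp_panel()] with at least two locus groups.
#' @param tol AUC tolerance for flagging the parsimonious model
#'   (default 0.001).
#' @return A list of class `grs_parsimonious`: `trajectory` (tibble:
#'   `step`, `removed_locus`, `n_snps`, `auc`, `mcfadden_r2`,
#'   `within_tol`), `drop_one` (tibble of full-model leave-one-out AUCs),
#'   `locus_rank`, and `parsimonious` (row index of the flagged model).
#' @export
parsimonious_search <- function(study, panel, tol = 0.001) {
  loci <- unique(panel$locus_group)
  if (length(loci) < 2) abort("Need at least two locus groups.")
  single_auc <- vapply(loci, function(l) locus_auc(study, panel, l), numeric(1))
  order_weakest <- loci[order(single_auc)]
  fit_subset <- function(keep_loci) {
    sub <- snp_panel(as_tibble(as.data.frame(panel))[panel$locus_group %in% keep_loci, ])
    fit <- fit_joint_model(study, sub)
    tibble(n_snps = nrow(sub), auc = roc_auc(compute_grs(fit, study)),
           mcfadden_r2 = mcfadden_r2(fit))
  }
  keep <- loci
  steps <- list(bind_cols(tibble(step = 0L, removed_locus = NA_character_),
                          fit_subset(keep)))
  for (i in seq_len(length(loci) - 1)) {
    drop_locus <- order_weakest[i]
    keep <- setdiff(keep, drop_locus)
    row <- tryCatch(fit_subset(keep), error = function(e) NULL)
    if (is.null(row)) break
    steps[[length(steps) + 1]] <- bind_cols(
      tibble(step = i, removed_locus = drop_locus), row)
  }
  trajectory <- bind_rows(steps)
  full_auc <- trajectory$auc[1]
  trajectory$within_tol <- trajectory$auc >= full_auc - tol
  drop_one <- bind_rows(map(loci, function(l) {
    row <- tryCatch(fit_subset(setdiff(loci, l)), error = function(e) NULL)
    if (is.null(row)) return(tibble(removed_locus = l, n_snps = NA_integer_,
                                    auc = NA_real_, mcfadden_r2 = NA_real_))
    bind_cols(tibble(removed_locus = l), row)
  }))
  structure(
    list(
      trajectory = trajectory,
      drop_one = drop_one,
      locus_rank = tibble(locus_group = loci, single_locus_auc = single_auc)[
        order(single_auc), ],
      parsimonious = max(which(trajectory$within_tol))
    ),
    class = "grs_parsimonious"
  )
}

#' @export
print.grs_parsimonious <- function(x, ...) {
  cat("<grs_parsimonious> backward elimination trajectory:\n")
  print(x$trajectory)
  invisible(x)
}
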