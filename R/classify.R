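#' Equal-width GRS risk categories
#'
#' Splits the observed GRS range into `k` equal-width intervals. With
#' `w = (max - min) / k`, the interior cut points are `min + w * (1..k-1)`
#' and assignment is right-closed (`]a, b]`): a score exactly at a cut
#' point falls in the lower category; scores at or below the first cut
#' point are category 1, above the last cut point category `k`.
#'
#' @param data A data frame with a score column (e.g. output of
#'   [compute_grs()]).
#' @param k Number of categories (default 5).
#' @param score Name of the score column.
#' @return A `grs_classification`: list with `boundaries` (the `k - 1`
#'   interior cut points), `k`, and `observed_range`.
#' @export
grs_categories <- function(data, k = 5, score = "grs") {
  s <- data[[score]]
  if (is.null(s)) abort(paste0("No score column '", score, "'."))
  if (k < 2) abort("k must be at least 2.")
  rng <- range(s)
  if (diff(rng) == 0) abort("Scores are constant; categories undefined.")
  w <- diff(rng) / k
  structure(
    list(boundaries = rng[1] + w * seq_len(k - 1), k = as.integer(k),
         observed_range = rng),
    class = "grs_classification"
  )
}

#' @export
print.grs_classification <- function(x, ...) {
  cat(sprintf("<grs_classification> %d right-closed equal-width categories over [%.3f, %.3f]\n",
              x$k, x$observed_range[1], x$observed_range[2]))
  cat("cut points:", paste(sprintf("%.3f", x$boundaries), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname grs_categories
#' @param classification A `grs_classification` (or a numeric vector of
#'   ascending cut points).
#' @return For `assign_grs_category()`: the data with an integer
#'   `category` column appended.
#' @export
assign_grs_category <- function(data, classification, score = "grs") {
  cuts <- if (inherits(classification, "grs_classification")) {
    classification$boundaries
  } else {
    as.numeric(classification)
  }
  if (is.unsorted(cuts, strictly = TRUE)) abort("Cut points must be strictly increasing.")
  s <- data[[score]]
  if (is.null(s)) abort(paste0("No score column '", score, "'."))
  out <- as_tibble(as.data.frame(data))
  # right-closed: category = 1 + number of cut points strictly below the score
  out$category <- as.integer(rowSums(outer(s, cuts, `>`)) + 1L)
  out
}

#' Per-category case/control composition
#'
#' Counts and within-group percentages per risk category: cases as a
#' percentage of all cases and controls as a percentage of all controls.
#' An optional age split adds the same case percentages within the
#' younger/older strata.
#'
#' @param data A data frame with `status` and `category` columns (see
#'   [assign_grs_category()]).
#' @param k Number of categories; defaults to the highest observed label
#'   so that empty categories still appear when `k` is given.
#' @param age_split Optional age threshold (years); adds
#'   `pct_cases_younger` / `pct_cases_older` columns computed among cases
#'   below / at-or-above the threshold (requires an `age_years` column).
#' @return A tibble of class `grs_category_table`: `category`, `n_cases`,
#'   `n_controls`, `n_total`, `pct_cases`, `pct_controls`.
#' @export
category_table <- function(data, k = NULL, age_split = NULL) {
  if (!all(c("status", "category") %in% names(data))) {
    abort("Data needs 'status' and 'category' columns.")
  }
  k <- k %||% max(data$category)
  cats <- seq_len(k)
  n_ca <- vapply(cats, function(g) sum(data$status == "case" & data$category == g), numeric(1))
  n_co <- vapply(cats, function(g) sum(data$status == "control" & data$category == g), numeric(1))
  out <- tibble(
    category = cats,
    n_cases = n_ca,
    n_controls = n_co,
    n_total = n_ca + n_co,
    pct_cases = 100 * n_ca / sum(n_ca),
    pct_controls = 100 * n_co / sum(n_co)
  )
  if (!is.null(age_split)) {
    if (!"age_years" %in% names(data)) abort("age_split requires an 'age_years' column.")
    young <- data$status == "case" & data$age_years < age_split
    old <- data$status == "case" & data$age_years >= age_split
    out$pct_cases_younger <- vapply(cats, function(g) {
      100 * sum(young & data$category == g) / max(sum(young), 1)
    }, numeric(1))
    out$pct_cases_older <- vapply(cats, function(g) {
      100 * sum(old & data$category == g) / max(sum(old), 1)
    }, numeric(1))
  }
  class(out) <- c("grs_category_table", class(out))
  out
}

#' Build a category table from per-category counts
#'
#' @param n_cases,n_controls Per-category counts (parallel vectors).
#' @return A `grs_category_table` tibble.
#' @export
category_table_from_counts <- function(n_cases, n_controls) {
  stopifnot(length(n_cases) == length(n_controls))
  out <- tibble(
    category = seq_along(n_cases),
    n_cases = as.numeric(n_cases),
    n_controls = as.numeric(n_controls),
    n_total = as.numeric(n_cases + n_controls),
    pct_cases = 100 * n_cases / sum(n_cases),
    pct_controls = 100 * n_controls / sum(n_controls)
  )
  class(out) <- c("grs_category_table", class(out))
  out
}

#' Reconstruct category counts from published percentages
#'
#' Published five-category tables often print only within-group
#' percentages; integer counts are recovered as
#' `round(pct / 100 * margin)` against the case and control margins.
#' Set `integer_counts = FALSE` to keep the fractional counts
#' `pct / 100 * margin` instead (the two conventions differ in rounding
#' only, but published derived values are not all reproducible under a
#' single one).
#'
#' @param pct_cases,pct_controls Per-category percentages (summing to
#'   ~100 each).
#' @param n_cases,n_controls Group margins.
#' @param integer_counts Round the recovered counts (default TRUE).
#' @return A `grs_category_table` tibble.
#' @export
reconstruct_category_counts <- function(pct_cases, pct_controls,
                                        n_cases = 986, n_controls = 796,
                                        integer_counts = TRUE) {
  ca <- pct_cases / 100 * n_cases
  co <- pct_controls / 100 * n_controls
  if (integer_counts) {
    ca <- round(ca); co <- round(co)
  }
  out <- category_table_from_counts(ca, co)
  # rounding can shift the count sums off the true margins; keep the true
  # margins so prevalence reweighting uses the study's actual sample sizes
  attr(out, "margins") <- c(n_cases, n_controls)
  out
}

#' Published five-category AMD reference classification
#'
#' The published study's five equal-width GRS categories: interval cut
#' points (-1.79, -0.05, 1.70, 3.44) on the GRS scale and the printed
#' within-group percentages of its 986 cases and 796 controls, returned
#' as integer counts reconstructed per [reconstruct_category_counts()].
#'
#' @param integer_counts Passed to [reconstruct_category_counts()].
#' @return A `grs_category_table` with an extra `boundaries` attribute.
#' @export
amd_reference_categories <- function(integer_counts = TRUE) {
  tab <- reconstruct_category_counts(
    pct_cases = c(0.81, 9.00, 42.5, 39.7, 7.92),
    pct_controls = c(6.99, 41.7, 43.6, 7.50, 0.13),
    n_cases = 986, n_controls = 796,
    integer_counts = integer_counts
  )
  attr(tab, "boundaries") <- c(-1.79, -0.05, 1.70, 3.44)
  tab
}

#' Category odds ratios with exact conditional inference
#'
#' For each category versus the reference (default: the middle category
#' 3), forms the 2x2 table of cases/controls and reports the conditional
#' maximum-likelihood odds ratio with the exact conditional 95% CI
#' (noncentral hypergeometric inference, as in [stats::fisher.test()]).
#' Exact inference keeps sparse cells — e.g. a single control in the top
#' category — honest without continuity corrections. A category empty of
#' both cases and controls yields an `NA` row.
#'
#' @param table A `grs_category_table`.
#' @param reference Reference category index (default 3).
#' @return A tibble: `category`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `reference` (logical).
#' @export
category_odds_ratios <- function(table, reference = 3) {
  if (!reference %in% table$category) abort("Reference category not in table.")
  ref <- table[table$category == reference, ]
  if (ref$n_cases < 1 || ref$n_controls < 1) {
    abort("Reference category needs at least one case and one control.")
  }
  rows <- map(seq_len(nrow(table)), function(i) {
    g <- table$category[i]
    if (g == reference) {
      return(tibble(category = g, or = 1, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_, reference = TRUE))
    }
    ca <- table$n_cases[i]; co <- table$n_controls[i]
    if (ca + co == 0) {
      return(tibble(category = g, or = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_, reference = FALSE))
    }
    m <- matrix(round(c(ca, co, ref$n_cases, ref$n_controls)), nrow = 2,
                byrow = TRUE)
    ft <- fisher.test(m)
    tibble(category = g, or = unname(ft$estimate),
           ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
           p_value = ft$p.value, reference = FALSE)
  })
  bind_rows(rows)
}

#' Screening sensitivity and specificity for a positive-category rule
#'
#' Treating membership of the positive categories as a positive test:
#' sensitivity is the fraction of cases in the positive set, specificity
#' the fraction of controls outside it; 95% CIs are Clopper-Pearson
#' exact.
#'
#' @param table A `grs_category_table`.
#' @param positive_categories Non-empty proper subset of the category
#'   indices.
#' @return One-row tibble: `sensitivity`, `specificity` (percent) with
#'   exact CI bounds (percent).
#' @export
screening_metrics <- function(table, positive_categories) {
  if (length(positive_categories) == 0 ||
      !all(positive_categories %in% table$category) ||
      length(setdiff(table$category, positive_categories)) == 0) {
    abort("positive_categories must be a non-empty proper subset of the categories.")
  }
  pos <- table$category %in% positive_categories
  tp <- sum(table$n_cases[pos]); fn <- sum(table$n_cases[!pos])
  tn <- sum(table$n_controls[!pos]); fp <- sum(table$n_controls[pos])
  sens_ci <- binom.test(round(tp), round(tp + fn))$conf.int
  spec_ci <- binom.test(round(tn), round(tn + fp))$conf.int
  tibble(
    sensitivity = 100 * tp / (tp + fn),
    sens_ci_low = 100 * sens_ci[1], sens_ci_high = 100 * sens_ci[2],
    specificity = 100 * tn / (tn + fp),
    spec_ci_low = 100 * spec_ci[1], spec_ci_high = 100 * spec_ci[2]
  )
}
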