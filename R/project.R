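#' Case weight for prevalence-standardized projection
#'
#' A case-control sample over-represents cases; scaling each case count by
#' `w = (prevalence / (1 - prevalence)) * (n_controls / n_cases)` makes
#' the weighted case fraction equal the assumed population prevalence
#' exactly: `w * n_cases / (w * n_cases + n_controls) = prevalence`.
#'
#' @param prevalence Assumed population disease prevalence in (0,1).
#' @param n_cases,n_controls Study margins.
#' @return The positive case weight.
#' @examples
#' case_weight(0.5, 100, 100)  # 1
#' @export
case_weight <- function(prevalence, n_cases, n_controls) {
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must lie in (0,1).")
  if (n_cases <= 0 || n_controls <= 0) abort("Margins must be positive.")
  prevalence / (1 - prevalence) * n_controls / n_cases
}

#' Default prevalence schedule by age band
#'
#' Published late-stage AMD prevalences by age group: 1% (65-69 y),
#' 2.5% (70-74 y), 5% (75-79 y), 10% (80-84 y), 15% (>85 y).
#'
#' @return A tibble: `age_band`, `prevalence`.
#' @export
amd_prevalence_schedule <- function() {
  tibble(
    age_band = c("65-69", "70-74", "75-79", "80-84", ">85"),
    prevalence = c(0.01, 0.025, 0.05, 0.10, 0.15)
  )
}

#' Absolute disease risk per category in a modelled population
#'
#' With the case weight `w` of [case_weight()], the absolute risk in
#' category `g` is `w * cases_g / (w * cases_g + controls_g)` — the
#' fraction diseased among modelled-population members of that category.
#'
#' @param table A `grs_category_table`.
#' @param prevalence Assumed population prevalence in (0,1).
#' @return A tibble: `category`, `prevalence`, `weight`,
#'   `absolute_risk` (fraction; `NA` for an empty category) and
#'   `absolute_risk_pct`.
#' @export
absolute_risk_by_category <- function(table, prevalence) {
  m <- table_margins(table)
  w <- case_weight(prevalence, m[1], m[2])
  risk <- ifelse(table$n_total == 0, NA_real_,
                 w * table$n_cases / (w * table$n_cases + table$n_controls))
  tibble(
    category = table$category,
    prevalence = prevalence,
    weight = w,
    absolute_risk = risk,
    absolute_risk_pct = 100 * risk
  )
}

#' Modelled population fraction per category
#'
#' The share of the prevalence-reweighted population falling in each
#' category: `(w * cases_g + controls_g) / (w * N_cases + N_controls)`.
#' Fractions sum to one.
#'
#' @inheritParams absolute_risk_by_category
#' @return A tibble: `category`, `prevalence`, `population_fraction`,
#'   `population_pct`.
#' @export
modeled_population_fractions <- function(table, prevalence) {
  m <- table_margins(table)
  w <- case_weight(prevalence, m[1], m[2])
  denom <- w * sum(table$n_cases) + sum(table$n_controls)
  frac <- (w * table$n_cases + table$n_controls) / denom
  tibble(
    category = table$category,
    prevalence = prevalence,
    population_fraction = frac,
    population_pct = 100 * frac
  )
}

#' Predictive values of a positive-category screening rule
#'
#' Under the prevalence reweighting, PPV is the weighted fraction of
#' cases among subjects in the positive categories and NPV the weighted
#' fraction of non-cases among the rest. The PPV of a single positive
#' category equals its [absolute_risk_by_category()] entry.
#'
#' @inheritParams absolute_risk_by_category
#' @param positive_categories Non-empty subset of the category indices.
#' @return One-row tibble: `prevalence`, `ppv`, `npv` (fractions) and
#'   percent versions.
#' @export
predictive_values <- function(table, prevalence, positive_categories) {
  if (length(positive_categories) == 0 ||
      !all(positive_categories %in% table$category)) {
    abort("positive_categories must be a non-empty subset of the categories.")
  }
  m <- table_margins(table)
  w <- case_weight(prevalence, m[1], m[2])
  pos <- table$category %in% positive_categories
  w_cases_pos <- w * sum(table$n_cases[pos])
  w_total_pos <- w_cases_pos + sum(table$n_controls[pos])
  w_cases_neg <- w * sum(table$n_cases[!pos])
  w_total_neg <- w_cases_neg + sum(table$n_controls[!pos])
  ppv <- if (w_total_pos > 0) w_cases_pos / w_total_pos else NA_real_
  npv <- if (w_total_neg > 0) 1 - w_cases_neg / w_total_neg else NA_real_
  tibble(prevalence = prevalence, ppv = ppv, npv = npv,
         ppv_pct = 100 * ppv, npv_pct = 100 * npv)
}

# study margins entering the case weight: counts reconstructed from rounded
# percentages need not sum exactly to the true margins, so tables may carry
# the true margins as an attribute (see reconstruct_category_counts)
table_margins <- function(table) {
  attr(table, "margins") %||% c(sum(table$n_cases), sum(table$n_controls))
}

#' Projection table over a prevalence grid
#'
#' Absolute risks and modelled population fractions for every category at
#' each prevalence of the grid — the full modelled-population summary.
#'
#' @param table A `grs_category_table`.
#' @param prevalences Numeric vector of prevalences in (0,1); defaults to
#'   the [amd_prevalence_schedule()] grid.
#' @return A tibble: one row per prevalence x category with
#'   `absolute_risk_pct` and `population_pct`.
#' @export
projection_table <- function(table, prevalences = amd_prevalence_schedule()$prevalence) {
  rows <- map(prevalences, function(p) {
    left_join(absolute_risk_by_category(table, p),
              modeled_population_fractions(table, p),
              by = c("category", "prevalence"))
  })
  bind_rows(rows)
}

#' Prevalence-reweighted GRS histogram data
#'
#' Bin counts of the score distribution with case counts scaled by the
#' prevalence case weight of [case_weight()], suitable for plotting a
#' modelled general population; emitted as data, rendering is up to the
#' caller (see [plot_grs_distribution()]).
#'
#' @param data A data frame with `status` and a score column.
#' @param prevalence Assumed population prevalence; `NULL` (default)
#'   leaves case counts unweighted (the raw study view).
#' @param binwidth Histogram bin width on the GRS scale.
#' @param score Name of the score column.
#' @return A tibble: `bin_mid`, `status`, `weighted_count`.
#' @export
grs_histogram_data <- function(data, prevalence = NULL, binwidth = 0.25,
                               score = "grs") {
  s <- data[[score]]
  if (is.null(s)) abort(paste0("No score column '", score, "'."))
  w <- if (is.null(prevalence)) 1 else {
    case_weight(prevalence, sum(data$status == "case"),
                sum(data$status == "control"))
  }
  breaks <- seq(floor(min(s) / binwidth) * binwidth,
                ceiling(max(s) / binwidth) * binwidth + binwidth, by = binwidth)
  bin <- cut(s, breaks, include.lowest = TRUE)
  tibble(bin = bin, status = data$status) |>
    count(.data$bin, .data$status, name = "count") |>
    mutate(
      bin_mid = breaks[as.integer(.data$bin)] + binwidth / 2,
      weighted_count = ifelse(.data$status == "case", .data$count * w, .data$count)
    ) |>
    select("bin_mid", "status", "weighted_count")
}
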