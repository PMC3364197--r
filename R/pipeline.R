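#' One-command analysis pipeline
#'
#' Runs the full analysis on a loaded or simulated cohort — per-SNP
#' association, joint model, risk classification with exact category
#' odds ratios, prevalence projection, cross-validation and the
#' parsimonious search — and writes a report bundle of TSV tables plus a
#' JSON manifest. Reruns with the same config and seed produce identical
#' output.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{genotype_table}{Path to a dosage TSV; omit to simulate.}
#'     \item{panel}{Path to a panel YAML/JSON; omit for the built-in
#'       13-SNP panel.}
#'     \item{simulate}{List of overrides for [simulation_config()]
#'       (`target_prevalence`, `n_cases`, `n_controls`, `use_ld`).}
#'     \item{prevalences}{Prevalence grid; default the built-in schedule.}
#'     \item{k}{Number of risk categories (default 5).}
#'     \item{cv}{List: `n_repeats` (default 200), `train_fraction` (2/3).}
#'     \item{out_dir}{Output directory (created if needed).}
#'     \item{seed}{Integer seed driving all randomness.}
#'   }
#' @return Invisibly, a named list of the output file paths and the
#'   in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) abort("config$out_dir is required.")
  if (is.null(config$seed)) abort("config$seed is required.")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- if (is.null(config$panel)) amd_panel() else load_panel(config$panel)
  if (!is.null(config$genotype_table) && !is.null(config$simulate)) {
    abort("Give either genotype_table or simulate, not both.")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name),
                 file.path(out_dir, "FAILURE"))
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }

  study <- stage("input", {
    if (!is.null(config$genotype_table)) {
      read_genotype_table(config$genotype_table, panel)
    } else {
      sim <- config$simulate %||% list()
      sc <- simulation_config(
        panel,
        target_prevalence = sim$target_prevalence %||% 0.15,
        n_cases = sim$n_cases %||% 986,
        n_controls = sim$n_controls %||% 796,
        use_ld = isTRUE(sim$use_ld)
      )
      simulate_cohort(sc, seed = seed)
    }
  })

  paths <- list()
  assoc <- stage("association", association_table(study, panel))
  paths$association <- file.path(out_dir, "association.tsv")
  readr::write_tsv(assoc, paths$association, progress = FALSE)

  model <- stage("joint_model", fit_joint_model(study, panel))
  scored <- compute_grs(model, study)
  paths$model_export <- file.path(out_dir, "model_export.tsv")
  write_model_export(model, panel, paths$model_export)
  paths$forest <- file.path(out_dir, "forest_data.tsv")
  readr::write_tsv(tidy(model), paths$forest, progress = FALSE)

  k <- config$k %||% 5
  cls <- stage("classification", {
    classification <- grs_categories(scored, k = k)
    labelled <- assign_grs_category(scored, classification)
    tab <- category_table(labelled, k = k)
    ors <- category_odds_ratios(tab, reference = ceiling(k / 2))
    list(classification = classification, table = tab, ors = ors)
  })
  paths$classification <- file.path(out_dir, "classification.tsv")
  readr::write_tsv(left_join(cls$table, cls$ors, by = "category"),
                   paths$classification, progress = FALSE)

  prevs <- unlist(config$prevalences) %||% amd_prevalence_schedule()$prevalence
  proj <- stage("projection", projection_table(cls$table, prevs))
  paths$projection <- file.path(out_dir, "projection.tsv")
  readr::write_tsv(proj, paths$projection, progress = FALSE)

  cv_cfg <- config$cv %||% list()
  cv <- stage("cross_validation", cross_validate(
    study, panel,
    n_repeats = cv_cfg$n_repeats %||% 200,
    train_fraction = cv_cfg$train_fraction %||% (2 / 3),
    seed = seed + 1L
  ))
  paths$cv_summary <- file.path(out_dir, "cv_summary.tsv")
  readr::write_tsv(glance(cv), paths$cv_summary, progress = FALSE)

  pars <- stage("parsimonious", parsimonious_search(study, panel))
  paths$parsimonious <- file.path(out_dir, "parsimonious.tsv")
  readr::write_tsv(pars$trajectory, paths$parsimonious, progress = FALSE)

  manifest <- list(
    seed = seed,
    n_cases = sum(study$status == "case"),
    n_controls = sum(study$status == "control"),
    k = k,
    prevalences = prevs,
    panel_snps = panel$snp_id,
    config_hash = digest_config(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("amdgrs")),
    files = lapply(paths, basename)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(paths = paths, study = study, association = assoc,
                 model = model, classification = cls, projection = proj,
                 cv = cv, parsimonious = pars))
}

# order-stable hash of the analysis-defining config fields (the output
# location does not alter the results, so it is excluded)
digest_config <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 97 + 1)) %% .Machine$integer.max)
}
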