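#' Construct a SNP panel
#'
#' A SNP panel defines the variants entering the risk model: their rsIDs,
#' gene labels, locus grouping (variants at the same locus share a group and
#' are dropped together during parsimonious model search), the risk allele
#' orientation, and optional fixed log-odds weights for scoring a new cohort
#' without refitting.
#'
#' Dosages throughout the package count the *risk* allele (the allele
#' associated with increased disease odds), not the minor allele; the panel
#' is the single source of orientation truth.
#'
#' @param snps A data frame with columns `snp_id`, `gene_label`,
#'   `locus_group`, `risk_allele`, `other_allele`, and optionally
#'   `fixed_weight` (log-odds per risk allele), `control_freq`, `case_freq`
#'   and `or_per_allele` (reference allele frequencies / per-allele odds
#'   ratios, used as simulation defaults).
#' @return A tibble of class `snp_panel`, one row per SNP, in input order.
#' @examples
#' snp_panel(data.frame(
#'   snp_id = "rs1061170", gene_label = "CFH", locus_group = "CFH",
#'   risk_allele = "C", other_allele = "T"
#' ))
#' @export
snp_panel <- function(snps) {
  snps <- as_tibble(snps)
  required <- c("snp_id", "gene_label", "locus_group", "risk_allele", "other_allele")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    abort(paste0("Panel is missing required field(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(snps) == 0) abort("Panel must contain at least one SNP.")
  if (anyDuplicated(snps$snp_id)) {
    dup <- unique(snps$snp_id[duplicated(snps$snp_id)])
    abort(paste0("Duplicate SNP id(s) in panel: ", paste(dup, collapse = ", ")))
  }
  same <- snps$snp_id[snps$risk_allele == snps$other_allele]
  if (length(same) > 0) {
    abort(paste0("risk_allele equals other_allele for: ",
                 paste(same, collapse = ", ")))
  }
  if (!"fixed_weight" %in% names(snps)) snps$fixed_weight <- NA_real_
  class(snps) <- c("snp_panel", class(snps))
  snps
}

#' Read a SNP panel from a YAML or JSON config file
#'
#' The config holds a top-level `snps` list; each entry needs `snp_id`,
#' `gene_label`, `locus_group`, `risk_allele` and `other_allele`, and may
#' carry `fixed_weight`, `control_freq`, `case_freq`, `or_per_allele` and
#' `ld_r2_with_first` (within-locus correlation with the locus' first SNP,
#' used by the simulator's optional LD mode).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` panel file.
#' @return A [snp_panel()] in file order.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("Panel file not found: ", path))
  parsed <- tryCatch(
    {
      if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::read_json(path, simplifyVector = FALSE)
      } else {
        yaml::read_yaml(path)
      }
    },
    error = function(e) abort(paste0("Failed to parse panel file '", path, "': ",
                                     conditionMessage(e)))
  )
  entries <- parsed$snps %||% parsed
  if (!is.list(entries) || length(entries) == 0) {
    abort(paste0("Panel file '", path, "' contains no SNP records."))
  }
  rows <- imap(entries, function(rec, i) {
    required <- c("snp_id", "gene_label", "locus_group", "risk_allele", "other_allele")
    miss <- setdiff(required, names(rec))
    if (length(miss) > 0) {
      abort(paste0("Panel record ", i, " (",
                   rec$snp_id %||% "unnamed", ") is missing: ",
                   paste(miss, collapse = ", ")))
    }
    tibble(
      snp_id = as.character(rec$snp_id),
      gene_label = as.character(rec$gene_label),
      locus_group = as.character(rec$locus_group),
      risk_allele = as.character(rec$risk_allele),
      other_allele = as.character(rec$other_allele),
      fixed_weight = as.numeric(rec$fixed_weight %||% NA_real_),
      control_freq = as.numeric(rec$control_freq %||% NA_real_),
      case_freq = as.numeric(rec$case_freq %||% NA_real_),
      or_per_allele = as.numeric(rec$or_per_allele %||% NA_real_),
      ld_r2_with_first = as.numeric(rec$ld_r2_with_first %||% NA_real_)
    )
  })
  snp_panel(bind_rows(rows))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reference 13-SNP AMD risk panel
#'
#' The 13 established late-stage AMD risk variants at eight gene loci
#' (CFH, ARMS2/HTRA1, CFB, C3, APOE, PLA2G12A/CFI, LIPC, SYN3/TIMP3), with
#' published control/case risk-allele frequencies and single-SNP per-allele
#' odds ratios from a German case-control study of 986 late-stage AMD cases
#' and 796 controls. These values are the default parameters of
#' [simulation_config()].
#'
#' @return A [snp_panel()] of 13 SNPs in 8 locus groups.
#' @export
amd_panel <- function() {
  load_panel(system.file("extdata", "amd_panel.yaml", package = "amdgrs"))
}
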