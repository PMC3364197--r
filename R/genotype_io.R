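#' Assemble a validated case-control study
#'
#' A study is a tidy subjects-by-variables tibble: `subject_id`, `status`
#' (`"case"`/`"control"`), optional covariates `age_years`, `sex`,
#' `subtype` (cases only; one of `GA`, `NV`, `mixed`), followed by one
#' integer risk-allele dosage column per panel SNP with values 0/1/2 and
#' no missing entries.
#'
#' @param data Data frame holding `subject_id`, `status`, optional
#'   covariates and the dosage columns.
#' @param panel A [snp_panel()]; dosage columns are checked and ordered
#'   against it.
#' @return A tibble of class `cc_study` with attribute `snp_ids`.
#' @export
case_control_study <- function(data, panel) {
  data <- as_tibble(data)
  if (!all(c("subject_id", "status") %in% names(data))) {
    abort("Study requires 'subject_id' and 'status' columns.")
  }
  missing_snps <- setdiff(panel$snp_id, names(data))
  if (length(missing_snps) > 0) {
    abort(paste0("Study is missing dosage column(s): ",
                 paste(missing_snps, collapse = ", ")))
  }
  bad_status <- setdiff(unique(data$status), c("case", "control"))
  if (length(bad_status) > 0) {
    abort(paste0("status must be 'case' or 'control'; found: ",
                 paste(bad_status, collapse = ", ")))
  }
  for (id in panel$snp_id) {
    v <- data[[id]]
    if (anyNA(v) || !all(v %in% c(0, 1, 2))) {
      bad_row <- which(is.na(v) | !(v %in% c(0, 1, 2)))[1]
      abort(paste0("Dosage outside {0,1,2} (or missing) at row ", bad_row,
                   ", SNP ", id))
    }
    data[[id]] <- as.integer(v)
  }
  if ("subtype" %in% names(data)) {
    ctrl_sub <- data$status == "control" & !is.na(data$subtype) & data$subtype != ""
    if (any(ctrl_sub)) abort("subtype may be set only for cases.")
    bad <- !is.na(data$subtype) & data$subtype != "" &
      !data$subtype %in% c("GA", "NV", "mixed")
    if (any(bad)) {
      abort(paste0("Unknown subtype value(s): ",
                   paste(unique(data$subtype[bad]), collapse = ", ")))
    }
  }
  covars <- intersect(c("age_years", "sex", "subtype"), names(data))
  data <- data[, c("subject_id", "status", covars, panel$snp_id)]
  structure(data, snp_ids = panel$snp_id,
            class = c("cc_study", class(data)))
}

#' @export
print.cc_study <- function(x, ...) {
  ids <- attr(x, "snp_ids")
  cat(sprintf("<cc_study> %d subjects (%d cases, %d controls), %d SNPs\n",
              nrow(x), sum(x$status == "case"), sum(x$status == "control"),
              length(ids)))
  NextMethod()
}

snp_ids_of <- function(study) attr(study, "snp_ids")

dosage_matrix <- function(study) {
  m <- as.matrix(as.data.frame(study)[, snp_ids_of(study), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- study$subject_id
  m
}

check_two_classes <- function(study) {
  if (sum(study$status == "case") < 1 || sum(study$status == "control") < 1) {
    abort("Study must contain at least one case and one control.")
  }
  invisible(study)
}

#' Read a genotype-dosage table
#'
#' The dialect is tab-separated with a header row: `subject_id`, `status`,
#' optional `age_years`, `sex`, `subtype`, then one column per panel rsID
#' holding the risk-allele dosage (0, 1 or 2). Any cell outside that
#' domain is rejected with its location; nothing is silently coerced.
#'
#' @param path Path to a dosage TSV.
#' @inheritParams case_control_study
#' @return A `cc_study` in file row order.
#' @export
read_genotype_table <- function(path, panel) {
  if (!file.exists(path)) abort(paste0("Genotype table not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_snps <- setdiff(panel$snp_id, names(raw))
  if (length(missing_snps) > 0) {
    abort(paste0("Genotype table '", path, "' lacks column(s): ",
                 paste(missing_snps, collapse = ", ")))
  }
  for (id in panel$snp_id) {
    v <- raw[[id]]
    ok <- v %in% c("0", "1", "2")
    if (!all(ok)) {
      bad <- which(!ok)[1]
      abort(paste0("Invalid dosage '", v[bad] %||% "<empty>", "' at row ",
                   bad, ", column ", id, " of ", path))
    }
    raw[[id]] <- as.integer(v)
  }
  if ("age_years" %in% names(raw)) raw$age_years <- as.numeric(raw$age_years)
  if ("subtype" %in% names(raw)) {
    raw$subtype <- ifelse(is.na(raw$subtype) | raw$subtype == "",
                          NA_character_, raw$subtype)
  }
  case_control_study(raw, panel)
}

#' Write a genotype-dosage table
#'
#' Emits the dialect read by [read_genotype_table()]; writing then reading
#' (then writing again) is the identity on all fields.
#'
#' @param study A `cc_study`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(study, path) {
  out <- as_tibble(as.data.frame(study))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Extract panel dosages from a VCF
#'
#' Counts panel risk alleles in the GT field of each panel variant
#' (matched by ID). Multi-allelic records and missing genotypes are
#' rejected; genomic coordinates are ignored — the risk model only needs
#' allele counts. Requires the `vcfR` package.
#'
#' @param path Path to a VCF (4.x) file.
#' @inheritParams case_control_study
#' @param status Character vector of `"case"`/`"control"` per VCF sample,
#'   in VCF sample order.
#' @return A `cc_study`.
#' @export
read_vcf_dosages <- function(path, panel, status) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf_dosages requires the 'vcfR' package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  idx <- match(panel$snp_id, fix$ID)
  if (anyNA(idx)) {
    abort(paste0("VCF lacks panel variant(s): ",
                 paste(panel$snp_id[is.na(idx)], collapse = ", ")))
  }
  multi <- grepl(",", fix$ALT[idx])
  if (any(multi)) {
    abort(paste0("Multi-allelic record(s) not supported: ",
                 paste(panel$snp_id[multi], collapse = ", ")))
  }
  samples <- colnames(gt)
  if (length(status) != length(samples)) {
    abort("'status' must have one entry per VCF sample.")
  }
  dos <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(panel),
                dimnames = list(samples, panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    row_i <- idx[j]
    alleles <- c(fix$REF[row_i], fix$ALT[row_i])
    risk <- panel$risk_allele[j]
    if (!risk %in% alleles) {
      abort(paste0("Risk allele ", risk, " of ", panel$snp_id[j],
                   " matches neither REF nor ALT in the VCF."))
    }
    risk_code <- as.character(which(alleles == risk) - 1L)
    g <- gt[row_i, ]
    if (anyNA(g) || any(grepl("\\.", g))) {
      abort(paste0("Missing genotype(s) at ", panel$snp_id[j]))
    }
    parts <- strsplit(g, "[/|]")
    dos[, j] <- vapply(parts, function(p) sum(p == risk_code), integer(1))
  }
  case_control_study(
    bind_cols(tibble(subject_id = samples, status = status),
              as_tibble(dos)),
    panel
  )
}
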