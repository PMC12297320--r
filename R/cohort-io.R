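#' @title Tabular input/output for trial cohorts
#' @description Readers, validators, and writers for the three patient-level
#'   tables the pipeline consumes: somatic mutation calls (MAF-lite),
#'   BCL2/BCL6/MYC FISH rearrangement flags, and clinical covariates with
#'   response and survival outcomes. All files are tab-separated UTF-8 with a
#'   header row; lines starting with `#` are ignored and `NA` is the sole
#'   missing-value token.
#' @name cohort_io
NULL

# Variant-effect classes recognised on ingest.
VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice_site",
                     "inframe_indel", "silent", "other")

#' Default variant-class whitelist
#'
#' Nonsynonymous effect classes retained by default when reading a mutation
#' table: missense, nonsense, frameshift, splice-site and in-frame indels.
#' Silent and unclassified variants are dropped.
#'
#' @return Character vector of variant classes.
#' @export
nonsynonymous_classes <- function() {
  setdiff(VARIANT_CLASSES, c("silent", "other"))
}

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", na.strings = "NA",
                          colClasses = "character", check.names = FALSE,
                          blank.lines.skip = TRUE, quote = "",
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    stop("format error in ", basename(path), ": missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a MAF-lite mutation table
#'
#' Reads per-sample somatic variant calls and filters them to a whitelist of
#' variant-effect classes. Gene symbols are uppercased on ingest; no alias
#' resolution is performed (HIST1H1E/HIST1H1C style symbols are kept
#' verbatim).
#'
#' @param path Path to a TSV with columns `sample_id`, `gene`,
#'   `variant_class`.
#' @param allowed_classes Variant classes to retain. Defaults to the
#'   nonsynonymous set from [nonsynonymous_classes()].
#' @param quiet Suppress the message reporting how many rows were filtered.
#' @return A data.frame of retained calls with columns `sample_id`, `gene`,
#'   `variant_class`.
#' @export
read_mutation_table <- function(path,
                                allowed_classes = nonsynonymous_classes(),
                                quiet = FALSE) {
  df <- read_tsv_strict(path, c("sample_id", "gene", "variant_class"))
  if (nrow(df) == 0) {
    return(data.frame(sample_id = character(), gene = character(),
                      variant_class = character(), stringsAsFactors = FALSE))
  }
  bad <- which(is.na(df$sample_id) | df$sample_id == "" |
               is.na(df$gene) | df$gene == "")
  if (length(bad)) {
    stop("unparseable mutation row (empty sample_id or gene) at data line ",
         bad[1], call. = FALSE)
  }
  cls <- tolower(df$variant_class)
  unknown <- which(!cls %in% VARIANT_CLASSES)
  if (length(unknown)) {
    stop("unknown variant_class '", df$variant_class[unknown[1]],
         "' at data line ", unknown[1], call. = FALSE)
  }
  keep <- cls %in% allowed_classes
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet) {
    message(n_dropped, " variant call(s) excluded by variant-class filter")
  }
  out <- data.frame(sample_id = df$sample_id[keep],
                    gene = toupper(df$gene[keep]),
                    variant_class = cls[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

parse_flag <- function(x, col, path) {
  out <- rep(NA, length(x))
  ok <- is.na(x) | x %in% c("0", "1")
  if (any(!ok)) {
    stop("invalid value '", x[which(!ok)[1]], "' in column ", col, " of ",
         basename(path), " (allowed: 0, 1, NA)", call. = FALSE)
  }
  out[!is.na(x)] <- x[!is.na(x)] == "1"
  out
}

#' Read a FISH rearrangement table
#'
#' One row per sample with tri-valued BCL2/BCL6/MYC rearrangement flags.
#' `NA` is preserved as missing and is never coerced to negative: a subtype
#' rule requiring a rearrangement cannot fire on a missing flag.
#'
#' @param path Path to a TSV with columns `sample_id`, `bcl2_rearranged`,
#'   `bcl6_rearranged`, `myc_rearranged`, values in \{0, 1, NA\}.
#' @return A data.frame with logical (NA-able) flag columns.
#' @export
read_fish_table <- function(path) {
  cols <- c("sample_id", "bcl2_rearranged", "bcl6_rearranged",
            "myc_rearranged")
  df <- read_tsv_strict(path, cols)
  if (nrow(df) > 0 && anyDuplicated(df$sample_id)) {
    dup <- df$sample_id[duplicated(df$sample_id)][1]
    stop("duplicate sample_id in FISH table: ", dup, call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    stringsAsFactors = FALSE)
  for (col in cols[-1]) out[[col]] <- parse_flag(df[[col]], col, path)
  out
}

DISEASE_STATUS <- c("refractory", "relapsed")
IPI_RISK <- c("low", "intermediate", "high")
RESPONSES <- c("CR", "PR", "SD", "PD")

parse_enum <- function(x, levels, col, path) {
  matched <- levels[match(tolower(x), tolower(levels))]
  bad <- which(!is.na(x) & is.na(matched))
  if (length(bad)) {
    stop("invalid value '", x[bad[1]], "' in column ", col, " of ",
         basename(path), " (allowed: ", paste(levels, collapse = ", "),
         ")", call. = FALSE)
  }
  matched
}

#' Read a clinical covariate/outcome table
#'
#' Validates the per-patient record invariants: progression-free survival
#' time never exceeds overall survival time, event flags require times, and
#' enumerated fields (disease status, IPI risk, response) are matched
#' case-insensitively.
#'
#' @param path Path to a TSV with columns `sample_id`, `age_years`,
#'   `disease_status`, `ipi_risk`, `bulky_disease`, `response`,
#'   `pfs_months`, `pfs_event`, `os_months`, `os_event`.
#' @return A validated data.frame, one row per patient.
#' @export
read_clinical_table <- function(path) {
  cols <- c("sample_id", "age_years", "disease_status", "ipi_risk",
            "bulky_disease", "response", "pfs_months", "pfs_event",
            "os_months", "os_event")
  df <- read_tsv_strict(path, cols)
  if (nrow(df) > 0 && anyDuplicated(df$sample_id)) {
    dup <- df$sample_id[duplicated(df$sample_id)][1]
    stop("duplicate sample_id in clinical table: ", dup, call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    age_years = as.integer(df$age_years),
                    disease_status = parse_enum(df$disease_status,
                                                DISEASE_STATUS,
                                                "disease_status", path),
                    ipi_risk = parse_enum(df$ipi_risk, IPI_RISK,
                                          "ipi_risk", path),
                    bulky_disease = parse_flag(df$bulky_disease,
                                               "bulky_disease", path),
                    response = parse_enum(df$response, RESPONSES,
                                          "response", path),
                    pfs_months = as.numeric(df$pfs_months),
                    pfs_event = parse_flag(df$pfs_event, "pfs_event", path),
                    os_months = as.numeric(df$os_months),
                    os_event = parse_flag(df$os_event, "os_event", path),
                    stringsAsFactors = FALSE)
  neg <- which(out$pfs_months < 0 | out$os_months < 0)
  if (length(neg)) {
    stop("negative survival time for sample ", out$sample_id[neg[1]],
         call. = FALSE)
  }
  both <- !is.na(out$pfs_months) & !is.na(out$os_months)
  viol <- which(both & out$pfs_months > out$os_months)
  if (length(viol)) {
    stop("validation error: pfs_months > os_months for sample(s) ",
         paste(out$sample_id[viol], collapse = ", "), call. = FALSE)
  }
  orphan_flag <- (!is.na(out$pfs_event) & is.na(out$pfs_months)) |
                 (!is.na(out$os_event) & is.na(out$os_months))
  if (any(orphan_flag)) {
    stop("validation error: event flag without a time for sample(s) ",
         paste(out$sample_id[orphan_flag], collapse = ", "), call. = FALSE)
  }
  out
}

#' Assemble a cohort object from parsed tables
#'
#' Joins clinical records with per-patient mutation profiles (the set of
#' genes with at least one retained variant call) and FISH status. Patients
#' absent from the mutation table receive an empty profile — distinct from a
#' missing file. Genomic records without a clinical row are kept out of the
#' cohort but reported in a reconciliation log, never silently dropped.
#'
#' @param variants Data.frame from [read_mutation_table()].
#' @param fish Data.frame from [read_fish_table()].
#' @param clinical Data.frame from [read_clinical_table()].
#' @return An object of class `cohort`: list with `clinical` (data.frame),
#'   `profiles` (named list of gene-symbol character vectors), `fish`
#'   (data.frame aligned to clinical order) and `reconciliation` (character
#'   vector of warnings about orphan genomic records).
#' @export
assemble_cohort <- function(variants, fish, clinical) {
  ids <- clinical$sample_id
  profiles <- lapply(ids, function(id) {
    sort(unique(variants$gene[variants$sample_id == id]))
  })
  names(profiles) <- ids

  blank_fish <- data.frame(sample_id = ids, bcl2_rearranged = NA,
                           bcl6_rearranged = NA, myc_rearranged = NA,
                           stringsAsFactors = FALSE)
  idx <- match(ids, fish$sample_id)
  fish_aligned <- blank_fish
  found <- !is.na(idx)
  fish_aligned[found, ] <- fish[idx[found], ]
  fish_aligned$sample_id <- ids

  recon <- character()
  orphan_mut <- setdiff(unique(variants$sample_id), ids)
  if (length(orphan_mut)) {
    recon <- c(recon, paste0("mutation records without clinical row: ",
                             paste(orphan_mut, collapse = ", ")))
  }
  orphan_fish <- setdiff(fish$sample_id, ids)
  if (length(orphan_fish)) {
    recon <- c(recon, paste0("FISH records without clinical row: ",
                             paste(orphan_fish, collapse = ", ")))
  }
  structure(list(clinical = clinical, profiles = profiles,
                 fish = fish_aligned, reconciliation = recon),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort of", nrow(x$clinical), "patients;",
      sum(lengths(x$profiles) > 0), "with >=1 retained mutation\n")
  if (length(x$reconciliation)) {
    cat("reconciliation notes:\n")
    for (r in x$reconciliation) cat(" -", r, "\n")
  }
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

fish_to_tsv <- function(fish) {
  out <- fish
  for (col in c("bcl2_rearranged", "bcl6_rearranged", "myc_rearranged")) {
    out[[col]] <- ifelse(is.na(fish[[col]]), NA, as.integer(fish[[col]]))
  }
  out
}

clinical_to_tsv <- function(clinical) {
  out <- clinical
  for (col in c("bulky_disease", "pfs_event", "os_event")) {
    out[[col]] <- ifelse(is.na(clinical[[col]]), NA,
                         as.integer(clinical[[col]]))
  }
  out
}

#' Write pipeline results to a directory
#'
#' Emits per-patient subtype calls as TSV (deterministic column order) and
#' any design/summary objects as JSON.
#'
#' @param calls Data.frame of subtype calls from [classify_cohort()], or
#'   NULL.
#' @param tables Named list of list/data.frame objects written as
#'   `<name>.json`.
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(calls = NULL, tables = list(), out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  written <- character()
  if (!is.null(calls)) {
    p <- file.path(out_dir, "subtype_calls.tsv")
    write_tsv(calls, p)
    written <- c(written, p)
  }
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(tables[[nm]], p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    written <- c(written, p)
  }
  invisible(written)
}
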