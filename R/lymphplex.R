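#' @title Rule-based genetic subtyping of DLBCL
#' @description A 38-gene + 3-FISH-marker rule engine assigning each patient
#'   one of seven genetic subtypes (MCD-like, BN2-like, N1-like, TP53-mutant,
#'   EZB-like, ST2-like, NOS) and mapping the subtype to its trial regimen.
#'   TP53 mutation takes absolute precedence; otherwise the rule matching the
#'   most defining features wins, with ties broken by a fixed, configurable
#'   priority order. Patients matching no rule are NOS (not otherwise
#'   specified).
#' @name lymphplex
NULL

SUBTYPES <- c("TP53_mut", "N1_like", "MCD_like", "BN2_like", "EZB_like",
              "ST2_like", "NOS")

REGIMENS <- c(MCD_like = "R_ICE_zanubrutinib",
              BN2_like = "R_ICE_zanubrutinib",
              N1_like  = "R_ICE_lenalidomide",
              NOS      = "R_ICE_lenalidomide",
              TP53_mut = "R_ICE_decitabine",
              EZB_like = "R_ICE_chidamide",
              ST2_like = "R_ICE_tofacitinib")

#' Default subtyping ruleset
#'
#' The defining feature sets of the six non-NOS genetic subtypes:
#' \describe{
#'   \item{MCD_like}{BTG1, CD79B, IRF4, MYD88, MPEG1, PIM1, PRDM1, TBL1XR1
#'     mutations}
#'   \item{BN2_like}{BCL6 rearrangement; BTG2, CD70, CCND3, DTX1, NOTCH2,
#'     TNFAIP3 mutations}
#'   \item{N1_like}{NOTCH1 mutations}
#'   \item{TP53_mut}{TP53 mutations (any retained nonsynonymous call)}
#'   \item{EZB_like}{BCL2 rearrangement; ARID1A, B2M, CIITA, CREBBP, EZH2,
#'     EP300, FAS, GNA13, KMT2D, STAT6, TNFRSF14 mutations}
#'   \item{ST2_like}{DDX3X, DUSP2, IRF8, SGK1, SOCS1, STAT3, TET2, ZFP36L1
#'     mutations}
#' }
#'
#' @return A named list of rules; each rule has `subtype`,
#'   `mutation_features` (character vector of HUGO symbols), `fish_features`
#'   (subset of `BCL2_R`, `BCL6_R`, `MYC_R`) and `priority_rank` (1 =
#'   strongest tie-break claim).
#' @export
default_ruleset <- function() {
  rules <- list(
    TP53_mut = list(mutation_features = "TP53", fish_features = character()),
    N1_like  = list(mutation_features = "NOTCH1",
                    fish_features = character()),
    MCD_like = list(mutation_features = c("BTG1", "CD79B", "IRF4", "MYD88",
                                          "MPEG1", "PIM1", "PRDM1",
                                          "TBL1XR1"),
                    fish_features = character()),
    BN2_like = list(mutation_features = c("BTG2", "CD70", "CCND3", "DTX1",
                                          "NOTCH2", "TNFAIP3"),
                    fish_features = "BCL6_R"),
    EZB_like = list(mutation_features = c("ARID1A", "B2M", "CIITA", "CREBBP",
                                          "EZH2", "EP300", "FAS", "GNA13",
                                          "KMT2D", "STAT6", "TNFRSF14"),
                    fish_features = "BCL2_R"),
    ST2_like = list(mutation_features = c("DDX3X", "DUSP2", "IRF8", "SGK1",
                                          "SOCS1", "STAT3", "TET2",
                                          "ZFP36L1"),
                    fish_features = character())
  )
  for (i in seq_along(rules)) {
    rules[[i]]$subtype <- names(rules)[i]
    rules[[i]]$priority_rank <- i
  }
  rules
}

#' The mutation-panel gene universe
#'
#' All gene symbols carried by the default ruleset (35 mutation features
#' across the six subtypes).
#'
#' @param ruleset A ruleset from [default_ruleset()].
#' @return Sorted character vector of gene symbols.
#' @export
panel_genes <- function(ruleset = default_ruleset()) {
  sort(unique(unlist(lapply(ruleset, `[[`, "mutation_features"))))
}

fish_flags_true <- function(fish_row) {
  flags <- c(BCL2_R = isTRUE(fish_row$bcl2_rearranged),
             BCL6_R = isTRUE(fish_row$bcl6_rearranged),
             MYC_R  = isTRUE(fish_row$myc_rearranged))
  names(flags)[flags]
}

#' Evaluate one rule against one patient
#'
#' The matched feature set is the intersection of the mutation profile with
#' the rule's gene list, plus any rule FISH marker whose flag is positively
#' TRUE. A missing FISH flag never matches (conservative: absence of
#' evidence is not evidence of rearrangement).
#'
#' @param genes Character vector of mutated genes (set semantics).
#' @param fish_row One-row data.frame (or list) with the three rearrangement
#'   flags; may be NULL for no FISH data.
#' @param rule One rule from [default_ruleset()].
#' @return Character vector of matched features (genes and/or FISH markers).
#' @export
evaluate_features <- function(genes, fish_row, rule) {
  matched <- intersect(unique(genes), rule$mutation_features)
  if (!is.null(fish_row) && length(rule$fish_features)) {
    matched <- c(matched, intersect(fish_flags_true(fish_row),
                                    rule$fish_features))
  }
  matched
}

#' Classify a single patient
#'
#' Precedence: any retained TP53 mutation assigns TP53_mut outright,
#' regardless of all other features. Otherwise every remaining rule is
#' scored by its matched-feature count; a patient matching no rule is NOS;
#' otherwise the highest count wins and ties fall to the configured priority
#' order.
#'
#' @param genes Mutated gene set for the patient.
#' @param fish_row FISH flags (may be NULL).
#' @param ruleset Ruleset, default [default_ruleset()].
#' @param priority Character vector ordering subtypes for tie-breaks;
#'   earlier wins. Default `TP53_mut, N1_like, MCD_like, BN2_like, EZB_like,
#'   ST2_like`.
#' @param min_features Minimum matched-feature count for a rule to qualify
#'   (default 1).
#' @return A list with `subtype`, `matched_features`, `candidates` (named
#'   integer vector of nonzero match counts), `tie` (logical) and `regimen`.
#' @export
classify_patient <- function(genes, fish_row = NULL,
                             ruleset = default_ruleset(),
                             priority = names(default_ruleset()),
                             min_features = 1L) {
  genes <- unique(toupper(genes))
  if ("TP53" %in% genes && "TP53_mut" %in% names(ruleset)) {
    return(list(subtype = "TP53_mut", matched_features = "TP53",
                candidates = c(TP53_mut = 1L), tie = FALSE,
                regimen = unname(REGIMENS["TP53_mut"])))
  }
  rules <- ruleset[setdiff(names(ruleset), "TP53_mut")]
  matches <- lapply(rules, function(r) evaluate_features(genes, fish_row, r))
  counts <- vapply(matches, length, integer(1))
  eligible <- counts >= min_features
  if (!any(eligible)) {
    return(list(subtype = "NOS", matched_features = character(),
                candidates = counts[counts > 0], tie = FALSE,
                regimen = unname(REGIMENS["NOS"])))
  }
  best <- max(counts[eligible])
  top <- names(counts)[eligible & counts == best]
  ranked <- priority[priority %in% top]
  winner <- if (length(ranked)) ranked[1] else sort(top)[1]
  list(subtype = winner,
       matched_features = sort(matches[[winner]]),
       candidates = counts[counts > 0],
       tie = length(top) > 1,
       regimen = unname(REGIMENS[winner]))
}

#' Map a genetic subtype to its trial regimen
#'
#' The fixed assignment: zanubrutinib added for MCD-like and BN2-like,
#' lenalidomide for N1-like and NOS, decitabine for TP53-mutant, chidamide
#' for EZB-like, tofacitinib for ST2-like — each on an R-ICE backbone.
#'
#' @param subtype Subtype label(s).
#' @return Regimen label(s).
#' @export
assign_regimen <- function(subtype) {
  bad <- setdiff(subtype, names(REGIMENS))
  if (length(bad)) {
    stop("unknown subtype label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(REGIMENS[subtype])
}

#' Classify a whole cohort
#'
#' @param cohort A `cohort` from [assemble_cohort()].
#' @inheritParams classify_patient
#' @return A list with `calls` (data.frame: sample_id, subtype, regimen,
#'   matched_features semicolon-joined, n_candidates, tie) and `frequency`
#'   (data.frame of subtype counts and proportions summing to 1).
#' @export
classify_cohort <- function(cohort, ruleset = default_ruleset(),
                            priority = names(default_ruleset()),
                            min_features = 1L) {
  ids <- cohort$clinical$sample_id
  rows <- lapply(seq_along(ids), function(i) {
    res <- classify_patient(cohort$profiles[[ids[i]]], cohort$fish[i, ],
                            ruleset, priority, min_features)
    data.frame(sample_id = ids[i], subtype = res$subtype,
               regimen = res$regimen,
               matched_features = paste(res$matched_features,
                                        collapse = ";"),
               n_candidates = length(res$candidates),
               tie = res$tie, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  counts <- table(factor(calls$subtype, levels = SUBTYPES))
  freq <- data.frame(subtype = names(counts),
                     n = as.integer(counts),
                     proportion = as.numeric(counts) / nrow(calls),
                     stringsAsFactors = FALSE)
  list(calls = calls, frequency = freq)
}

#' Concordance between two labelings
#'
#' Compares two subtype labelings of the same samples, omitting from the
#' denominator any pair whose label on either side is NOS/unclassified or in
#' `exclude` — the convention used when benchmarking one rule-based
#' classifier against another.
#'
#' @param calls_a,calls_b Data.frames with `sample_id` and `subtype`.
#' @param exclude Labels to drop from the comparison (in addition to NOS).
#' @return List with `n_compared`, `n_agreeing`, `proportion`.
#' @export
compare_labelings <- function(calls_a, calls_b, exclude = character()) {
  if (!setequal(calls_a$sample_id, calls_b$sample_id)) {
    stop("labelings cover different sample sets", call. = FALSE)
  }
  b <- calls_b$subtype[match(calls_a$sample_id, calls_b$sample_id)]
  a <- calls_a$subtype
  drop_labels <- union(exclude, c("NOS", "unclassified", "Other"))
  keep <- !(a %in% drop_labels) & !(b %in% drop_labels)
  n_compared <- sum(keep)
  n_agreeing <- sum(a[keep] == b[keep])
  list(n_compared = n_compared, n_agreeing = n_agreeing,
       proportion = if (n_compared > 0) n_agreeing / n_compared else NA_real_)
}

#' Export / import a ruleset as JSON
#'
#' @param ruleset Ruleset to write.
#' @param path File path.
#' @return `write_ruleset` invisibly returns `path`; `read_ruleset` returns
#'   the ruleset.
#' @export
write_ruleset <- function(ruleset, path) {
  doc <- lapply(ruleset, function(r) {
    list(subtype = r$subtype,
         mutation_features = as.list(r$mutation_features),
         fish_features = as.list(r$fish_features),
         priority_rank = r$priority_rank)
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  doc <- jsonlite::read_json(path)
  rules <- lapply(doc, function(r) {
    list(mutation_features = as.character(unlist(r$mutation_features)),
         fish_features = as.character(unlist(r$fish_features)),
         subtype = r$subtype,
         priority_rank = r$priority_rank)
  })
  names(rules) <- vapply(doc, `[[`, "", "subtype")
  rules[order(vapply(rules, function(r) as.numeric(r$priority_rank),
                     numeric(1)))]
}
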