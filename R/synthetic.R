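#' @title Seeded synthetic trial cohorts
#' @description Generates mutation, FISH and clinical tables with the
#'   statistical structure the analysis pipeline assumes: per-gene marginal
#'   mutation frequencies matching the trial's printed mutation spectrum, a
#'   subtype-first mode drawing patients from the printed seven-subtype
#'   prevalence distribution with guaranteed classifier label recovery,
#'   per-arm multinomial response distributions, exponential survival
#'   anchored to the printed 2-year progression-free and overall survival
#'   rates, and uniform administrative censoring. One root seed drives
#'   independent named substreams per table, so regenerating one table never
#'   perturbs another's draws.
#' @name synthetic_cohort
NULL

# Printed per-gene marginal mutation frequencies (proportions).
PRINTED_GENE_FREQS <- c(
  PIM1 = 0.43, MYD88 = 0.36, KMT2D = 0.26, BTG2 = 0.25, CD79B = 0.24,
  TMSB4X = 0.24, BTG1 = 0.21, TNFAIP3 = 0.16, BCL6 = 0.16, DTX1 = 0.16,
  KMT2C = 0.16, B2M = 0.16, HIST1H1E = 0.14, TET2 = 0.14, NOTCH2 = 0.14,
  MPEG1 = 0.14, CARD11 = 0.13, CD70 = 0.13, SOCS1 = 0.13, TP53 = 0.12,
  TBL1XR1 = 0.11, DUSP2 = 0.11, IRF4 = 0.11, HIST1H1C = 0.11, CD58 = 0.11)

# Seven-subtype prevalence distribution.
DEFAULT_PREVALENCES <- c(MCD_like = 0.25, BN2_like = 0.20, N1_like = 0.05,
                         NOS = 0.34, TP53_mut = 0.12, EZB_like = 0.03,
                         ST2_like = 0.01)

# Per-arm response distributions over assessed outcomes (CR, PR, SD, PD).
# CR/PR cells are the printed per-arm counts; SD/PD cells are filled so the
# arm totals reproduce the printed overall SD = 3 and PD = 13 (two patients,
# one zanubrutinib and one lenalidomide, left induction early and are
# response-unassessed); distributions are normalised over assessed patients.
DEFAULT_ARM_RESPONSE <- list(
  R_ICE_zanubrutinib = c(CR = 18, PR = 9, SD = 1, PD = 5) / 33,
  R_ICE_lenalidomide = c(CR = 17, PR = 6, SD = 1, PD = 5) / 29,
  R_ICE_decitabine   = c(CR = 6, PR = 0, SD = 1, PD = 2) / 9,
  R_ICE_chidamide    = c(CR = 1, PR = 0, SD = 0, PD = 0),
  R_ICE_tofacitinib  = c(CR = 0, PR = 0, SD = 0, PD = 1))

VARIANT_CLASS_WEIGHTS <- c(missense = 0.60, nonsense = 0.12,
                           frameshift = 0.12, splice_site = 0.08,
                           inframe_indel = 0.08)

#' Cohort generator configuration
#'
#' Bundles every tunable of the synthetic generator with defaults matching
#' the trial's printed summary statistics.
#'
#' @param n_patients Number of patients.
#' @param mode `"subtype_first"` (draw a subtype label, then a consistent
#'   genotype) or `"marginal"` (independent per-gene Bernoulli draws).
#' @param seed Root seed (integer); all table substreams derive from it.
#' @param gene_frequencies Named vector of marginal mutation probabilities;
#'   panel genes not listed receive `background_rate`.
#' @param subtype_prevalences Named vector over the seven subtypes, summing
#'   to 1.
#' @param arm_response_probs Named list: regimen -> probability vector over
#'   `CR, PR, SD, PD` summing to 1.
#' @param pfs_anchor,os_anchor `c(months, survival)` anchors for the
#'   exponential survival scales (defaults: 2-year PFS 69.3%, OS 88.3%).
#' @param censor_window `c(min, max)` months of uniform administrative
#'   censoring; default `c(6, 33)` gives a median follow-up of 19.5 months.
#' @param background_rate Mutation probability for unlisted panel genes and
#'   (in strict subtype-first mode) the rate at which passenger/rival
#'   features are attempted.
#' @param strict In subtype-first mode, guarantee that the classifier
#'   recovers the drawn label for every patient (rival feature counts are
#'   kept strictly below the intended rule's count). Default TRUE.
#' @param fish_background Named vector of rearrangement rates used in
#'   marginal mode (`bcl2`, `bcl6`, `myc`).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 76L,
                          mode = c("subtype_first", "marginal"),
                          seed = 20220426L,
                          gene_frequencies = PRINTED_GENE_FREQS,
                          subtype_prevalences = DEFAULT_PREVALENCES,
                          arm_response_probs = DEFAULT_ARM_RESPONSE,
                          pfs_anchor = c(months = 24, survival = 0.693),
                          os_anchor = c(months = 24, survival = 0.883),
                          censor_window = c(6, 33),
                          background_rate = 0.05,
                          strict = TRUE,
                          fish_background = c(bcl2 = 0.04, bcl6 = 0.10,
                                              myc = 0.04)) {
  mode <- match.arg(mode)
  if (abs(sum(subtype_prevalences) - 1) > 1e-9) {
    stop("subtype prevalences must sum to 1", call. = FALSE)
  }
  if (any(subtype_prevalences < 0) ||
      any(gene_frequencies < 0 | gene_frequencies > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  for (nm in names(arm_response_probs)) {
    p <- arm_response_probs[[nm]]
    if (abs(sum(p) - 1) > 1e-9) {
      stop("response probabilities for ", nm, " do not sum to 1",
           call. = FALSE)
    }
  }
  if (!(pfs_anchor["survival"] > 0 && pfs_anchor["survival"] < 1 &&
        os_anchor["survival"] > 0 && os_anchor["survival"] < 1)) {
    stop("survival anchors must lie in (0, 1)", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients), mode = mode,
                 seed = as.integer(seed),
                 gene_frequencies = gene_frequencies,
                 subtype_prevalences = subtype_prevalences,
                 arm_response_probs = arm_response_probs,
                 pfs_anchor = pfs_anchor, os_anchor = os_anchor,
                 censor_window = censor_window,
                 background_rate = background_rate, strict = strict,
                 fish_background = fish_background),
            class = "cohort_config")
}

# Named substreams derived from the root seed: each table consumes its own
# stream so adding a column to one table never shifts another's draws.
STREAM_NAMES <- c("labels", "mutations", "fish", "response", "survival",
                  "censor", "clinical")

stream_seeds <- function(root_seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(root_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(STREAM_NAMES))
  names(seeds) <- STREAM_NAMES
  seeds
}

with_stream <- function(seeds, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seeds[[name]])
  expr
}

all_panel_genes <- function(config) {
  sort(unique(c(panel_genes(), names(config$gene_frequencies))))
}

gene_freq_of <- function(config, genes) {
  f <- config$gene_frequencies[genes]
  f[is.na(f)] <- config$background_rate
  names(f) <- genes
  f
}

sample_variant_classes <- function(k) {
  sample(names(VARIANT_CLASS_WEIGHTS), k, replace = TRUE,
         prob = VARIANT_CLASS_WEIGHTS)
}

draw_subtype_profile <- function(label, ruleset, config) {
  # intended features, rivals capped strictly below the intended count,
  # passengers from panel genes belonging to no rule
  bg <- config$background_rate
  genes <- character()
  fish <- c(BCL2_R = FALSE, BCL6_R = FALSE, MYC_R = FALSE)
  rule_genes <- unique(unlist(lapply(ruleset, `[[`, "mutation_features")))
  neutral <- setdiff(all_panel_genes(config), c(rule_genes, "TP53"))

  if (label == "TP53_mut") {
    genes <- "TP53"
    m <- Inf  # precedence is absolute; rivals are irrelevant
  } else if (label == "NOS") {
    m <- 0
  } else {
    rule <- ruleset[[label]]
    feats <- c(rule$mutation_features,
               if (length(rule$fish_features)) rule$fish_features)
    n_extra <- if (length(feats) > 1) {
      stats::rbinom(1, length(feats) - 1, 0.2)
    } else 0
    chosen <- sample(feats, 1 + n_extra)
    genes <- intersect(chosen, rule$mutation_features)
    for (fm in intersect(chosen, names(fish))) fish[fm] <- TRUE
    m <- length(chosen)
  }

  if (label != "TP53_mut" && config$strict) {
    # rival rules: features drawn at background rate, truncated so each
    # rival matched count stays strictly below m
    rivals <- setdiff(names(ruleset), c("TP53_mut", label))
    for (rv in rivals) {
      cap <- max(0, m - 1)
      if (cap == 0) next
      rg <- ruleset[[rv]]$mutation_features
      drawn <- rg[stats::runif(length(rg)) < bg]
      if (length(drawn) > cap) drawn <- drawn[seq_len(cap)]
      genes <- c(genes, drawn)
    }
  } else if (label != "TP53_mut") {
    rivals <- setdiff(rule_genes,
                      c("TP53", if (label != "NOS")
                        ruleset[[label]]$mutation_features))
    genes <- c(genes, rivals[stats::runif(length(rivals)) < bg])
  }
  passengers <- neutral[stats::runif(length(neutral)) <
                        gene_freq_of(config, neutral)]
  list(genes = unique(c(genes, passengers)), fish = fish)
}

#' Generate mutation and FISH tables
#'
#' In `marginal` mode every gene mutates independently at its configured
#' frequency and FISH flags follow the background rearrangement rates. In
#' `subtype_first` mode a subtype label is drawn per patient from the
#' prevalence distribution, at least one uniformly chosen defining feature
#' of that subtype is forced into the profile (FISH flags included), TP53 is
#' excluded unless the label is TP53-mutant, and (strict mode) rival rules
#' never accumulate enough features to out-score the intended label.
#'
#' @param config A [cohort_config()].
#' @return List with `mutations` (long data.frame: sample_id, gene,
#'   variant_class), `fish` (data.frame of flags) and `labels` (intended
#'   subtype per patient; NA in marginal mode).
#' @export
generate_profiles <- function(config) {
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  seeds <- stream_seeds(config$seed)
  ruleset <- default_ruleset()

  if (config$mode == "marginal") {
    genes <- all_panel_genes(config)
    freqs <- gene_freq_of(config, genes)
    mutations <- with_stream(seeds, "mutations", {
      mut_mat <- matrix(stats::runif(n * length(genes)) <
                          rep(freqs, each = n),
                        nrow = n, dimnames = list(ids, genes))
      rows <- which(mut_mat, arr.ind = TRUE)
      df <- data.frame(sample_id = ids[rows[, 1]],
                       gene = genes[rows[, 2]],
                       variant_class = sample_variant_classes(nrow(rows)),
                       stringsAsFactors = FALSE)
      df[order(df$sample_id, df$gene), ]
    })
    fish <- with_stream(seeds, "fish", {
      fb <- config$fish_background
      data.frame(sample_id = ids,
                 bcl2_rearranged = stats::runif(n) < fb[["bcl2"]],
                 bcl6_rearranged = stats::runif(n) < fb[["bcl6"]],
                 myc_rearranged = stats::runif(n) < fb[["myc"]],
                 stringsAsFactors = FALSE)
    })
    labels <- rep(NA_character_, n)
  } else {
    labels <- with_stream(seeds, "labels", {
      sample(names(config$subtype_prevalences), n, replace = TRUE,
             prob = config$subtype_prevalences)
    })
    mutfish <- with_stream(seeds, "mutations", {
      drawn <- lapply(labels, draw_subtype_profile, ruleset = ruleset,
                      config = config)
      per_patient <- lapply(seq_len(n), function(i) {
        g <- sort(drawn[[i]]$genes)
        if (length(g) == 0) return(NULL)
        data.frame(sample_id = ids[i], gene = g, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, per_patient)
      if (is.null(df)) {
        df <- data.frame(sample_id = character(), gene = character(),
                         stringsAsFactors = FALSE)
      }
      df$variant_class <- sample_variant_classes(nrow(df))
      list(mutations = df, drawn = drawn)
    })
    mutations <- mutfish$mutations
    fish <- with_stream(seeds, "fish", {
      data.frame(
        sample_id = ids,
        bcl2_rearranged = vapply(mutfish$drawn,
                                 function(d) d$fish[["BCL2_R"]],
                                 logical(1)),
        bcl6_rearranged = vapply(mutfish$drawn,
                                 function(d) d$fish[["BCL6_R"]],
                                 logical(1)),
        myc_rearranged = stats::runif(n) <
          config$fish_background[["myc"]],
        stringsAsFactors = FALSE)
    })
  }
  rownames(mutations) <- NULL
  list(mutations = mutations, fish = fish, labels = labels)
}

# Exponential rate hitting the anchor: S(t*) = exp(-rate t*) = s*.
anchor_rate <- function(anchor) {
  -log(anchor[["survival"]]) / anchor[["months"]]
}

# OS = PFS + independent exponential tail. The tail rate is solved so the
# marginal OS survival (hypoexponential) hits the OS anchor exactly.
os_tail_rate <- function(pfs_anchor, os_anchor) {
  a <- anchor_rate(pfs_anchor)
  t0 <- os_anchor[["months"]]
  target <- os_anchor[["survival"]]
  s_os <- function(b) {
    if (abs(b - a) < 1e-12) (1 + a * t0) * exp(-a * t0)
    else (b * exp(-a * t0) - a * exp(-b * t0)) / (b - a)
  }
  if (s_os(1e3) > target) {
    stop("OS anchor below the PFS anchor implies OS < PFS; not attainable",
         call. = FALSE)
  }
  stats::uniroot(function(b) s_os(b) - target, c(1e-8, 1e3),
                 tol = 1e-12)$root
}

#' Simulate response and survival outcomes
#'
#' Responses follow each regimen's multinomial distribution over CR/PR/SD/
#' PD. Progression-free survival is exponential with its rate identified by
#' the 2-year anchor; overall survival adds an independent exponential tail
#' whose rate is solved so the marginal OS meets its own anchor, which also
#' enforces OS >= PFS patientwise. Administrative censoring is uniform over
#' the configured window and truncates both endpoints.
#'
#' @param labels Character vector of subtype labels (regimens are derived
#'   via [assign_regimen()]).
#' @param config A [cohort_config()].
#' @return Clinical data.frame (one row per patient) with covariates,
#'   `response`, and observed `pfs_months`/`pfs_event`,
#'   `os_months`/`os_event`.
#' @export
simulate_outcomes <- function(labels, config) {
  n <- length(labels)
  ids <- sprintf("P%04d", seq_len(n))
  seeds <- stream_seeds(config$seed)
  regimens <- assign_regimen(labels)

  response <- with_stream(seeds, "response", {
    vapply(regimens, function(rg) {
      p <- config$arm_response_probs[[rg]]
      if (is.null(p)) stop("no response distribution for regimen ", rg,
                           call. = FALSE)
      sample(names(p), 1, prob = p)
    }, character(1))
  })

  rate_pfs <- anchor_rate(config$pfs_anchor)
  rate_tail <- os_tail_rate(config$pfs_anchor, config$os_anchor)
  surv <- with_stream(seeds, "survival", {
    pfs <- stats::rexp(n, rate_pfs)
    os <- pfs + stats::rexp(n, rate_tail)
    list(pfs = pfs, os = os)
  })
  cens <- with_stream(seeds, "censor", {
    stats::runif(n, config$censor_window[1], config$censor_window[2])
  })

  covars <- with_stream(seeds, "clinical", {
    data.frame(
      age_years = pmin(71L, pmax(18L,
                                 as.integer(round(stats::rnorm(n, 59,
                                                               10))))),
      disease_status = sample(c("refractory", "relapsed"), n,
                              replace = TRUE, prob = c(39, 37) / 76),
      ipi_risk = sample(c("low", "intermediate", "high"), n, replace = TRUE,
                        prob = c(12, 42, 22) / 76),
      bulky_disease = stats::runif(n) < 12 / 76,
      stringsAsFactors = FALSE)
  })

  data.frame(sample_id = ids,
             age_years = covars$age_years,
             disease_status = covars$disease_status,
             ipi_risk = covars$ipi_risk,
             bulky_disease = covars$bulky_disease,
             response = unname(response),
             pfs_months = round(pmin(surv$pfs, cens), 3),
             pfs_event = surv$pfs <= cens,
             os_months = round(pmin(surv$os, cens), 3),
             os_event = surv$os <= cens,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Draws profiles and outcomes under one root seed and, when `out_dir` is
#' given, writes `mutations.tsv`, `fish.tsv`, `clinical.tsv` and a
#' `manifest.json` recording the full configuration. In marginal mode the
#' intended labels are unknown, so outcomes are simulated from the labels
#' the classifier assigns to the generated profiles.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional output directory.
#' @return List with `mutations`, `fish`, `clinical` data.frames, `labels`
#'   (intended subtype per patient), and `files` (paths written, or NULL).
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  prof <- generate_profiles(config)
  labels <- prof$labels
  if (config$mode == "marginal") {
    clin_stub <- data.frame(sample_id = prof$fish$sample_id,
                            stringsAsFactors = FALSE)
    cohort <- structure(list(
      clinical = clin_stub,
      profiles = split(prof$mutations$gene, factor(prof$mutations$sample_id,
                                                   levels = clin_stub$sample_id)),
      fish = prof$fish, reconciliation = character()), class = "cohort")
    labels <- classify_cohort(cohort)$calls$subtype
  }
  clinical <- simulate_outcomes(labels, config)
  files <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    mut_p <- file.path(out_dir, "mutations.tsv")
    fish_p <- file.path(out_dir, "fish.tsv")
    clin_p <- file.path(out_dir, "clinical.tsv")
    man_p <- file.path(out_dir, "manifest.json")
    write_tsv(prof$mutations, mut_p)
    write_tsv(fish_to_tsv(prof$fish), fish_p)
    write_tsv(clinical_to_tsv(clinical), clin_p)
    manifest <- list(
      generator = "lymphtrial synthetic cohort",
      seed = config$seed, n_patients = config$n_patients,
      mode = config$mode, strict = config$strict,
      gene_frequencies = as.list(config$gene_frequencies),
      subtype_prevalences = as.list(config$subtype_prevalences),
      arm_response_probs = lapply(config$arm_response_probs, as.list),
      response_fill_note = paste(
        "per-arm SD/PD cells are not individually reported;",
        "filled as zanubrutinib SD1/PD5, lenalidomide SD1/PD5,",
        "decitabine SD1/PD2, tofacitinib PD1 to reproduce the overall",
        "SD 3 / PD 13, then normalised over assessed patients"),
      pfs_anchor = as.list(config$pfs_anchor),
      os_anchor = as.list(config$os_anchor),
      censor_window = config$censor_window,
      background_rate = config$background_rate,
      fish_background = as.list(config$fish_background))
    jsonlite::write_json(manifest, man_p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(mut_p, fish_p, clin_p, man_p)
  }
  list(mutations = prof$mutations, fish = prof$fish, clinical = clinical,
       labels = labels, files = files)
}
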