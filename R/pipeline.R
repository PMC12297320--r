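#' @title End-to-end pipeline
#' @description One call running simulate -> classify -> design -> analyze
#'   and writing every artifact (three input TSVs, per-patient subtype
#'   calls, design JSON, endpoint JSON, manifest) to a directory.
#' @name pipeline
NULL

#' Run the full analysis pipeline
#'
#' Either generates a synthetic cohort (when `mutations`/`fish`/`clinical`
#' paths are NULL) or reads user tables, assembles and classifies the
#' cohort, computes the Simon two-stage design for the configured response
#' hypotheses, and summarises endpoints: response rates, Kaplan-Meier
#' 2-year PFS/OS, and (when a `biomarker_gene` is given) a univariate Cox
#' hazard ratio for carriers of a mutation in that gene.
#'
#' @param out_dir Output directory.
#' @param config A [cohort_config()] used when simulating.
#' @param mutations,fish,clinical Optional paths to user-provided tables;
#'   all three must be given together.
#' @param design_spec List with `p0`, `p1`, `alpha`, `beta`,
#'   `dropout_rate`; defaults to the trial's hypotheses (36% vs 56%,
#'   one-sided alpha 0.05, power 80%, 10% dropout).
#' @param biomarker_gene Gene symbol tested for prognostic effect on PFS
#'   (default `CD70`); skipped if carriage is constant in the cohort.
#' @param horizon_months Time point for the survival read-out (default 24).
#' @return Invisibly, a list with `cohort`, `calls`, `frequency`, `design`,
#'   `endpoints`, and `files` written.
#' @export
run_pipeline <- function(out_dir,
                         config = cohort_config(),
                         mutations = NULL, fish = NULL, clinical = NULL,
                         design_spec = list(p0 = 0.36, p1 = 0.56,
                                            alpha = 0.05, beta = 0.20,
                                            dropout_rate = 0.10),
                         biomarker_gene = "CD70",
                         horizon_months = 24) {
  paths <- c(!is.null(mutations), !is.null(fish), !is.null(clinical))
  if (any(paths) && !all(paths)) {
    stop("provide all three of mutations, fish, clinical - or none",
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (!any(paths)) {
    gen <- generate_cohort(config, out_dir = out_dir)
    mutations <- file.path(out_dir, "mutations.tsv")
    fish <- file.path(out_dir, "fish.tsv")
    clinical <- file.path(out_dir, "clinical.tsv")
  }
  var_calls <- read_mutation_table(mutations, quiet = TRUE)
  fish_tab <- read_fish_table(fish)
  clin_tab <- read_clinical_table(clinical)
  cohort <- assemble_cohort(var_calls, fish_tab, clin_tab)

  cls <- classify_cohort(cohort)

  design <- simon_search(design_spec$p0, design_spec$p1,
                         alpha = design_spec$alpha, beta = design_spec$beta,
                         criterion = "optimal")
  enrolment <- inflate_for_dropout(design$n, design_spec$dropout_rate)

  resp <- response_rates(cohort$clinical$response)
  km_pfs <- km_estimate(cohort$clinical$pfs_months,
                        cohort$clinical$pfs_event)
  km_os <- km_estimate(cohort$clinical$os_months, cohort$clinical$os_event)

  cox <- NULL
  if (!is.null(biomarker_gene)) {
    carrier <- vapply(cohort$profiles, function(g) biomarker_gene %in% g,
                      logical(1))
    if (length(unique(carrier)) == 2 && sum(cohort$clinical$pfs_event) > 0) {
      cox <- cox_univariate(cohort$clinical$pfs_months,
                            cohort$clinical$pfs_event,
                            as.numeric(carrier))
    }
  }

  endpoints <- list(
    n = resp$n,
    cr_rate = resp$cr_rate, cr_ci = resp$cr_ci,
    orr = resp$orr, orr_ci = resp$orr_ci,
    pfs_at_horizon = survival_at(km_pfs, horizon_months),
    os_at_horizon = survival_at(km_os, horizon_months),
    horizon_months = horizon_months,
    subtype_frequency = cls$frequency,
    biomarker = if (!is.null(cox)) {
      list(gene = biomarker_gene, endpoint = "PFS", hr = cox$hr,
           ci = cox$ci, p = cox$wald_p)
    })

  design_out <- unclass(design)
  design_out$enrolment_with_dropout <- enrolment
  design_out$dropout_rate <- design_spec$dropout_rate
  files <- write_results(calls = cls$calls,
                         tables = list(design = design_out,
                                       endpoints = endpoints),
                         out_dir = out_dir)
  invisible(list(cohort = cohort, calls = cls$calls,
                 frequency = cls$frequency, design = design,
                 endpoints = endpoints, files = files))
}
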