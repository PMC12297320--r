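# In-code fixtures: small TSV trios written to a temp dir.

write_fixture_trio <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  mut <- c("sample_id\tgene\tvariant_class",
           "S1\tMYD88\tmissense",
           "S1\tCD79B\tnonsense",
           "S1\tMYD88\tframeshift",
           "S2\tNOTCH1\tmissense",
           "S3\tTP53\tmissense",
           "S3\tKMT2D\tsilent")
  fish <- c("sample_id\tbcl2_rearranged\tbcl6_rearranged\tmyc_rearranged",
            "S1\t0\t0\t0",
            "S2\t0\tNA\t0",
            "S3\t1\t0\t0",
            "S4\t0\t1\t0",
            "S5\t0\t0\tNA")
  clin_rows <- function(ids) {
    vapply(seq_along(ids), function(i) {
      paste(ids[i], 60 + i, c("refractory", "relapsed")[1 + i %% 2],
            c("low", "intermediate", "high")[1 + i %% 3], i %% 2,
            c("CR", "PR", "SD", "PD", "CR")[i],
            5 * i, 1, 6 * i, 0, sep = "\t")
    }, character(1))
  }
  clin <- c(paste("sample_id", "age_years", "disease_status", "ipi_risk",
                  "bulky_disease", "response", "pfs_months", "pfs_event",
                  "os_months", "os_event", sep = "\t"),
            clin_rows(paste0("S", 1:5)))
  paths <- list(mutations = file.path(dir, "mutations.tsv"),
                fish = file.path(dir, "fish.tsv"),
                clinical = file.path(dir, "clinical.tsv"))
  writeLines(mut, paths$mutations)
  writeLines(fish, paths$fish)
  writeLines(clin, paths$clinical)
  paths
}

# Exhaustive outcome-enumeration oracle for two-stage designs: walks every
# (x1, x2) pair; independent of design_oc.
oc_brute <- function(design, p) {
  r1 <- design$r1; n1 <- design$n1; r <- design$r; n <- design$n
  n2 <- n - n1
  pet <- 0; reject <- 0; en <- 0
  for (x1 in 0:n1) {
    p1 <- choose(n1, x1) * p^x1 * (1 - p)^(n1 - x1)
    if (x1 <= r1) {
      pet <- pet + p1
      en <- en + p1 * n1
    } else {
      en <- en + p1 * n
      for (x2 in 0:n2) {
        p2 <- choose(n2, x2) * p^x2 * (1 - p)^(n2 - x2)
        if (x1 + x2 > r) reject <- reject + p1 * p2
      }
    }
  }
  list(pet = pet, reject_prob = reject, expected_n = en)
}

# Direct risk-set-counting product-limit oracle, independent of km_estimate.
km_oracle_at <- function(times, events, t0) {
  s <- 1
  for (tt in sort(unique(times[as.logical(events)]))) {
    if (tt > t0) break
    n_i <- sum(times >= tt)
    d_i <- sum(times == tt & as.logical(events))
    s <- s * (1 - d_i / n_i)
  }
  s
}

# Written-out Breslow partial log-likelihood for a binary covariate,
# evaluated on a beta grid (brute-force oracle for cox_univariate).
breslow_grid_mle <- function(times, events, x, grid = seq(-5, 5, 1e-4)) {
  events <- as.logical(events)
  ll <- vapply(grid, function(b) {
    tot <- 0
    for (tt in sort(unique(times[events]))) {
      at <- times >= tt
      d <- times == tt & events
      tot <- tot + b * sum(x[d]) - sum(d) * log(sum(exp(b * x[at])))
    }
    tot
  }, numeric(1))
  grid[which.max(ll)]
}
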