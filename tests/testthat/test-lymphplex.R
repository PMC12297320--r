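test_that("default ruleset carries the published feature sets", {
  rs <- default_ruleset()
  expect_equal(length(rs$MCD_like$mutation_features), 8)
  expect_equal(length(rs$BN2_like$mutation_features), 6)
  expect_equal(rs$BN2_like$fish_features, "BCL6_R")
  expect_equal(rs$N1_like$mutation_features, "NOTCH1")
  expect_equal(length(rs$EZB_like$mutation_features), 11)
  expect_equal(rs$EZB_like$fish_features, "BCL2_R")
  expect_equal(length(rs$ST2_like$mutation_features), 8)
  expect_equal(length(rs$ST2_like$fish_features), 0)
  # 35 mutation features across the panel, no gene in two rules
  all_genes <- unlist(lapply(rs, `[[`, "mutation_features"))
  expect_equal(length(all_genes), 35)
  expect_equal(anyDuplicated(all_genes), 0)
  expect_true(all(all_genes %in% panel_genes()))
})

test_that("feature evaluation intersects genes and positive FISH only", {
  rs <- default_ruleset()
  expect_setequal(
    evaluate_features(c("MYD88", "CD79B"), NULL, rs$MCD_like),
    c("MYD88", "CD79B"))
  expect_equal(length(evaluate_features(character(), NULL, rs$MCD_like)), 0)
  # missing FISH never matches; a mutation in the same rule still does
  fish_missing <- data.frame(bcl2_rearranged = FALSE,
                             bcl6_rearranged = NA, myc_rearranged = FALSE)
  expect_equal(evaluate_features("NOTCH2", fish_missing, rs$BN2_like),
               "NOTCH2")
  fish_pos <- data.frame(bcl2_rearranged = FALSE, bcl6_rearranged = TRUE,
                         myc_rearranged = FALSE)
  expect_setequal(evaluate_features("NOTCH2", fish_pos, rs$BN2_like),
                  c("NOTCH2", "BCL6_R"))
})

test_that("classification follows TP53 precedence, count, then priority", {
  expect_equal(classify_patient(c("TP53", "MYD88", "CD79B"))$subtype,
               "TP53_mut")
  expect_equal(classify_patient("NOTCH1")$subtype, "N1_like")
  expect_equal(classify_patient(character())$subtype, "NOS")
  # 2 MCD features beat 1 BN2 feature
  res <- classify_patient(c("MYD88", "PIM1", "NOTCH2"))
  expect_equal(res$subtype, "MCD_like")
  expect_setequal(res$matched_features, c("MYD88", "PIM1"))
  expect_equal(unname(res$candidates["BN2_like"]), 1L)
  # tie at one feature each: priority order places N1 above MCD
  tie <- classify_patient(c("MYD88", "NOTCH1"))
  expect_equal(tie$subtype, "N1_like")
  expect_true(tie$tie)
  # reversing the configured priority flips the tie
  rev_priority <- rev(names(default_ruleset()))
  expect_equal(classify_patient(c("MYD88", "NOTCH1"),
                                priority = rev_priority)$subtype,
               "MCD_like")
})

test_that("classification invariants hold on random profiles", {
  rs <- default_ruleset()
  pool <- c(panel_genes(), "KMT2C", "TMSB4X", "CD58", "CARD11")
  set.seed(424)
  for (i in 1:200) {
    genes <- sample(pool, rpois(1, 3))
    res <- classify_patient(genes)
    # exactly one subtype, always from the seven-label set
    expect_true(res$subtype %in% c(names(rs), "NOS"))
    # TP53 precedence is absolute
    if ("TP53" %in% genes) expect_equal(res$subtype, "TP53_mut")
    # NOS iff no rule matches (given TP53 absent)
    if (!"TP53" %in% genes) {
      any_match <- any(vapply(rs[-1], function(r)
        length(evaluate_features(genes, NULL, r)) > 0, logical(1)))
      expect_equal(res$subtype == "NOS", !any_match)
    }
    # purity: same input, same output
    expect_identical(res, classify_patient(genes))
    # monotonicity: adding a feature of the winning rule never demotes it
    if (!res$subtype %in% c("NOS", "TP53_mut")) {
      extra <- setdiff(rs[[res$subtype]]$mutation_features, genes)
      if (length(extra)) {
        res2 <- classify_patient(c(genes, extra[1]))
        expect_gte(length(res2$matched_features),
                   length(res$matched_features))
        expect_equal(res2$subtype, res$subtype)
      }
    }
  }
})

test_that("regimen map is total, fixed, and rejects unknown labels", {
  expect_equal(assign_regimen("MCD_like"), "R_ICE_zanubrutinib")
  expect_equal(assign_regimen("BN2_like"), "R_ICE_zanubrutinib")
  expect_equal(assign_regimen("N1_like"), "R_ICE_lenalidomide")
  expect_equal(assign_regimen("NOS"), "R_ICE_lenalidomide")
  expect_equal(assign_regimen("TP53_mut"), "R_ICE_decitabine")
  expect_equal(assign_regimen("EZB_like"), "R_ICE_chidamide")
  expect_equal(assign_regimen("ST2_like"), "R_ICE_tofacitinib")
  expect_error(assign_regimen("A53"), "unknown subtype")
})

test_that("cohort classification returns one call per patient, freqs sum to 1", {
  profiles <- list(S1 = c("TP53", "MYD88"), S2 = "NOTCH1",
                   S3 = c("MYD88", "PIM1", "NOTCH2"), S4 = character())
  clin <- data.frame(sample_id = names(profiles))
  fish <- data.frame(sample_id = names(profiles), bcl2_rearranged = FALSE,
                     bcl6_rearranged = FALSE, myc_rearranged = FALSE)
  cohort <- structure(list(clinical = clin, profiles = profiles,
                           fish = fish, reconciliation = character()),
                      class = "cohort")
  res <- classify_cohort(cohort)
  expect_equal(res$calls$subtype,
               c("TP53_mut", "N1_like", "MCD_like", "NOS"))
  expect_equal(sum(res$frequency$proportion), 1)
  expect_equal(sum(res$frequency$n), 4)
  # arm counts equal sums of their subtypes' counts
  arm_n <- table(res$calls$regimen)
  expect_equal(unname(arm_n["R_ICE_lenalidomide"]), 2L)
})

test_that("labeling concordance excludes NOS and honours exclusion sets", {
  a <- data.frame(sample_id = paste0("S", 1:32),
                  subtype = c(rep("MCD_like", 15), rep("BN2_like", 15),
                              "NOS", "TP53_mut"))
  b <- a
  expect_equal(compare_labelings(a, b)$proportion, 1)
  b$subtype[1] <- "BN2_like"  # one disagreement among 31 non-NOS pairs
  cc <- compare_labelings(a, b)
  expect_equal(cc$n_compared, 31)
  expect_equal(cc$n_agreeing, 30)
  cc2 <- compare_labelings(a, b, exclude = "TP53_mut")
  expect_equal(cc2$n_compared, 30)  # denominator shrinks by the exclusion
  expect_equal(cc2$proportion, 29 / 30)
  expect_error(compare_labelings(a, b[1:5, ]), "different sample sets")
})

test_that("ruleset JSON round-trips", {
  rs <- default_ruleset()
  p <- file.path(withr::local_tempdir(), "rules.json")
  write_ruleset(rs, p)
  rs2 <- read_ruleset(p)
  expect_equal(names(rs2), names(rs))
  for (nm in names(rs)) {
    expect_equal(rs2[[nm]]$mutation_features, rs[[nm]]$mutation_features)
    expect_equal(rs2[[nm]]$fish_features, rs[[nm]]$fish_features)
  }
})
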