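test_that("combining rules reproduce reference calls", {
  tier <- function(codes) combine_evidence(evidence_profile(codes))$tier
  expect_equal(tier(c("PVS1", "PS1")), "Pathogenic")
  expect_equal(tier(c("PS1", "PM1", "PM2")), "LikelyPathogenic")
  expect_equal(tier(c("PM2", "PP3")), "VUS")
  expect_equal(tier(c("BA1", "PS1")), "VUS")          # conflicting
  expect_equal(tier(c("PS1", "PM1", "PM2", "PP3", "PP5")), "Pathogenic")
  expect_equal(tier("BA1"), "Benign")
  expect_equal(tier(c("BS1", "BS2")), "Benign")
  expect_equal(tier(c("BS1", "BP1")), "LikelyBenign")
  expect_equal(tier(c("BP1", "BP4")), "LikelyBenign")
  expect_equal(tier(character()), "VUS")
})

test_that("classification is invariant under code permutation", {
  set.seed(4)
  for (i in 1:25) {
    codes <- sample(all_acmg_codes, sample(2:6, 1))
    t1 <- combine_evidence(evidence_profile(codes))$tier
    t2 <- combine_evidence(evidence_profile(sample(codes)))$tier
    expect_identical(t1, t2)
  }
})

test_that("combine agrees with the clause-enumeration oracle (<=3 codes)", {
  combos <- c(
    list(character()),
    as.list(all_acmg_codes),
    combn(all_acmg_codes, 2, simplify = FALSE),
    combn(all_acmg_codes, 3, simplify = FALSE)
  )
  got <- vapply(combos,
                function(cd) combine_evidence(evidence_profile(cd))$tier,
                character(1))
  want <- vapply(combos, acmg_oracle_tier, character(1))
  expect_identical(got, want)
})

test_that("added pathogenic evidence never moves a call toward benign", {
  rank <- c(Benign = 1, LikelyBenign = 2, VUS = 3, LikelyPathogenic = 4,
            Pathogenic = 5)
  set.seed(8)
  path_codes <- all_acmg_codes[substr(all_acmg_codes, 1, 1) == "P"]
  ben_codes <- setdiff(all_acmg_codes, path_codes)
  for (i in 1:60) {
    codes <- sample(all_acmg_codes, sample(0:4, 1))
    base <- rank[combine_evidence(evidence_profile(codes))$tier]
    add_p <- setdiff(path_codes, codes)
    if (length(add_p) > 0) {
      plus <- rank[combine_evidence(
        evidence_profile(c(codes, sample(add_p, 1))))$tier]
      expect_gte(plus, base)
    }
    add_b <- setdiff(ben_codes, codes)
    if (length(add_b) > 0) {
      minus <- rank[combine_evidence(
        evidence_profile(c(codes, sample(add_b, 1))))$tier]
      expect_lte(minus, base)
    }
  }
})

test_that("strength overrides shift the combined call", {
  # PVS1 downgraded to strong no longer triggers the very-strong clauses
  prof <- evidence_profile(c("PVS1", "PM1"),
                           strengths = c(PVS1 = "strong"))
  expect_equal(combine_evidence(prof)$tier, "LikelyPathogenic")
  prof2 <- evidence_profile(c("PP3", "PM1", "PM2"),
                            strengths = c(PP3 = "moderate"))
  expect_equal(combine_evidence(prof2)$tier, "LikelyPathogenic")  # 3 moderate
})

test_that("VUS+ flags exactly the VUS one supporting criterion short of LP", {
  prof <- evidence_profile(c("PM1", "PM2", "PP3"))
  base <- combine_evidence(prof)
  expect_equal(base$tier, "VUS")
  up <- apply_vus_plus(prof, base)
  expect_true(up$vus_plus)
  expect_equal(up$tier, "VUS")  # tier itself never changes

  weak <- evidence_profile("PM2")
  res <- apply_vus_plus(weak, combine_evidence(weak))
  expect_false(res$vus_plus)

  path_prof <- evidence_profile(c("PVS1", "PS1"))
  path_base <- combine_evidence(path_prof)
  expect_identical(apply_vus_plus(path_prof, path_base), path_base)
})

test_that("automatic evidence assigns only file-computable codes", {
  panel <- test_panel()
  # curated-fixture-style survivor: rare missense, P/LP ClinVar, damaging scores
  c1 <- auto_evidence(make_annotation(
    gene_symbol = "SCN5A", gnomad_af = 1.28e-4,
    clinvar_assertion = "path_or_lp"), panel)
  expect_setequal(c1$code, c("PM2", "PP3", "PP5"))

  common <- auto_evidence(make_annotation(gnomad_af = 0.10), panel)
  expect_true(all(c("BA1", "BS1") %in% common$code))

  lof <- auto_evidence(make_annotation(
    gene_symbol = "MYBPC3", consequence = "stop_gained", gnomad_af = NA,
    polyphen_call = NA, sift_call = NA, cadd_phred = NA, fathmm_call = NA,
    clinvar_assertion = "not_found"), panel)
  expect_setequal(lof$code, c("PVS1", "PM2"))

  # LoF consequence outside a LoF-mechanism gene gets no PVS1
  no_pvs1 <- auto_evidence(make_annotation(
    gene_symbol = "CRYAB", consequence = "stop_gained",
    clinvar_assertion = "not_found"), panel)
  expect_false("PVS1" %in% no_pvs1$code)

  # family-only criteria are never automatic
  expect_false(any(c("PS2", "BS4", "PP1", "PP4") %in%
                     c(c1$code, common$code, lof$code)))

  # conflicting ClinVar contributes neither PP5 nor BP6
  confl <- auto_evidence(make_annotation(clinvar_assertion = "conflicting"),
                         panel)
  expect_false(any(c("PP5", "BP6") %in% confl$code))

  # concordant benign calls earn BP4
  ben <- auto_evidence(make_annotation(
    polyphen_call = "benign", sift_call = "tolerated", cadd_phred = 3,
    fathmm_call = "tolerated", clinvar_assertion = "not_found"), panel)
  expect_true("BP4" %in% ben$code)
})

test_that("callset classification tallies tiers and tolerates empty input", {
  profiles <- list(
    "1:10A>G" = evidence_profile(c("PVS1", "PS1")),
    "1:20A>G" = evidence_profile(c("PM1", "PM2", "PP3")),
    "1:30A>G" = evidence_profile("BA1")
  )
  cls <- classify_callset(profiles)
  expect_equal(cls$label,
               c("Pathogenic", "VUS+", "Benign"))
  expect_equal(as.integer(attr(cls, "summary")[c("Pathogenic", "VUS+")]),
               c(1L, 1L))
  empty <- classify_callset(list())
  expect_equal(nrow(empty), 0L)
})

test_that("manual evidence merges with automatic codes", {
  panel <- test_panel()
  ann <- make_annotation("3:38613773G>A", gene_symbol = "SCN5A",
                         gnomad_af = 1.28e-4,
                         clinvar_assertion = "path_or_lp")
  manual <- data.frame(variant_id = "3:38613773G>A",
                       code = c("PS1", "PM1"), strength = NA_character_,
                       stringsAsFactors = FALSE)
  profs <- build_profiles(ann, panel, manual = manual)
  prof <- profs[["3:38613773G>A"]]
  expect_setequal(prof$code, c("PM2", "PP3", "PP5", "PS1", "PM1"))
  expect_equal(combine_evidence(prof)$tier, "Pathogenic")
})
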