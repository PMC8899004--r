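vocab <- consequence_vocabulary()

test_that("worst consequence follows the severity order", {
  expect_equal(worst_consequence(c("synonymous_variant", "missense_variant")),
               "missense_variant")
  expect_equal(worst_consequence(c("missense_variant", "stop_gained")),
               "stop_gained")
  expect_equal(worst_consequence("start_lost"), "start_lost")
  expect_error(worst_consequence("made_up_term"), "unknown")
  expect_error(worst_consequence(character()), "non-empty")
})

test_that("monomorphism is judged on the subsample, ignoring missing calls", {
  geno <- genotype_matrix(matrix(
    c(0L, 0L, 0L, 1L,
      0L, 1L, 0L, 0L,
      0L, NA, 0L, 2L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("v1", "v2", "v3"), c("a", "b", "c", "d"))
  ))
  sub <- c("a", "b", "c")
  expect_true(is_monomorphic("v1", geno, sub))   # variation only outside
  expect_false(is_monomorphic("v2", geno, sub))
  expect_true(is_monomorphic("v3", geno, sub))   # missing ignored
  expect_error(is_monomorphic("v9", geno, sub), "unknown variant_id")
})

test_that("frequency screen requires rarity in both sources, strictly", {
  expect_true(passes_frequency(make_annotation(gnomad_af = 1.28e-4)))
  expect_true(passes_frequency(make_annotation(gnomad_af = 9.84e-4)))
  expect_false(passes_frequency(make_annotation(gnomad_af = 0.002)))
  expect_false(passes_frequency(make_annotation(gnomad_af = 0.001)))  # strict
  expect_true(passes_frequency(make_annotation(gnomad_af = NA, kg_af = NA)))
  expect_false(passes_frequency(make_annotation(gnomad_af = 1e-5,
                                                kg_af = 0.01)))
})

test_that("in-silico screen matches its truth table over all score states", {
  # independent predicate, written directly from the rule statement
  oracle <- function(pp, cadd, sift, fathmm) {
    b1 <- (is.na(pp) || pp != "benign") && (is.na(cadd) || cadd >= 20)
    b2 <- (is.na(sift) || sift == "deleterious") &&
      (is.na(fathmm) || fathmm == "damaging")
    b1 || b2
  }
  grid <- expand.grid(
    pp = c("benign", "possibly_damaging", "probably_damaging", NA),
    cadd = c(10, 25, NA),
    sift = c("tolerated", "deleterious", NA),
    fathmm = c("tolerated", "damaging", NA),
    stringsAsFactors = FALSE
  )
  got <- passes_in_silico(make_annotation(
    variant_id = sprintf("1:%d A>G", seq_len(nrow(grid))),
    polyphen_call = grid$pp, cadd_phred = grid$cadd,
    sift_call = grid$sift, fathmm_call = grid$fathmm
  ))
  want <- mapply(oracle, grid$pp, grid$cadd, grid$sift, grid$fathmm)
  expect_identical(unname(got), unname(want))
  # an all-missing variant passes
  expect_true(passes_in_silico(make_annotation(
    polyphen_call = NA, cadd_phred = NA, sift_call = NA, fathmm_call = NA)))
})

test_that("ClinVar screen removes only benign-side assertions", {
  passing <- c("pathogenic", "likely_pathogenic", "path_or_lp", "vus",
               "conflicting", "not_found")
  for (lvl in passing) {
    expect_true(passes_clinvar_screen(make_annotation(
      clinvar_assertion = lvl)), info = lvl)
  }
  expect_false(passes_clinvar_screen(make_annotation(
    clinvar_assertion = "benign")))
  expect_false(passes_clinvar_screen(make_annotation(
    clinvar_assertion = "likely_benign")))
})

make_cascade_fixture <- function() {
  # 10 variants: 3 off-panel, then of the 7 on-panel 2 common, 1 synonymous,
  # 1 ClinVar-benign, 3 clean survivors
  ann <- rbind(
    make_annotation("1:11A>G", gene_symbol = "OFFPANEL", gnomad_af = 1e-5),
    make_annotation("1:12A>G", gene_symbol = "OFFPANEL", gnomad_af = 1e-5),
    make_annotation("1:13A>G", gene_symbol = "OFFPANEL", gnomad_af = 1e-5),
    make_annotation("1:14A>G", gnomad_af = 0.01),
    make_annotation("1:15A>G", gnomad_af = 0.002),
    make_annotation("1:16A>G", consequence = "synonymous_variant",
                    gnomad_af = 0),
    make_annotation("1:17A>G", clinvar_assertion = "benign"),
    make_annotation("1:18A>G", gene_symbol = "SCN5A",
                    clinvar_assertion = "path_or_lp", gnomad_af = 1.28e-4),
    make_annotation("1:19A>G", gene_symbol = "CRYAB"),
    make_annotation("1:20A>G", gene_symbol = "MYBPC3")
  )
  variants <- data.frame(
    chrom = "1", pos = 11:20, ref = "A", alt = "G",
    variant_id = ann$variant_id, stringsAsFactors = FALSE
  )
  ids <- sprintf("S%02d", 1:10)
  geno <- matrix(0L, 10, 10, dimnames = list(ann$variant_id, ids))
  geno[, 1] <- 1L  # every variant polymorphic via participant S01
  list(variants = variants, annotations = ann,
       genotypes = genotype_matrix(geno), ids = ids)
}

test_that("the cascade removes each planned variant at its planned stage", {
  fx <- make_cascade_fixture()
  panel <- test_panel()
  tr <- run_cascade(fx$variants, fx$annotations, fx$genotypes, panel, fx$ids)
  expect_equal(tr$counts$n,
               c(10L, 7L, 7L, 7L, 5L, 4L, 4L, 3L))
  expect_setequal(selected_variants(tr),
                  c("1:18A>G", "1:19A>G", "1:20A>G"))
  # curated-fixture-style survivor: SCN5A missense, rare, ClinVar P/LP
  expect_true("1:18A>G" %in% selected_variants(tr))
})

test_that("each cascade stage output is a subset of the previous stage", {
  panel <- test_panel()
  for (seed in c(11, 12)) {
    ann <- random_annotations(120, panel, seed)
    variants <- data.frame(
      chrom = "1", pos = seq_len(nrow(ann)) * 10 + 1, ref = "A", alt = "G",
      variant_id = ann$variant_id, stringsAsFactors = FALSE
    )
    ids <- sprintf("P%02d", 1:20)
    geno <- random_genotypes(ann, ids, seed)
    tr <- run_cascade(variants, ann, geno, panel, ids)
    stages <- tr$stages
    for (k in 2:length(stages)) {
      expect_true(all(stages[[k]] %in% stages[[k - 1]]))
    }
    expect_true(all(diff(tr$counts$n) <= 0))
  }
})

test_that("the final set equals the intersection of per-variant predicates", {
  panel <- test_panel()
  ann <- random_annotations(200, panel, 31)
  variants <- data.frame(
    chrom = "1", pos = seq_len(nrow(ann)) * 10 + 1, ref = "A", alt = "G",
    variant_id = ann$variant_id, stringsAsFactors = FALSE
  )
  ids <- sprintf("P%02d", 1:25)
  geno <- random_genotypes(ann, ids, 31)
  tr <- run_cascade(variants, ann, geno, panel, ids)

  vocab <- consequence_vocabulary()
  expected <- ann$variant_id[vapply(seq_len(nrow(ann)), function(i) {
    a <- ann[i, ]
    a$gene_symbol %in% panel$genes$symbol &&
      !is_monomorphic(a$variant_id, geno, ids) &&
      a$consequence %in% c(vocab$coding, vocab$canonical_splice) &&
      passes_frequency(a, panel$maf_threshold) &&
      !(a$consequence %in% vocab$synonymous) &&
      passes_in_silico(a, panel$cadd_threshold) &&
      passes_clinvar_screen(a)
  }, logical(1))]
  expect_setequal(selected_variants(tr), expected)
})

test_that("making an in-silico score missing never removes a survivor", {
  panel <- test_panel()
  ann <- random_annotations(80, panel, 77)
  variants <- data.frame(
    chrom = "1", pos = seq_len(nrow(ann)) * 10 + 1, ref = "A", alt = "G",
    variant_id = ann$variant_id, stringsAsFactors = FALSE
  )
  ids <- sprintf("P%02d", 1:15)
  geno <- random_genotypes(ann, ids, 77)
  base <- selected_variants(run_cascade(variants, ann, geno, panel, ids))
  for (col in c("polyphen_call", "sift_call", "cadd_phred", "fathmm_call")) {
    blanked <- ann
    blanked[[col]] <- blanked[[col]][NA]
    after <- selected_variants(run_cascade(variants, blanked, geno, panel,
                                           ids))
    expect_true(all(base %in% after), info = col)
  }
})

test_that("a variant with no annotation row drops at the panel stage", {
  fx <- make_cascade_fixture()
  panel <- test_panel()
  ann <- fx$annotations[fx$annotations$variant_id != "1:20A>G", ]
  tr <- run_cascade(fx$variants, ann, fx$genotypes, panel, fx$ids)
  expect_false("1:20A>G" %in% tr$stages$panel)
  expect_setequal(selected_variants(tr), c("1:18A>G", "1:19A>G"))
})
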