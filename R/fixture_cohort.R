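#' Load the packaged nine-variant fixture
#'
#' A packaged case study of nine rare cardiomyopathy-gene variants (seven in
#' the high-fibrosis case group, two in controls) with their published
#' genomic coordinates, gnomAD frequencies and ClinVar assertions, embedded
#' in a deterministic synthetic cohort of 1,164 participants (29 carrying an
#' MI/HF exclusion flag; after exclusion, 420 cases split 139 ECV-only /
#' 139 native-T1-only / 142 both, against explicit thresholds ECV > 28.8%
#' and native T1 > 1,006 ms, and 715 controls). In-silico scores and the
#' manual ACMG evidence codes are synthetic: they were reverse-engineered so
#' that the evidence combiner reproduces the published tier of each variant
#' (1 Pathogenic, 5 Likely pathogenic, 3 VUS+), since the original
#' per-variant curation is not public.
#'
#' @param dir directory in which the pipeline input files are written.
#' @return list with `paths` (vcf, annotations, phenotypes, manual_evidence),
#'   `fixture` (the nine-row metadata table, including `expected_label` and
#'   carrier ids), `thresholds` (explicit case-definition thresholds) and
#'   `case_ids`.
#' @export
load_nine_variant_fixture <- function(dir = tempfile("ninevar")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx_path <- system.file("extdata", "nine_variant_fixture_synthetic.tsv",
                         package = "rarefib", mustWork = TRUE)
  fx <- read.delim(fx_path, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"),
                   colClasses = c(chrom = "character"))
  fx$variant_id <- variant_id(fx$chrom, fx$pos, fx$ref, fx$alt)

  n_cases <- 420L; n_controls <- 715L; n_excluded <- 29L
  n_total <- n_cases + n_controls + n_excluded
  ids <- sprintf("P%04d", seq_len(n_total))

  # deterministic phenotype blocks: 139 ECV-only, 139 T1-only, 142 both,
  # 715 controls, 29 excluded (order fixed; thresholds are explicit)
  category <- c(rep("ecv_only", 139), rep("t1_only", 139), rep("both", 142),
                rep("control", n_controls), rep("excluded", n_excluded))
  ecv <- c(rep(29.4, 139), rep(27.0, 139), rep(29.4, 142),
           rep(25.6, n_controls), rep(26.0, n_excluded))
  t1 <- c(rep(990, 139), rep(1014, 139), rep(1014, 142),
          rep(957, n_controls), rep(960, n_excluded))
  participants <- data.frame(
    id = ids, age_at_cmr = 68, sex = rep(c("F", "M"), length.out = n_total),
    race = "White",
    mi_history = category == "excluded", hf_history = FALSE,
    hct = 0.41, native_t1 = t1, ecv = ecv,
    stringsAsFactors = FALSE
  )

  # one distinct carrier per variant, placed in a participant whose
  # phenotype block matches the variant's published criteria
  first_of <- function(cat, k) which(category == cat)[k]
  carrier_idx <- integer(nrow(fx))
  counters <- c(ecv_only = 0L, t1_only = 0L, both = 0L, control = 0L)
  for (i in seq_len(nrow(fx))) {
    cat_i <- fx$category[i]
    counters[cat_i] <- counters[cat_i] + 1L
    carrier_idx[i] <- first_of(cat_i, counters[cat_i])
  }
  fx$carrier_id <- ids[carrier_idx]

  variants <- data.frame(
    chrom = fx$chrom, pos = fx$pos, ref = fx$ref, alt = fx$alt,
    variant_id = fx$variant_id, stringsAsFactors = FALSE
  )
  geno <- matrix(0L, nrow(fx), n_total,
                 dimnames = list(fx$variant_id, ids))
  geno[cbind(seq_len(nrow(fx)), carrier_idx)] <- 1L
  genotypes <- genotype_matrix(geno)

  annotations <- data.frame(
    variant_id = fx$variant_id, gene_symbol = fx$gene_symbol,
    consequence = fx$consequence, protein_change = fx$protein_change,
    gnomad_af = fx$gnomad_af, kg_af = NA_real_,
    polyphen_call = fx$polyphen_call, sift_call = fx$sift_call,
    cadd_phred = fx$cadd_phred, fathmm_call = fx$fathmm_call,
    clinvar_assertion = fx$clinvar_assertion, stringsAsFactors = FALSE
  )

  manual <- do.call(rbind, lapply(seq_len(nrow(fx)), function(i) {
    if (is.na(fx$manual_codes[i])) return(NULL)
    codes <- strsplit(fx$manual_codes[i], ",")[[1]]
    if (length(codes) == 0L) return(NULL)
    data.frame(variant_id = fx$variant_id[i], code = codes,
               strength = NA_character_, stringsAsFactors = FALSE)
  }))

  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    manual_evidence = file.path(dir, "manual_evidence.tsv")
  )
  write_vcf(variants, genotypes, paths$vcf)
  write_annotations(annotations, paths$annotations)
  write_phenotypes(participants, paths$phenotypes)
  write.table(manual, paths$manual_evidence, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")

  list(
    paths = paths,
    fixture = fx,
    thresholds = list(ecv = 28.8, native_t1 = 1006),
    case_ids = ids[category %in% c("ecv_only", "t1_only", "both")]
  )
}
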