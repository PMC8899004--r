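#' Synthetic cohort specification
#'
#' Parameters for the synthetic multi-ethnic cohort generator. Defaults
#' emulate the study conditions of the source design: 1,164 participants of
#' whom 29 carry an MI/HF exclusion flag; race mix 38/28/23/11
#' White / African American / Hispanic / Chinese American; fibrosis
#' phenotypes drawn from a latent two-component bivariate normal (high-
#' fibrosis component ECV 29.4 (2.5) %, native T1 1,014 (37.1) ms; remainder
#' 25.6 (1.8) % and 957.2 (30.7) ms) with ECV–T1 correlation 0.5 and a 37%
#' high-fibrosis fraction; carrier prevalences 1.2% / 0.1% (P/LP,
#' cases/controls) rising to 1.7% / 0.3% when VUS+ carriers are added.
#'
#' @param n_total cohort size.
#' @param n_excluded participants flagged with MI/HF history.
#' @param race_mix named mixture weights (must sum to 1).
#' @param case_fraction latent high-fibrosis fraction among non-excluded.
#' @param ecv_case,ecv_control,t1_case,t1_control c(mean, sd) pairs.
#' @param rho ECV–native-T1 correlation within each latent component.
#' @param p_plp_case,p_plp_control P/LP carrier prevalence by group.
#' @param p_any_case,p_any_control P/LP + VUS+ carrier prevalence by group.
#' @param decoys plant one decoy variant per filter stage (default TRUE).
#' @param seed RNG seed.
#' @return list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(
    n_total = 1164, n_excluded = 29,
    race_mix = c(White = 0.38, AfricanAmerican = 0.28, Hispanic = 0.23,
                 ChineseAmerican = 0.11),
    case_fraction = 0.37,
    ecv_case = c(29.4, 2.5), ecv_control = c(25.6, 1.8),
    t1_case = c(1014, 37.1), t1_control = c(957.2, 30.7),
    rho = 0.5,
    p_plp_case = 0.012, p_plp_control = 0.001,
    p_any_case = 0.017, p_any_control = 0.003,
    decoys = TRUE, seed = 1) {
  stopifnot(
    n_total >= 8, n_excluded >= 0, n_excluded < n_total,
    abs(sum(race_mix) - 1) < 1e-8,
    case_fraction > 0, case_fraction < 1,
    ecv_case[2] > 0, ecv_control[2] > 0, t1_case[2] > 0, t1_control[2] > 0,
    rho >= -1, rho <= 1,
    p_plp_case >= 0, p_plp_case <= 1,
    p_plp_control >= 0, p_plp_control <= 1,
    p_any_case >= p_plp_case, p_any_control >= p_plp_control,
    p_any_case <= 1, p_any_control <= 1
  )
  structure(as.list(environment()), class = "synthetic_cohort_spec")
}

.rbvn <- function(n, mean1, sd1, mean2, sd2, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(mean1 + sd1 * z1, mean2 + sd2 * z2)
}

.rand_allele_pair <- function() {
  ref <- sample(c("A", "C", "G", "T"), 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  c(ref, alt)
}

#' Generate a complete synthetic cohort
#'
#' Writes the three pipeline inputs (VCF genotypes, annotation TSV,
#' phenotype CSV) plus a manual-evidence TSV and a planted-truth JSON to
#' `dir`. Phenotypes come from the latent two-component model; case status
#' is then derived by the top-quartile union rule on the generated data, and
#' qualifying carrier genotypes are planted at the specified prevalences
#' within the resulting case and control groups (one variant per carrier,
#' heterozygous, in autosomal-dominant panel genes). P/LP variants are
#' stop-gained alleles in LoF-mechanism genes; VUS+ variants are missense
#' alleles whose manual PM1 evidence leaves them one supporting criterion
#' short of Likely Pathogenic. One decoy variant per filter stage is planted
#' to fail exactly that stage. The truth table records every planted fact.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (vcf, annotations, phenotypes, manual_evidence,
#'   truth) and `truth` (the planted-truth list, also written as JSON).
#' @export
generate_cohort <- function(spec, dir = tempfile("cohort")) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n <- spec$n_total
  ids <- sprintf("S%05d", seq_len(n))
  race <- sample(names(spec$race_mix), n, replace = TRUE,
                 prob = spec$race_mix)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.52, 0.48))
  age <- pmin(pmax(round(stats::rnorm(n, 68, 9)), 45), 84)

  excluded_idx <- sample.int(n, spec$n_excluded)
  mi <- hf <- rep(FALSE, n)
  if (spec$n_excluded > 0) {
    which_flag <- sample(c("mi", "hf", "both"), spec$n_excluded,
                         replace = TRUE, prob = c(0.45, 0.45, 0.10))
    mi[excluded_idx] <- which_flag %in% c("mi", "both")
    hf[excluded_idx] <- which_flag %in% c("hf", "both")
  }
  included <- !(mi | hf)

  # latent high-fibrosis component among the non-excluded
  latent_high <- rep(FALSE, n)
  inc_idx <- which(included)
  n_high <- round(spec$case_fraction * length(inc_idx))
  latent_high[sample(inc_idx, n_high)] <- TRUE

  pheno <- matrix(NA_real_, n, 2)
  pheno[latent_high, ] <- .rbvn(sum(latent_high),
                                spec$ecv_case[1], spec$ecv_case[2],
                                spec$t1_case[1], spec$t1_case[2], spec$rho)
  pheno[!latent_high, ] <- .rbvn(sum(!latent_high),
                                 spec$ecv_control[1], spec$ecv_control[2],
                                 spec$t1_control[1], spec$t1_control[2],
                                 spec$rho)
  ecv <- pmin(pmax(pheno[, 1], 5), 60)
  t1 <- pmax(pheno[, 2], 700)
  hct <- pmin(pmax(stats::rnorm(n, 0.41, 0.03), 0.25), 0.55)

  participants <- data.frame(
    id = ids, age_at_cmr = age, sex = sex, race = race,
    mi_history = mi, hf_history = hf, hct = round(hct, 3),
    native_t1 = round(t1, 2), ecv = round(ecv, 3),
    lv_edm_index = round(stats::rnorm(n, 65, 13), 1),
    lv_edv_index = round(stats::rnorm(n, 65, 13), 1),
    lv_esv_index = round(pmax(stats::rnorm(n, 25, 8), 5), 1),
    lv_ed_mvr = round(pmax(stats::rnorm(n, 1.0, 0.2), 0.4), 2),
    ef = round(pmin(pmax(stats::rnorm(n, 62, 7), 30), 80), 1),
    gcs = round(stats::rnorm(n, 18, 2.2), 1),
    gls = round(stats::rnorm(n, 19.7, 2.7), 1),
    lge_scar = stats::rbinom(n, 1, 0.05) == 1,
    stringsAsFactors = FALSE
  )

  inc <- participants[included, , drop = FALSE]
  assignment <- assign_case_status(inc)
  case_ids <- assignment$status$id[assignment$status$status == "case"]
  control_ids <- assignment$status$id[assignment$status$status == "control"]
  n_cases <- length(case_ids)
  n_controls <- length(control_ids)

  n_plp_case <- round(spec$p_plp_case * n_cases)
  n_plp_control <- round(spec$p_plp_control * n_controls)
  n_vus_case <- round((spec$p_any_case - spec$p_plp_case) * n_cases)
  n_vus_control <- round((spec$p_any_control - spec$p_plp_control) *
                           n_controls)
  if (n_plp_case + n_vus_case > n_cases ||
      n_plp_control + n_vus_control > n_controls) {
    stop("infeasible spec: more planted carriers than participants in a group")
  }

  carrier_case <- sample(case_ids, n_plp_case + n_vus_case)
  carrier_control <- sample(control_ids, n_plp_control + n_vus_control)

  panel <- read_panel_config()
  lof_genes <- panel$genes[panel$genes$lof_mechanism &
                             panel$genes$inheritance == "AD", ]
  mis_genes <- panel$genes[!panel$genes$lof_mechanism &
                             panel$genes$inheritance == "AD", ]

  planted <- list()
  .new_variant <- function(gene_row, consequence, clinvar, damaging,
                           gnomad_af, class, carrier_id, expected_label,
                           removal_stage = NA_character_,
                           manual = character()) {
    alleles <- .rand_allele_pair()
    pos <- gene_row$start + sample.int(gene_row$end - gene_row$start, 1)
    list(
      chrom = gene_row$chrom, pos = pos, ref = alleles[1], alt = alleles[2],
      gene_symbol = gene_row$symbol, consequence = consequence,
      clinvar = clinvar, damaging = damaging, gnomad_af = gnomad_af,
      class = class, carrier_id = carrier_id,
      expected_label = expected_label, removal_stage = removal_stage,
      manual = manual
    )
  }

  for (i in seq_len(n_plp_case)) {
    g <- lof_genes[1 + (i - 1) %% nrow(lof_genes), ]
    planted <- c(planted, list(.new_variant(
      g, "stop_gained",
      sample(c("path_or_lp", "vus", "conflicting"), 1), TRUE,
      signif(stats::runif(1, 1e-6, 5e-4), 3), "plp_case",
      carrier_case[i], "Pathogenic"
    )))
  }
  for (i in seq_len(n_plp_control)) {
    g <- lof_genes[1 + (i + 2) %% nrow(lof_genes), ]
    planted <- c(planted, list(.new_variant(
      g, "stop_gained", "vus", TRUE,
      signif(stats::runif(1, 1e-6, 5e-4), 3), "plp_control",
      carrier_control[i], "Pathogenic"
    )))
  }
  for (i in seq_len(n_vus_case)) {
    g <- mis_genes[1 + (i - 1) %% nrow(mis_genes), ]
    planted <- c(planted, list(.new_variant(
      g, "missense_variant", "conflicting", TRUE,
      signif(stats::runif(1, 1e-6, 5e-4), 3), "vusplus_case",
      carrier_case[n_plp_case + i], "VUS+", manual = "PM1"
    )))
  }
  for (i in seq_len(n_vus_control)) {
    g <- mis_genes[1 + (i + 4) %% nrow(mis_genes), ]
    planted <- c(planted, list(.new_variant(
      g, "missense_variant", "conflicting", TRUE,
      signif(stats::runif(1, 1e-6, 5e-4), 3), "vusplus_control",
      carrier_control[n_plp_control + i], "VUS+", manual = "PM1"
    )))
  }

  # a variant that survives every filter but classifies VUS (not counted)
  bystander_id <- if (n_cases > n_plp_case + n_vus_case) {
    setdiff(case_ids, carrier_case)[1]
  } else {
    control_ids[1]
  }
  planted <- c(planted, list(.new_variant(
    mis_genes[10, ], "missense_variant", "vus", TRUE,
    signif(stats::runif(1, 1e-6, 5e-4), 3), "vus_filter_pass",
    bystander_id, "VUS"
  )))

  if (isTRUE(spec$decoys)) {
    decoy_carrier <- function() sample(inc$id, min(3L, nrow(inc)))
    off_panel <- list(symbol = "OFFPANEL1", chrom = "9",
                      start = 90000000, end = 90200000)
    mono_carriers <- if (spec$n_excluded > 0) {
      ids[excluded_idx][seq_len(min(2L, spec$n_excluded))]
    } else {
      character()  # no carriers at all: monomorphic everywhere
    }
    decoy_rows <- list(
      .new_variant(as.data.frame(off_panel), "missense_variant",
                   "conflicting", TRUE, 1e-5, "decoy_off_panel",
                   decoy_carrier(), NA_character_, "panel"),
      .new_variant(mis_genes[12, ], "missense_variant", "conflicting", TRUE,
                   1e-5, "decoy_monomorphic", mono_carriers,
                   NA_character_, "non_monomorphic"),
      .new_variant(mis_genes[13, ], "intron_variant", "not_found", TRUE,
                   1e-5, "decoy_non_coding", decoy_carrier(),
                   NA_character_, "coding_or_splice"),
      .new_variant(mis_genes[14, ], "missense_variant", "conflicting", TRUE,
                   0.002, "decoy_common", decoy_carrier(),
                   NA_character_, "rare"),
      .new_variant(mis_genes[15, ], "synonymous_variant", "not_found", TRUE,
                   1e-5, "decoy_synonymous", decoy_carrier(),
                   NA_character_, "non_synonymous"),
      .new_variant(mis_genes[16, ], "missense_variant", "vus", FALSE,
                   1e-5, "decoy_benign_scores", decoy_carrier(),
                   NA_character_, "in_silico"),
      .new_variant(mis_genes[17, ], "missense_variant", "benign", TRUE,
                   1e-5, "decoy_clinvar_benign", decoy_carrier(),
                   NA_character_, "clinvar_non_benign")
    )
    planted <- c(planted, decoy_rows)
  }

  variants <- do.call(rbind, lapply(planted, function(v) {
    data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
               stringsAsFactors = FALSE)
  }))
  variants$variant_id <- variant_id(variants$chrom, variants$pos,
                                    variants$ref, variants$alt)
  if (anyDuplicated(variants$variant_id)) {
    stop("internal: duplicate planted variant positions; change seed")
  }

  geno <- matrix(0L, nrow(variants), n, dimnames = list(variants$variant_id,
                                                        ids))
  for (i in seq_along(planted)) {
    geno[i, planted[[i]]$carrier_id] <- 1L
  }
  genotypes <- genotype_matrix(geno)

  annotations <- do.call(rbind, lapply(seq_along(planted), function(i) {
    v <- planted[[i]]
    data.frame(
      variant_id = variants$variant_id[i],
      gene_symbol = v$gene_symbol,
      consequence = v$consequence,
      protein_change = "",
      gnomad_af = v$gnomad_af,
      kg_af = NA_real_,
      polyphen_call = if (v$damaging) "probably_damaging" else "benign",
      sift_call = if (v$damaging) "deleterious" else "tolerated",
      cadd_phred = if (v$damaging) round(stats::runif(1, 22, 35), 1) else
        round(stats::runif(1, 1, 10), 1),
      fathmm_call = if (v$damaging) "damaging" else "tolerated",
      clinvar_assertion = v$clinvar,
      stringsAsFactors = FALSE
    )
  }))

  manual <- do.call(rbind, lapply(seq_along(planted), function(i) {
    v <- planted[[i]]
    if (length(v$manual) == 0L) return(NULL)
    data.frame(variant_id = variants$variant_id[i], code = v$manual,
               strength = NA_character_, stringsAsFactors = FALSE)
  }))
  if (is.null(manual)) {
    manual <- data.frame(variant_id = character(), code = character(),
                         strength = character(), stringsAsFactors = FALSE)
  }

  case_map <- stats::setNames(assignment$status$status, assignment$status$id)
  qual_class <- c("plp_case", "plp_control", "vusplus_case",
                  "vusplus_control")
  carrier_of <- function(classes) {
    unique(unlist(lapply(planted, function(v) {
      if (v$class %in% classes) v$carrier_id else NULL
    })))
  }
  plp_carriers <- carrier_of(c("plp_case", "plp_control"))
  any_carriers <- carrier_of(qual_class)
  tab_of <- function(carriers) {
    a <- sum(case_ids %in% carriers); c <- sum(control_ids %in% carriers)
    c(a = a, b = n_cases - a, c = c, d = n_controls - c)
  }

  truth <- list(
    seed = spec$seed,
    n_total = n, n_excluded = spec$n_excluded,
    n_included = nrow(inc), n_cases = n_cases, n_controls = n_controls,
    case_ids = case_ids,
    latent_high_ids = ids[latent_high],
    thresholds = list(
      ecv = assignment$definition$ecv_threshold,
      native_t1 = assignment$definition$native_t1_threshold
    ),
    decomposition = as.list(assignment$decomposition),
    planted = data.frame(
      variant_id = variants$variant_id,
      class = vapply(planted, `[[`, character(1), "class"),
      expected_label = vapply(planted, `[[`, character(1), "expected_label"),
      removal_stage = vapply(planted, `[[`, character(1), "removal_stage"),
      carriers = vapply(planted, function(v)
        paste(v$carrier_id, collapse = ","), character(1)),
      stringsAsFactors = FALSE
    ),
    tables = list(plp = as.list(tab_of(plp_carriers)),
                  plp_vusplus = as.list(tab_of(any_carriers)))
  )

  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    manual_evidence = file.path(dir, "manual_evidence.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(variants, genotypes, paths$vcf)
  write_annotations(annotations, paths$annotations)
  write_phenotypes(participants, paths$phenotypes)
  write.table(manual, paths$manual_evidence, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  list(paths = paths, truth = truth)
}
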