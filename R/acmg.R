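.ACMG_CODES <- c(
  PVS1 = "very_strong",
  PS1 = "strong", PS2 = "strong", PS3 = "strong", PS4 = "strong",
  PM1 = "moderate", PM2 = "moderate", PM3 = "moderate", PM4 = "moderate",
  PM5 = "moderate", PM6 = "moderate",
  PP1 = "supporting", PP2 = "supporting", PP3 = "supporting",
  PP4 = "supporting", PP5 = "supporting",
  BA1 = "stand_alone",
  BS1 = "strong", BS2 = "strong", BS3 = "strong", BS4 = "strong",
  BP1 = "supporting", BP2 = "supporting", BP3 = "supporting",
  BP4 = "supporting", BP5 = "supporting", BP6 = "supporting",
  BP7 = "supporting"
)
.STRENGTHS <- c("stand_alone", "very_strong", "strong", "moderate",
                "supporting")

#' Build an evidence profile
#'
#' A set of ACMG/AMP evidence codes with effective strengths. Each code keeps
#' its native strength unless overridden (e.g. `PVS1` used at strong).
#'
#' @param codes character vector of evidence codes (PVS1, PS1..PS4, PM1..PM6,
#'   PP1..PP5, BA1, BS1..BS4, BP1..BP7); no duplicates.
#' @param strengths optional named character vector of strength overrides
#'   (values among stand_alone/very_strong/strong/moderate/supporting).
#' @param origin provenance per code, `"auto"` or `"manual"`; recycled.
#' @return An object of class `evidence_profile`: data.frame with columns
#'   `code`, `strength`, `origin`.
#' @export
evidence_profile <- function(codes = character(), strengths = NULL,
                             origin = "manual") {
  codes <- as.character(codes)
  unknown <- setdiff(codes, names(.ACMG_CODES))
  if (length(unknown) > 0L) {
    stop("unknown ACMG code(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(codes)) stop("duplicate evidence codes in profile")
  strength <- unname(.ACMG_CODES[codes])
  if (!is.null(strengths)) {
    bad <- setdiff(strengths, .STRENGTHS)
    if (length(bad) > 0L) stop("invalid strength: ", paste(bad, collapse = ", "))
    idx <- match(names(strengths), codes)
    if (anyNA(idx)) stop("strength override for code not in profile")
    strength[idx] <- unname(strengths)
  }
  structure(
    data.frame(code = codes, strength = strength,
               origin = rep_len(origin, length(codes)),
               stringsAsFactors = FALSE),
    class = c("evidence_profile", "data.frame")
  )
}

.is_pathogenic_code <- function(code) substr(code, 1, 1) == "P"

#' Combine ACMG/AMP evidence into a 5-tier classification
#'
#' Implements the guideline combining rules. With pathogenic-side counts
#' (very strong `vs`, strong `s`, moderate `m`, supporting `p`) and
#' benign-side counts (stand-alone `ba`, strong `bs`, supporting `bp`):
#'
#' * Pathogenic: `vs>=1` with (>=1 strong | >=2 moderate | 1 moderate +
#'   1 supporting | >=2 supporting); or `>=2` strong; or 1 strong with
#'   (>=3 moderate | 2 moderate + >=2 supporting | 1 moderate +
#'   >=4 supporting).
#' * Likely pathogenic: `vs>=1` + 1 moderate; 1 strong + 1–2 moderate;
#'   1 strong + >=2 supporting; >=3 moderate; 2 moderate + >=2 supporting;
#'   1 moderate + >=4 supporting.
#' * Benign: `ba>=1` or `>=2` benign-strong.
#' * Likely benign: 1 benign-strong + 1 benign-supporting, or >=2
#'   benign-supporting.
#'
#' Conflicting evidence returns VUS: a profile is conflicting when both
#' sides are substantial, i.e. each side either qualifies under its own
#' rules or carries evidence of strong or greater strength (so BA1 plus a
#' strong pathogenic criterion is VUS, not Benign). Profiles meeting no
#' rule are VUS. Strength overrides are respected (counts use effective
#' strengths).
#'
#' @param profile an [evidence_profile()].
#' @return list of class `acmg_classification` with `tier` (Pathogenic,
#'   LikelyPathogenic, VUS, LikelyBenign, Benign) and `vus_plus` (logical,
#'   meaningful only for VUS).
#' @export
combine_evidence <- function(profile) {
  if (!inherits(profile, "evidence_profile")) {
    stop("'profile' must be an evidence_profile")
  }
  path <- profile[.is_pathogenic_code(profile$code), ]
  ben <- profile[!.is_pathogenic_code(profile$code), ]
  vs <- sum(path$strength == "very_strong")
  s <- sum(path$strength == "strong")
  m <- sum(path$strength == "moderate")
  p <- sum(path$strength == "supporting")
  ba <- sum(ben$strength == "stand_alone")
  bs <- sum(ben$strength %in% c("very_strong", "strong"))
  bp <- sum(ben$strength %in% c("moderate", "supporting"))

  pathogenic <-
    (vs >= 1 && (s >= 1 || m >= 2 || (m >= 1 && p >= 1) || p >= 2)) ||
    vs >= 2 ||
    s >= 2 ||
    (s == 1 && (m >= 3 || (m == 2 && p >= 2) || (m == 1 && p >= 4)))
  likely_pathogenic <-
    (vs >= 1 && m == 1) ||
    (s == 1 && m >= 1 && m <= 2) ||
    (s == 1 && p >= 2) ||
    m >= 3 ||
    (m == 2 && p >= 2) ||
    (m == 1 && p >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs == 1 && bp >= 1) || bp >= 2

  path_side <- pathogenic || likely_pathogenic || vs >= 1 || s >= 1
  benign_side <- benign || likely_benign || ba >= 1 || bs >= 1
  conflict <- (pathogenic || likely_pathogenic || benign || likely_benign) &&
    path_side && benign_side
  tier <- if (conflict) {
    "VUS"  # conflicting evidence
  } else if (pathogenic) {
    "Pathogenic"
  } else if (likely_pathogenic) {
    "LikelyPathogenic"
  } else if (benign) {
    "Benign"
  } else if (likely_benign) {
    "LikelyBenign"
  } else {
    "VUS"
  }
  structure(list(tier = tier, vus_plus = FALSE),
            class = "acmg_classification")
}

#' @export
print.acmg_classification <- function(x, ...) {
  cat(format_tier(x), "\n")
  invisible(x)
}

#' Render a classification as the report vocabulary
#' @param cls an `acmg_classification`.
#' @return "Pathogenic", "Likely pathogenic", "VUS+", "VUS", "Likely benign"
#'   or "Benign".
#' @export
format_tier <- function(cls) {
  switch(cls$tier,
    Pathogenic = "Pathogenic",
    LikelyPathogenic = "Likely pathogenic",
    VUS = if (isTRUE(cls$vus_plus)) "VUS+" else "VUS",
    LikelyBenign = "Likely benign",
    Benign = "Benign"
  )
}

#' Phenotype-supported VUS upgrade (VUS+)
#'
#' A VUS is flagged VUS+ when adding one phenotype-based pathogenic criterion
#' (PP4-like, supporting strength by default) to its evidence would lift the
#' combined call to Likely Pathogenic or Pathogenic. Non-VUS tiers are
#' returned unchanged; the tier itself never changes — only the flag is set.
#'
#' @param profile the [evidence_profile()] the base call was computed from.
#' @param base the base `acmg_classification` from [combine_evidence()].
#' @param strength strength of the hypothetical phenotype criterion.
#' @return an `acmg_classification`.
#' @export
apply_vus_plus <- function(profile, base, strength = "supporting") {
  if (base$tier != "VUS") return(base)
  free <- setdiff(c("PP4", "PP1", "PP2"), profile$code)
  if (length(free) == 0L) return(base)  # phenotype support already counted
  aug <- evidence_profile(
    c(profile$code, free[1]),
    strengths = stats::setNames(
      c(profile$strength, strength), c(profile$code, free[1])
    )
  )
  upgraded <- combine_evidence(aug)
  if (upgraded$tier %in% c("LikelyPathogenic", "Pathogenic")) {
    base$vus_plus <- TRUE
  }
  base
}

#' Automatable evidence codes from file-based annotation
#'
#' Assigns only criteria computable from the annotation record: PVS1 (LoF
#' consequence in a gene with an established LoF mechanism), PM2 (absent or
#' below the rarity threshold in both frequency sources), PP3 (passes the
#' in-silico screen with at least two concordant non-missing damaging calls),
#' BP4 (at least two non-missing benign calls and no damaging call), PP5 /
#' BP6 (ClinVar pathogenic-side / benign-side assertion; conflicting
#' assertions contribute neither), BA1 (gnomAD AF > 0.05) and BS1 (gnomAD AF
#' above a disease-incidence threshold). Family-dependent criteria (PS2, BS4,
#' PP1, PP4) are never assigned automatically; a manual-evidence table can
#' supply them.
#'
#' @param ann single-row annotation data.frame.
#' @param panel `panel_config` (rarity threshold, CADD cutoff, LoF genes).
#' @param vocab consequence vocabulary.
#' @param bs1_threshold gnomAD frequency above which BS1 is assigned
#'   (default 0.001, a generic upper bound on disease incidence).
#' @param use_clinvar_codes assign PP5/BP6 from ClinVar assertions (default
#'   TRUE, mirroring pipelines that weigh ClinVar; set FALSE to follow later
#'   guidance deprecating these codes).
#' @return an [evidence_profile()] with origin `"auto"`.
#' @export
auto_evidence <- function(ann, panel, vocab = consequence_vocabulary(),
                          bs1_threshold = 0.001, use_clinvar_codes = TRUE) {
  stopifnot(nrow(ann) == 1L)
  codes <- character()
  gene <- panel$genes[match(ann$gene_symbol, panel$genes$symbol), ]
  if (!is.na(gene$symbol[1]) && isTRUE(gene$lof_mechanism) &&
      ann$consequence %in% vocab$lof) {
    codes <- c(codes, "PVS1")
  }
  if ((is.na(ann$gnomad_af) || ann$gnomad_af < panel$maf_threshold) &&
      (is.na(ann$kg_af) || ann$kg_af < panel$maf_threshold)) {
    codes <- c(codes, "PM2")
  }
  damaging <- c(
    !is.na(ann$polyphen_call) &&
      ann$polyphen_call %in% c("possibly_damaging", "probably_damaging"),
    !is.na(ann$cadd_phred) && ann$cadd_phred >= panel$cadd_threshold,
    !is.na(ann$sift_call) && ann$sift_call == "deleterious",
    !is.na(ann$fathmm_call) && ann$fathmm_call == "damaging"
  )
  benign_call <- c(
    !is.na(ann$polyphen_call) && ann$polyphen_call == "benign",
    !is.na(ann$cadd_phred) && ann$cadd_phred < panel$cadd_threshold,
    !is.na(ann$sift_call) && ann$sift_call == "tolerated",
    !is.na(ann$fathmm_call) && ann$fathmm_call == "tolerated"
  )
  if (passes_in_silico(ann, panel$cadd_threshold) && sum(damaging) >= 2L) {
    codes <- c(codes, "PP3")
  }
  if (sum(benign_call) >= 2L && sum(damaging) == 0L) {
    codes <- c(codes, "BP4")
  }
  if (use_clinvar_codes) {
    if (ann$clinvar_assertion %in%
        c("pathogenic", "likely_pathogenic", "path_or_lp")) {
      codes <- c(codes, "PP5")
    } else if (ann$clinvar_assertion %in% c("benign", "likely_benign")) {
      codes <- c(codes, "BP6")
    }
  }
  if (!is.na(ann$gnomad_af) && ann$gnomad_af > 0.05) codes <- c(codes, "BA1")
  if (!is.na(ann$gnomad_af) && ann$gnomad_af > bs1_threshold) {
    codes <- c(codes, "BS1")
  }
  evidence_profile(codes, origin = "auto")
}

#' Read a manual-evidence table
#'
#' TSV with columns `variant_id` and `code` (one code per row; optional
#' `strength` column overrides the code's native strength), supplying
#' criteria the automatic assigner cannot compute (PS1, PM1, PM5, ...).
#'
#' @param path TSV path.
#' @return data.frame variant_id/code/strength.
#' @export
read_manual_evidence <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!all(c("variant_id", "code") %in% names(d))) {
    stop("manual evidence table needs variant_id and code columns")
  }
  if (!"strength" %in% names(d)) d$strength <- NA_character_
  unknown <- setdiff(d$code, names(.ACMG_CODES))
  if (length(unknown) > 0L) {
    stop("unknown ACMG code(s): ", paste(unknown, collapse = ", "))
  }
  d[c("variant_id", "code", "strength")]
}

#' Evidence profiles for a set of variants
#'
#' Merges automatic (annotation-derived) and manual codes per variant;
#' a manual row for a code already auto-assigned overrides its strength.
#'
#' @param annotations annotation data.frame.
#' @param panel `panel_config`.
#' @param manual optional data.frame from [read_manual_evidence()].
#' @param ... passed to [auto_evidence()].
#' @return named list of [evidence_profile()], keyed by variant_id.
#' @export
build_profiles <- function(annotations, panel, manual = NULL, ...) {
  out <- lapply(seq_len(nrow(annotations)), function(i) {
    prof <- auto_evidence(annotations[i, , drop = FALSE], panel, ...)
    vid <- annotations$variant_id[i]
    if (!is.null(manual)) {
      man <- manual[manual$variant_id == vid, , drop = FALSE]
      for (j in seq_len(nrow(man))) {
        if (man$code[j] %in% prof$code) {
          k <- match(man$code[j], prof$code)
          if (!is.na(man$strength[j])) prof$strength[k] <- man$strength[j]
          prof$origin[k] <- "manual"
        } else {
          strength <- if (is.na(man$strength[j])) {
            unname(.ACMG_CODES[man$code[j]])
          } else {
            man$strength[j]
          }
          prof <- rbind(prof, data.frame(
            code = man$code[j], strength = strength, origin = "manual",
            stringsAsFactors = FALSE
          ))
        }
      }
      class(prof) <- c("evidence_profile", "data.frame")
    }
    prof
  })
  names(out) <- annotations$variant_id
  out
}

#' Classify a call set
#'
#' Applies [combine_evidence()] then [apply_vus_plus()] to each profile.
#'
#' @param profiles named list of evidence profiles keyed by variant_id.
#' @param vus_plus_strength strength of the hypothetical phenotype criterion.
#' @return data.frame with columns `variant_id`, `tier`, `vus_plus`,
#'   `label` (report vocabulary) and `codes` (collapsed evidence string);
#'   attribute `summary` holds counts by label.
#' @export
classify_callset <- function(profiles, vus_plus_strength = "supporting") {
  if (length(profiles) == 0L) {
    out <- data.frame(variant_id = character(), tier = character(),
                      vus_plus = logical(), label = character(),
                      codes = character(), stringsAsFactors = FALSE)
    attr(out, "summary") <- table(factor(character()))
    return(out)
  }
  rows <- lapply(names(profiles), function(vid) {
    prof <- profiles[[vid]]
    cls <- apply_vus_plus(prof, combine_evidence(prof),
                          strength = vus_plus_strength)
    data.frame(
      variant_id = vid, tier = cls$tier, vus_plus = cls$vus_plus,
      label = format_tier(cls),
      codes = paste(prof$code, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- table(out$label)
  out
}

#' Write classifications as TSV
#' @param classifications data.frame from [classify_callset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(classifications, path) {
  write.table(classifications, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
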