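#' Is a variant monomorphic within a subsample?
#'
#' A variant is monomorphic in the phenotyped subsample when all non-missing
#' genotype codes within that subsample are equal (missing calls are ignored;
#' an all-missing subsample is treated as monomorphic).
#'
#' @param vid variant identifier (must be a row of `genotypes`).
#' @param genotypes a `genotype_matrix`.
#' @param subsample_ids participant ids forming the phenotyped subsample.
#' @return logical scalar.
#' @export
is_monomorphic <- function(vid, genotypes, subsample_ids) {
  if (!vid %in% rownames(genotypes)) stop("unknown variant_id: ", vid)
  missing_ids <- setdiff(subsample_ids, colnames(genotypes))
  if (length(missing_ids) > 0L) {
    stop("subsample ids absent from genotype matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  g <- genotypes[vid, subsample_ids]
  g <- g[!is.na(g)]
  length(unique(g)) <= 1L
}

#' Rarity screen against both population frequency sources
#'
#' Passes when the variant is rarer than `threshold` in gnomAD AND in
#' 1000 Genomes, treating a missing frequency as "not observed" (passes).
#' Strict inequality, matching a "frequency of < 0.1%" style rule.
#'
#' @param annotations annotation data.frame (vectorized over rows).
#' @param threshold allele-frequency cutoff in (0,1), default 0.001.
#' @return logical vector.
#' @export
passes_frequency <- function(annotations, threshold = 0.001) {
  stopifnot(threshold > 0, threshold < 1)
  g <- annotations$gnomad_af
  k <- annotations$kg_af
  (is.na(g) | g < threshold) & (is.na(k) | k < threshold)
}

#' In-silico deleteriousness screen
#'
#' Two tool branches, each lenient to missing predictions:
#' branch 1 — PolyPhen damaging-spectrum (or no call) AND CADD phred at or
#' above the cutoff (or no score); branch 2 — SIFT deleterious (or no call)
#' AND FATHMM damaging (or no call). A variant passes if either branch holds;
#' a variant with no prediction from any tool passes.
#'
#' @param annotations annotation data.frame (vectorized over rows).
#' @param cadd_threshold CADD phred cutoff, default 20 (the top percentile
#'   of genome-wide scores).
#' @param polyphen_strict if `TRUE` only `probably_damaging` counts as
#'   damaging; by default `possibly_damaging` counts too.
#' @return logical vector.
#' @export
passes_in_silico <- function(annotations, cadd_threshold = 20,
                             polyphen_strict = FALSE) {
  damaging_pp <- if (polyphen_strict) "probably_damaging" else
    c("possibly_damaging", "probably_damaging")
  pp <- annotations$polyphen_call
  cadd <- annotations$cadd_phred
  sift <- annotations$sift_call
  fathmm <- annotations$fathmm_call
  branch1 <- (is.na(pp) | pp %in% damaging_pp) &
    (is.na(cadd) | cadd >= cadd_threshold)
  branch2 <- (is.na(sift) | sift == "deleterious") &
    (is.na(fathmm) | fathmm == "damaging")
  branch1 | branch2
}

#' ClinVar non-benign screen
#'
#' Removes only variants asserted benign or likely benign; pathogenic,
#' likely pathogenic, VUS, conflicting and absent-from-ClinVar variants all
#' pass (absence of evidence is not benign evidence).
#'
#' @param annotations annotation data.frame (vectorized over rows).
#' @return logical vector.
#' @export
passes_clinvar_screen <- function(annotations) {
  !(annotations$clinvar_assertion %in% c("benign", "likely_benign"))
}

.CASCADE_STAGES <- c(
  "panel", "non_monomorphic", "coding_or_splice", "rare",
  "non_synonymous", "in_silico", "clinvar_non_benign"
)

#' Run the rare-variant prioritization cascade
#'
#' Applies, in order: gene-panel membership; non-monomorphism within the
#' phenotyped subsample; coding-or-canonical-splice consequence; rarity in
#' both frequency sources; non-synonymous consequence; in-silico
#' deleteriousness; ClinVar non-benign. Returns the full funnel (per-stage
#' surviving sets and counts).
#'
#' Panel membership is judged from the annotation's gene symbol; a variant
#' with no annotation row cannot be placed in a panel gene and drops at the
#' panel stage. An annotated, on-panel variant whose annotation row is lost
#' downstream raises an error naming the variant.
#'
#' @param variants variant data.frame from [read_vcf()].
#' @param annotations annotation data.frame from [read_annotations()].
#' @param genotypes `genotype_matrix`.
#' @param panel `panel_config`.
#' @param subsample_ids ids of the phenotyped subsample used for the
#'   monomorphism stage.
#' @param vocab consequence vocabulary.
#' @return An object of class `filter_trace`: list with `stages` (named list
#'   of surviving variant_id vectors, in cascade order, preceded by `input`)
#'   and `counts` (data.frame stage/n/removed).
#' @export
run_cascade <- function(variants, annotations, genotypes, panel,
                        subsample_ids, vocab = consequence_vocabulary()) {
  ids <- variants$variant_id
  ann <- annotations[match(ids, annotations$variant_id), , drop = FALSE]

  surviving <- list(input = ids)
  keep <- !is.na(ann$variant_id) & ann$gene_symbol %in% panel$genes$symbol
  surviving$panel <- ids[keep]

  .require_annotation <- function(live) {
    miss <- live[is.na(match(live, annotations$variant_id))]
    if (length(miss) > 0L) {
      stop("missing annotation for surviving variant(s): ",
           paste(miss, collapse = ", "))
    }
  }
  .require_annotation(surviving$panel)

  mono <- vapply(surviving$panel, is_monomorphic, logical(1),
                 genotypes = genotypes, subsample_ids = subsample_ids)
  surviving$non_monomorphic <- surviving$panel[!mono]

  stage_ann <- function(live) {
    annotations[match(live, annotations$variant_id), , drop = FALSE]
  }

  live <- surviving$non_monomorphic
  a <- stage_ann(live)
  keep <- a$consequence %in% c(vocab$coding, vocab$canonical_splice)
  surviving$coding_or_splice <- live[keep]

  live <- surviving$coding_or_splice
  a <- stage_ann(live)
  surviving$rare <- live[passes_frequency(a, panel$maf_threshold)]

  live <- surviving$rare
  a <- stage_ann(live)
  surviving$non_synonymous <- live[!(a$consequence %in% vocab$synonymous)]

  live <- surviving$non_synonymous
  a <- stage_ann(live)
  surviving$in_silico <- live[passes_in_silico(a, panel$cadd_threshold)]

  live <- surviving$in_silico
  a <- stage_ann(live)
  surviving$clinvar_non_benign <- live[passes_clinvar_screen(a)]

  n <- vapply(surviving, length, integer(1))
  counts <- data.frame(
    stage = names(surviving),
    n = unname(n),
    removed = c(0L, -diff(unname(n))),
    stringsAsFactors = FALSE
  )
  structure(list(stages = surviving, counts = counts), class = "filter_trace")
}

#' Final surviving set of a filter trace
#' @param trace a `filter_trace`.
#' @return character vector of variant_ids surviving every stage.
#' @export
selected_variants <- function(trace) {
  trace$stages$clinvar_non_benign
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("Variant prioritization funnel\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Serialize a filter trace to JSON
#' @param trace a `filter_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_trace <- function(trace, path) {
  jsonlite::write_json(
    list(counts = trace$counts, stages = trace$stages),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
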