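#' Consequence vocabulary
#'
#' Controlled vocabulary of sequence-ontology consequence terms with a total
#' severity order (most severe first, VEP-style ranking) and the subsets the
#' filter cascade needs: coding terms, canonical splice-site terms, synonymous
#' terms and predicted loss-of-function (LoF) terms.
#'
#' @param extra_terms optional character vector of additional terms appended
#'   at the benign end of the severity order.
#' @return An object of class `consequence_vocabulary`: a list with elements
#'   `severity` (character, most severe first), `coding`, `canonical_splice`,
#'   `synonymous` and `lof`.
#' @examples
#' v <- consequence_vocabulary()
#' worst_consequence(c("synonymous_variant", "missense_variant"), v)
#' @export
consequence_vocabulary <- function(extra_terms = character()) {
  severity <- c(
    "splice_acceptor_variant",
    "splice_donor_variant",
    "stop_gained",
    "frameshift_variant",
    "stop_lost",
    "start_lost",
    "inframe_insertion",
    "inframe_deletion",
    "missense_variant",
    "protein_altering_variant",
    "splice_region_variant",
    "synonymous_variant",
    "5_prime_UTR_variant",
    "3_prime_UTR_variant",
    "non_coding_transcript_exon_variant",
    "intron_variant",
    "upstream_gene_variant",
    "downstream_gene_variant",
    "intergenic_variant"
  )
  severity <- c(severity, setdiff(extra_terms, severity))
  vocab <- list(
    severity = severity,
    coding = c(
      "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
      "inframe_insertion", "inframe_deletion", "missense_variant",
      "protein_altering_variant", "synonymous_variant"
    ),
    canonical_splice = c("splice_acceptor_variant", "splice_donor_variant"),
    synonymous = "synonymous_variant",
    lof = c(
      "stop_gained", "frameshift_variant", "start_lost",
      "splice_acceptor_variant", "splice_donor_variant"
    )
  )
  stopifnot(all(vocab$lof %in% c(vocab$coding, vocab$canonical_splice)))
  class(vocab) <- "consequence_vocabulary"
  vocab
}

#' Worst consequence across transcripts
#'
#' Reduces the per-transcript consequence terms of one variant to the single
#' most severe term under the vocabulary's severity order.
#'
#' @param terms non-empty character vector of consequence terms.
#' @param vocab a [consequence_vocabulary()].
#' @return The maximal-severity term (length-1 character).
#' @export
worst_consequence <- function(terms, vocab = consequence_vocabulary()) {
  if (length(terms) == 0L) stop("'terms' must be non-empty")
  unknown <- setdiff(terms, vocab$severity)
  if (length(unknown) > 0L) {
    stop("unknown consequence term(s): ", paste(unknown, collapse = ", "))
  }
  vocab$severity[min(match(terms, vocab$severity))]
}
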