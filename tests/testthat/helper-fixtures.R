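# Shared builders and independent oracles used across test files.

# one annotation row with sensible defaults, overridable field by field
make_annotation <- function(variant_id = "1:100A>G", gene_symbol = "MYH7",
                            consequence = "missense_variant",
                            protein_change = "p.Arg1His",
                            gnomad_af = 1e-4, kg_af = NA_real_,
                            polyphen_call = "probably_damaging",
                            sift_call = "deleterious", cadd_phred = 25,
                            fathmm_call = "damaging",
                            clinvar_assertion = "vus") {
  data.frame(variant_id = variant_id, gene_symbol = gene_symbol,
             consequence = consequence, protein_change = protein_change,
             gnomad_af = gnomad_af, kg_af = kg_af,
             polyphen_call = polyphen_call, sift_call = sift_call,
             cadd_phred = cadd_phred, fathmm_call = fathmm_call,
             clinvar_assertion = clinvar_assertion, stringsAsFactors = FALSE)
}

# write a VCF from raw lines (for parser edge cases)
write_vcf_lines <- function(body, samples = "S1") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), path)
  path
}

test_panel <- function() read_panel_config()

# --- independent ACMG combining-rule oracle ------------------------------
# Literal clause-by-clause enumeration of the guideline's disjunctions,
# working from code prefixes only (native strengths, no overrides).
acmg_oracle_tier <- function(codes) {
  vs <- sum(codes == "PVS1")
  s <- sum(grepl("^PS", codes))
  m <- sum(grepl("^PM", codes))
  p <- sum(grepl("^PP", codes))
  ba <- sum(codes == "BA1")
  bs <- sum(grepl("^BS", codes))
  bp <- sum(grepl("^BP", codes))
  path_clauses <- c(
    vs >= 1 && s >= 1,
    vs >= 1 && m >= 2,
    vs >= 1 && m == 1 && p >= 1,
    vs >= 1 && p >= 2,
    vs >= 2,
    s >= 2,
    s == 1 && m >= 3,
    s == 1 && m == 2 && p >= 2,
    s == 1 && m == 1 && p >= 4
  )
  lp_clauses <- c(
    vs == 1 && m == 1,
    s == 1 && (m == 1 || m == 2),
    s == 1 && p >= 2,
    m >= 3,
    m == 2 && p >= 2,
    m == 1 && p >= 4
  )
  b_clauses <- c(ba >= 1, bs >= 2)
  lb_clauses <- c(bs == 1 && bp >= 1, bp >= 2)
  qualifies <- any(path_clauses) || any(lp_clauses) ||
    any(b_clauses) || any(lb_clauses)
  path_substantial <- any(path_clauses) || any(lp_clauses) ||
    vs >= 1 || s >= 1
  ben_substantial <- any(b_clauses) || any(lb_clauses) ||
    ba >= 1 || bs >= 1
  if (qualifies && path_substantial && ben_substantial) return("VUS")
  if (any(path_clauses)) return("Pathogenic")
  if (any(lp_clauses)) return("LikelyPathogenic")
  if (any(b_clauses)) return("Benign")
  if (any(lb_clauses)) return("LikelyBenign")
  "VUS"
}

all_acmg_codes <- c(
  "PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
  "BA1", paste0("BS", 1:4), paste0("BP", 1:7)
)

# --- independent exact-test oracle ---------------------------------------
# direct summation of stats::dhyper point probabilities (minimum-likelihood
# two-sided definition), independent of the package's log-factorial route
fisher_oracle <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  if (n1 == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n2):min(k, n1)
  probs <- stats::dhyper(support, n1, n2, k)
  p_obs <- stats::dhyper(a, n1, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# random small annotation sets for cascade property tests
random_annotations <- function(n, panel, seed) {
  set.seed(seed)
  vocab <- consequence_vocabulary()
  genes <- c(sample(panel$genes$symbol, ceiling(n * 0.7), replace = TRUE),
             rep("NOTAPANELGENE", n - ceiling(n * 0.7)))
  genes <- sample(genes)
  data.frame(
    variant_id = sprintf("1:%d%s>%s", seq_len(n) * 10 + 1, "A", "G"),
    gene_symbol = genes,
    consequence = sample(vocab$severity, n, replace = TRUE),
    protein_change = "",
    gnomad_af = ifelse(runif(n) < 0.2, NA,
                       signif(10^runif(n, -6, -1.5), 3)),
    kg_af = ifelse(runif(n) < 0.7, NA, signif(10^runif(n, -6, -2), 3)),
    polyphen_call = sample(c("benign", "possibly_damaging",
                             "probably_damaging", NA), n, replace = TRUE),
    sift_call = sample(c("tolerated", "deleterious", NA), n, replace = TRUE),
    cadd_phred = ifelse(runif(n) < 0.3, NA, round(runif(n, 0, 40), 1)),
    fathmm_call = sample(c("tolerated", "damaging", NA), n, replace = TRUE),
    clinvar_assertion = sample(
      c("pathogenic", "likely_pathogenic", "path_or_lp", "vus",
        "conflicting", "likely_benign", "benign", "not_found"),
      n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# genotypes for random_annotations: mostly polymorphic, a few monomorphic
random_genotypes <- function(annotations, participant_ids, seed) {
  set.seed(seed + 1)
  n <- nrow(annotations)
  geno <- matrix(0L, n, length(participant_ids),
                 dimnames = list(annotations$variant_id, participant_ids))
  for (i in seq_len(n)) {
    if (runif(1) < 0.15) next  # monomorphic all-reference
    k <- sample(1:3, 1)
    geno[i, sample(length(participant_ids), k)] <- sample(1:2, k,
                                                          replace = TRUE)
  }
  genotype_matrix(geno)
}
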