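#' @importFrom utils read.delim read.csv write.csv write.table
NULL

.CLINVAR_LEVELS <- c(
  "pathogenic", "likely_pathogenic", "path_or_lp", "vus", "conflicting",
  "likely_benign", "benign", "not_found"
)
.POLYPHEN_LEVELS <- c("benign", "possibly_damaging", "probably_damaging")
.SIFT_LEVELS <- c("tolerated", "deleterious")
.FATHMM_LEVELS <- c("tolerated", "damaging")

#' Canonical variant identifier
#'
#' Renders a variant as `"chrom:posREF>ALT"` (e.g. `"3:38613773G>A"`), the key
#' used to join genotypes, annotations and classifications.
#'
#' @param chrom chromosome label, `pos` 1-based position, `ref`/`alt` alleles.
#' @param pos,ref,alt see `chrom`.
#' @return character vector of identifiers.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d%s>%s", chrom, as.integer(pos), ref, alt)
}

#' Read genotypes from a VCF file
#'
#' Consumes the CHROM/POS/REF/ALT/GT subset of VCF v4.x. Multi-allelic sites
#' are decomposed into one biallelic record per alternate allele; the genotype
#' code for each record is the count of that alternate allele in the call
#' (0, 1, 2, or `NA` for missing/partial calls). QUAL and FILTER are ignored:
#' quality recalibration is assumed to have happened upstream.
#'
#' @param path path to an (uncompressed or gzipped) VCF file with a GT field.
#' @return A list with `variants` (data.frame: chrom, pos, ref, alt,
#'   variant_id) and `genotypes` (a `genotype_matrix`: integer matrix, one row
#'   per variant_id, one column per participant).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) {
    return(list(
      variants = data.frame(
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), variant_id = character(),
        stringsAsFactors = FALSE
      ),
      genotypes = genotype_matrix(
        matrix(integer(), nrow = 0, ncol = ncol(vcf@gt) - 1L,
               dimnames = list(NULL, colnames(vcf@gt)[-1]))
      )
    ))
  }
  format_col <- vcf@gt[, 1L]
  if (!all(vapply(strsplit(format_col, ":"), function(f) "GT" %in% f, TRUE))) {
    stop("VCF record without GT in FORMAT field")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  sample_ids <- colnames(gt)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs in VCF header")

  chrom <- vcf@fix[, "CHROM"]
  pos <- as.integer(vcf@fix[, "POS"])
  ref <- vcf@fix[, "REF"]
  alt_field <- vcf@fix[, "ALT"]
  if (any(is.na(pos)) || any(pos < 1L)) stop("malformed POS in VCF")

  out_var <- vector("list", length(chrom))
  out_gt <- vector("list", length(chrom))
  for (i in seq_along(chrom)) {
    alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gt[i, ], "[/|]")
    rows <- matrix(NA_integer_, nrow = length(alts), ncol = length(sample_ids))
    for (k in seq_along(alts)) {
      rows[k, ] <- vapply(alleles, function(a) {
        if (length(a) == 0L || any(a == ".") || anyNA(a)) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
    }
    # fully missing call strings come through extract.gt as NA
    rows[, is.na(gt[i, ])] <- NA_integer_
    out_var[[i]] <- data.frame(
      chrom = unname(chrom[i]), pos = unname(pos[i]), ref = unname(ref[i]),
      alt = unname(alts), stringsAsFactors = FALSE, row.names = NULL
    )
    out_gt[[i]] <- rows
  }
  variants <- do.call(rbind, out_var)
  if (any(variants$ref == variants$alt)) stop("REF equal to ALT in VCF record")
  variants$variant_id <- variant_id(
    variants$chrom, variants$pos, variants$ref, variants$alt
  )
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant records after decomposition: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
               collapse = ", "))
  }
  geno <- do.call(rbind, out_gt)
  rownames(geno) <- variants$variant_id
  colnames(geno) <- sample_ids
  list(variants = variants, genotypes = genotype_matrix(geno))
}

#' Genotype matrix container
#'
#' @param m integer matrix, rows named by variant_id, columns by participant
#'   id; entries in \{0, 1, 2, NA\}.
#' @return the matrix with class `genotype_matrix`.
#' @export
genotype_matrix <- function(m) {
  storage.mode(m) <- "integer"
  ok <- is.na(m) | (m >= 0L & m <= 2L)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(colnames(m))) stop("duplicate participant ids")
  structure(m, class = c("genotype_matrix", "matrix"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d variants x %d participants\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Write genotypes as a minimal VCF
#'
#' Inverse of [read_vcf()] for biallelic records; round-trips variant records
#' and genotype codes exactly.
#'
#' @param variants data.frame as returned by [read_vcf()].
#' @param genotypes `genotype_matrix` aligned with `variants`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path) {
  stopifnot(nrow(variants) == nrow(genotypes))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L],
                   nrow = nrow(genotypes))
  gt_str[is.na(genotypes)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t")
  ), con)
  if (nrow(variants) > 0L) {
    body <- cbind(
      variants$chrom, variants$pos, ".", variants$ref, variants$alt,
      ".", "PASS", ".", "GT", gt_str
    )
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read the per-variant annotation table
#'
#' Tab-separated table with one row per variant carrying the worst consequence
#' across transcripts, population frequencies and in-silico scores. Required
#' columns: `variant_id`, `gene_symbol`, `consequence`, `protein_change`,
#' `gnomad_af`, `kg_af`, `polyphen_call`, `sift_call`, `cadd_phred`,
#' `fathmm_call`, `clinvar_assertion`. Empty cells become `NA`. Numeric
#' PolyPhen/SIFT scores, if supplied instead of categorical calls, are binned
#' by the published cutoffs (PolyPhen >= 0.908 probably damaging, >= 0.446
#' possibly damaging; SIFT < 0.05 deleterious).
#'
#' @param path path to the TSV file.
#' @param vocab consequence vocabulary used to validate the consequence column.
#' @return data.frame of annotation records keyed by `variant_id`.
#' @export
read_annotations <- function(path, vocab = consequence_vocabulary()) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = c("", "NA"))
  required <- c("variant_id", "gene_symbol", "consequence", "protein_change",
                "gnomad_af", "kg_af", "polyphen_call", "sift_call",
                "cadd_phred", "fathmm_call", "clinvar_assertion")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0L) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(d$variant_id)) {
    stop("duplicate variant_id in annotations: ",
         paste(unique(d$variant_id[duplicated(d$variant_id)]), collapse = ", "))
  }
  d$gnomad_af <- .parse_frequency(d$gnomad_af, "gnomad_af")
  d$kg_af <- .parse_frequency(d$kg_af, "kg_af")
  d$cadd_phred <- as.numeric(d$cadd_phred)
  if (any(d$cadd_phred < 0, na.rm = TRUE)) stop("negative CADD phred score")
  d$polyphen_call <- .bin_polyphen(d$polyphen_call)
  d$sift_call <- .bin_sift(d$sift_call)
  bad_f <- !is.na(d$fathmm_call) & !(d$fathmm_call %in% .FATHMM_LEVELS)
  if (any(bad_f)) stop("invalid fathmm_call: ", d$fathmm_call[bad_f][1])
  d$clinvar_assertion[is.na(d$clinvar_assertion)] <- "not_found"
  bad_c <- !(d$clinvar_assertion %in% .CLINVAR_LEVELS)
  if (any(bad_c)) stop("invalid clinvar_assertion: ",
                       d$clinvar_assertion[bad_c][1])
  unknown <- setdiff(stats::na.omit(d$consequence), vocab$severity)
  if (length(unknown) > 0L) {
    stop("unknown consequence term(s): ", paste(unknown, collapse = ", "))
  }
  d$protein_change[is.na(d$protein_change)] <- ""
  d[required]
}

.parse_frequency <- function(x, what) {
  v <- as.numeric(x)
  bad <- !is.na(v) & (v < 0 | v > 1)
  if (any(bad)) {
    stop(sprintf("%s outside [0,1]: %s", what, x[bad][1]))
  }
  v
}

.bin_polyphen <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  is_num <- !is.na(num)
  x[is_num] <- ifelse(num[is_num] >= 0.908, "probably_damaging",
                      ifelse(num[is_num] >= 0.446, "possibly_damaging",
                             "benign"))
  bad <- !is.na(x) & !(x %in% .POLYPHEN_LEVELS)
  if (any(bad)) stop("invalid polyphen_call: ", x[bad][1])
  x
}

.bin_sift <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  is_num <- !is.na(num)
  x[is_num] <- ifelse(num[is_num] < 0.05, "deleterious", "tolerated")
  bad <- !is.na(x) & !(x %in% .SIFT_LEVELS)
  if (any(bad)) stop("invalid sift_call: ", x[bad][1])
  x
}

#' Write an annotation table
#' @param annotations data.frame as returned by [read_annotations()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

.PHENO_NUMERIC <- c(
  "age_at_cmr", "hct", "t1_myo_pre", "t1_myo_post", "t1_blood_pre",
  "t1_blood_post", "native_t1", "ecv", "lv_edm_index", "lv_edv_index",
  "lv_esv_index", "lv_ed_mvr", "ef", "gcs", "gls"
)
.PHENO_LOGICAL <- c("mi_history", "hf_history", "lge_scar")

#' Read the participant phenotype table
#'
#' CSV with one row per participant: demographics, MI/HF history flags,
#' hematocrit, T1-mapping values (native and post-contrast myocardial and
#' blood T1 in ms), ECV (percent, optional — derived from T1 values when
#' absent) and optional left-ventricular features. Booleans accept
#' 0/1/TRUE/FALSE (case-insensitive).
#'
#' @param path path to the CSV file.
#' @return data.frame of participants keyed by `id`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                na.strings = c("", "NA"))
  if (!"id" %in% names(d)) stop("phenotype table lacks 'id' column")
  if (anyDuplicated(d$id)) {
    stop("duplicate participant id: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  }
  for (col in intersect(.PHENO_NUMERIC, names(d))) {
    d[[col]] <- as.numeric(d[[col]])
  }
  for (col in intersect(.PHENO_LOGICAL, names(d))) {
    d[[col]] <- .parse_logical(d[[col]], col)
  }
  t1_cols <- intersect(
    c("t1_myo_pre", "t1_myo_post", "t1_blood_pre", "t1_blood_post",
      "native_t1"), names(d)
  )
  for (col in t1_cols) {
    if (any(d[[col]] <= 0, na.rm = TRUE)) {
      stop("non-positive T1 value in column ", col)
    }
  }
  if ("ecv" %in% names(d) &&
      any(d$ecv <= 0 | d$ecv >= 100, na.rm = TRUE)) {
    stop("ecv outside (0,100)")
  }
  if ("hct" %in% names(d) && any(d$hct <= 0 | d$hct >= 1, na.rm = TRUE)) {
    stop("hct outside (0,1)")
  }
  d
}

.parse_logical <- function(x, col) {
  out <- rep(NA, length(x))
  lx <- tolower(x)
  out[lx %in% c("1", "true")] <- TRUE
  out[lx %in% c("0", "false")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) stop(sprintf("invalid boolean in column %s: %s", col,
                             x[bad][1]))
  out
}

#' Write a participant phenotype table
#' @param participants data.frame as returned by [read_phenotypes()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(participants, path) {
  write.csv(participants, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read the gene-panel configuration
#'
#' YAML (or JSON) file with keys `maf_threshold`, `cadd_threshold` and
#' `genes`, the latter a list of entries with `symbol`, `inheritance`
#' (AD/AR/both), `lof_mechanism` (whether haploinsufficiency/LoF is an
#' established disease mechanism, gating PVS1) and a genomic window
#' (`chrom`, `start`, `end`) used only by the synthetic-cohort generator.
#'
#' @param path path to the config file; defaults to the 82-gene
#'   cardiomyopathy panel shipped with the package.
#' @return An object of class `panel_config`: list with `genes` (data.frame),
#'   `maf_threshold`, `cadd_threshold`.
#' @export
read_panel_config <- function(path = default_panel_path()) {
  if (!file.exists(path)) stop("panel config not found: ", path)
  cfg <- if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  genes <- do.call(rbind, lapply(cfg$genes, function(g) {
    data.frame(
      symbol = g$symbol,
      inheritance = if (is.null(g$inheritance)) "AD" else g$inheritance,
      lof_mechanism = isTRUE(g$lof_mechanism),
      chrom = if (is.null(g$chrom)) NA_character_ else as.character(g$chrom),
      start = if (is.null(g$start)) NA_integer_ else as.integer(g$start),
      end = if (is.null(g$end)) NA_integer_ else as.integer(g$end),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(genes) || nrow(genes) == 0L) stop("panel gene list is empty")
  if (anyDuplicated(genes$symbol)) stop("duplicate gene symbol in panel")
  if (!all(genes$inheritance %in% c("AD", "AR", "both"))) {
    stop("inheritance must be AD, AR or both")
  }
  maf <- if (is.null(cfg$maf_threshold)) 0.001 else as.numeric(cfg$maf_threshold)
  if (!(maf > 0 && maf < 1)) stop("maf_threshold must be in (0,1)")
  cadd <- if (is.null(cfg$cadd_threshold)) 20 else as.numeric(cfg$cadd_threshold)
  structure(
    list(genes = genes, maf_threshold = maf, cadd_threshold = cadd),
    class = "panel_config"
  )
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf(
    "<panel_config> %d genes; MAF < %g; CADD >= %g\n",
    nrow(x$genes), x$maf_threshold, x$cadd_threshold
  ))
  invisible(x)
}

#' Path of the default cardiomyopathy panel shipped with the package
#' @return file path (character).
#' @export
default_panel_path <- function() {
  system.file("extdata", "cm_panel.yaml", package = "rarefib", mustWork = TRUE)
}
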