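#' Post-calling variant quality-control configuration
#'
#' Thresholds for the four exome post-calling filters, with boundary
#' semantics following the filter definitions verbatim: a record is rejected
#' iff `quality < min_quality`, `copy_number >= copy_number_max_exclusive`,
#' `nearest_snp_distance < min_adjacent_distance` (SNVs only), or
#' `depth < min_depth` or `depth > max_depth`.  So quality exactly 20, copy
#' number 1.99, adjacent distance exactly 5 and depths 4 and 500 are all
#' kept, while copy number exactly 2 is rejected.
#'
#' @param min_quality minimum phred-like consensus quality (default 20).
#' @param copy_number_max_exclusive rejection threshold on average copy
#'   number at the site (default 2; values >= this are rejected).
#' @param min_adjacent_distance minimum distance in bp to the nearest other
#'   called SNP (default 5); applies to SNVs only.
#' @param min_depth,max_depth allowed read-depth range (defaults 4 and 500,
#'   inclusive).
#' @return object of class `qc_config`.
#' @export
qc_config <- function(min_quality = 20, copy_number_max_exclusive = 2,
                      min_adjacent_distance = 5, min_depth = 4,
                      max_depth = 500) {
  if (min_depth > max_depth)
    stop_lx("lx_bad_config", "min_depth (%g) exceeds max_depth (%g)",
            min_depth, max_depth)
  structure(list(min_quality = min_quality,
                 copy_number_max_exclusive = copy_number_max_exclusive,
                 min_adjacent_distance = min_adjacent_distance,
                 min_depth = min_depth, max_depth = max_depth),
            class = "qc_config")
}

variant_required_cols <- c("chromosome", "position", "ref", "alt", "var_type",
                           "quality", "depth", "copy_number",
                           "nearest_snp_distance")

#' Validate a variant record table
#'
#' A variant table is a data.frame with one row per called variant:
#' `chromosome`, `position` (1-based), `ref`, `alt` (`"-"` for pure
#' insertions/deletions), `var_type` (`snv`/`insertion`/`deletion`),
#' `quality`, `depth`, `copy_number`, `nearest_snp_distance` (may be `NA`
#' for indels), and optionally `gene`, `functional_class`
#' (`nonsynonymous`/`splice_site`/`synonymous`/`other`), `codon_change` and
#' `genotype` (`ref_hom`/`het`/`alt_hom`/`missing`).
#'
#' @param records data.frame to validate.
#' @return `records`, invisibly, after checks.
#' @export
validate_variants <- function(records) {
  stopifnot_cols(records, variant_required_cols, "variant table")
  if (!all(records$var_type %in% c("snv", "insertion", "deletion")))
    stop_lx("lx_bad_variant", "var_type must be snv/insertion/deletion (row %d)",
            which(!records$var_type %in% c("snv", "insertion", "deletion"))[1])
  bad <- which(records$position < 1 | records$quality < 0 | records$depth < 0)
  if (length(bad))
    stop_lx("lx_bad_variant",
            "row %d: position must be >= 1 and quality/depth non-negative",
            bad[1])
  snv_len <- records$var_type == "snv" &
    (nchar(records$ref) != 1L | nchar(records$alt) != 1L)
  if (any(snv_len))
    stop_lx("lx_bad_variant", "row %d: SNV with multi-base alleles",
            which(snv_len)[1])
  invisible(records)
}

qc_reason_labels <- function(cfg) {
  c(quality = sprintf("quality score<%g", cfg$min_quality),
    copy_number = sprintf("copy number>=%g", cfg$copy_number_max_exclusive),
    adjacency = sprintf("adjacent SNP distance<%g bp", cfg$min_adjacent_distance),
    depth = sprintf("depth<%g or >%g", cfg$min_depth, cfg$max_depth))
}

#' Apply post-calling variant quality filters
#'
#' Partitions the input into kept and rejected records.  Each rejected
#' record carries the first criterion it fails, in the canonical order:
#' (i) low quality, (ii) high copy number, (iii) adjacent-SNP distance
#' (SNVs only; indels skip this criterion), (iv) out-of-range depth.
#' `kept` and `rejected` are disjoint and their union is the input.
#'
#' @param records validated variant table (see [validate_variants()]).
#' @param cfg a [qc_config()].
#' @return list with elements `kept` (data.frame) and `rejected`
#'   (data.frame with an extra `reason` column), of class `qc_result`.
#' @export
apply_qc <- function(records, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  validate_variants(records)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  labels <- qc_reason_labels(cfg)
  hit <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- labels[[code]]
  }
  hit(records$quality < cfg$min_quality, "quality")
  hit(records$copy_number >= cfg$copy_number_max_exclusive, "copy_number")
  hit(records$var_type == "snv" &
        records$nearest_snp_distance < cfg$min_adjacent_distance, "adjacency")
  hit(records$depth < cfg$min_depth | records$depth > cfg$max_depth, "depth")
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  structure(list(kept = records[is.na(reason), , drop = FALSE],
                 rejected = rejected),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("Variant QC: %d kept, %d rejected\n",
              nrow(x$kept), nrow(x$rejected)))
  if (nrow(x$rejected)) {
    tab <- table(x$rejected$reason)
    for (r in names(tab)) cat(sprintf("  %-28s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Recompute nearest-SNP distances from positions
#'
#' The adjacency criterion consumes a stored per-record distance so that
#' merges and indel handling cannot change its semantics; this helper
#' derives that field from the record positions themselves (distance to the
#' closest *other* SNV on the same chromosome; `NA` for indels and for a
#' chromosome's only SNV).
#'
#' @param records variant table.
#' @return `records` with `nearest_snp_distance` recomputed.
#' @export
recompute_snp_distance <- function(records) {
  records$nearest_snp_distance <- NA_real_
  snv <- which(records$var_type == "snv")
  for (chrom in unique(norm_chrom(records$chromosome[snv]))) {
    i <- snv[norm_chrom(records$chromosome[snv]) == chrom]
    if (length(i) < 2L) next
    ord <- i[order(records$position[i])]
    pos <- records$position[ord]
    gaps <- diff(pos)
    nearest <- pmin(c(Inf, gaps), c(gaps, Inf))
    records$nearest_snp_distance[ord] <- nearest
  }
  records
}

#' Read and write variant tables in the package TSV dialect
#'
#' Tab-separated files mirroring the variant record fields (see
#' [validate_variants()]); `#` lines are comments.  [write_variants_tsv()]
#' writes any variant table, including rejected tables carrying a `reason`
#' column.
#'
#' @param path file path.
#' @return a validated variant data.frame.
#' @export
read_variants_tsv <- function(path) {
  if (!file.exists(path))
    stop_lx("lx_missing_file", "variant file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          quote = "")
  validate_variants(df)
  df
}

#' @rdname read_variants_tsv
#' @param records variant table to write.
#' @export
write_variants_tsv <- function(records, path) {
  utils::write.table(records, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}

#' Read a variant table from a VCF file
#'
#' Maps VCF fields onto the package's variant records: QUAL to `quality`,
#' the `DP` INFO key to `depth`, a configurable INFO key (default `"CN"`)
#' to `copy_number`, and the named sample's GT call to `genotype`.
#' Functional annotation is taken from the `GENE` and `FCLASS` INFO keys
#' when present.  Nearest-SNP distances are recomputed from the record
#' positions via [recompute_snp_distance()].
#'
#' @param path VCF file path.
#' @param sample sample name whose genotypes to extract (default: first).
#' @param cn_key INFO key holding the average copy number (default `"CN"`).
#' @return a validated variant data.frame.
#' @export
read_variants_vcf <- function(path, sample = NULL, cn_key = "CN") {
  if (!file.exists(path))
    stop_lx("lx_missing_file", "VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_field <- function(key) {
    out <- vcfR::extract.info(v, element = key)
    suppressWarnings(as.numeric(out))
  }
  chr_field <- function(key) vcfR::extract.info(v, element = key)
  ref <- fix$REF; alt <- fix$ALT
  var_type <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv",
              ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  gt_code <- "missing"
  if (!is.null(v@gt) && ncol(v@gt) > 1L) {
    samples <- colnames(v@gt)[-1]
    sample <- sample %||% samples[1]
    if (!sample %in% samples)
      stop_lx("lx_unknown_sample", "sample '%s' not in VCF (%s)",
              sample, paste(samples, collapse = ", "))
    gt_raw <- vcfR::extract.gt(v, element = "GT")[, sample]
    alleles <- gsub("[|/]", "", gt_raw)
    gt_code <- ifelse(is.na(gt_raw) | grepl("\\.", gt_raw), "missing",
               ifelse(alleles == "00", "ref_hom",
               ifelse(grepl("0", gt_raw), "het", "alt_hom")))
  }
  df <- data.frame(
    chromosome = fix$CHROM,
    position = as.numeric(fix$POS),
    ref = ref, alt = alt, var_type = var_type,
    quality = suppressWarnings(as.numeric(fix$QUAL)),
    depth = info_field("DP"),
    copy_number = info_field(cn_key),
    nearest_snp_distance = NA_real_,
    gene = chr_field("GENE"),
    functional_class = chr_field("FCLASS"),
    genotype = gt_code,
    stringsAsFactors = FALSE
  )
  df <- recompute_snp_distance(df)
  validate_variants(df)
  df
}
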