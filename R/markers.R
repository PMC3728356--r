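#' Define a marker locus
#'
#' @param name marker name (e.g. `"D9S177"`).
#' @param chromosome chromosome label (with or without a `chr` prefix).
#' @param genetic_pos genetic position in centimorgans.
#' @param physical_pos 1-based physical position in base pairs.
#' @param n_alleles number of alleles (>= 2).
#' @param allele_freqs probability vector of length `n_alleles`; `NULL`
#'   (the default) means equal frequencies `1/n_alleles`, the conventional
#'   choice for microsatellites when population frequencies are unknown.
#' @return object of class `marker_locus`.
#' @export
marker_locus <- function(name, chromosome, genetic_pos = NA_real_,
                         physical_pos = NA_real_, n_alleles = 2L,
                         allele_freqs = NULL) {
  stopifnot(is_string(name), n_alleles >= 2L)
  if (is.null(allele_freqs)) allele_freqs <- rep(1 / n_alleles, n_alleles)
  if (length(allele_freqs) != n_alleles)
    stop_lx("lx_bad_marker", "marker %s: %d allele frequencies for %d alleles",
            name, length(allele_freqs), n_alleles)
  if (abs(sum(allele_freqs) - 1) > 1e-9)
    stop_lx("lx_bad_marker", "marker %s: allele frequencies sum to %.12f, not 1",
            name, sum(allele_freqs))
  if (any(allele_freqs < 0))
    stop_lx("lx_bad_marker", "marker %s: negative allele frequency", name)
  structure(list(name = name, chromosome = as.character(chromosome),
                 genetic_pos = as.numeric(genetic_pos),
                 physical_pos = as.numeric(physical_pos),
                 n_alleles = as.integer(n_alleles),
                 allele_freqs = as.numeric(allele_freqs)),
            class = "marker_locus")
}

#' @export
print.marker_locus <- function(x, ...) {
  cat(sprintf("Marker %s  chr%s  %.2f cM  %.0f bp  %d alleles\n",
              x$name, norm_chrom(x$chromosome), x$genetic_pos,
              x$physical_pos, x$n_alleles))
  invisible(x)
}

#' Read a marker map table
#'
#' Tab-separated columns `name`, `chrom`, `cM`, `bp`, `n_alleles`,
#' `allele_freqs` (comma-joined probabilities, or `"."` for equal
#' frequencies).  Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return data.frame with one row per marker (class `marker_map`).
#' @seealso [map_marker()] to extract one marker as a [marker_locus()].
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path))
    stop_lx("lx_missing_file", "marker map file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  stopifnot_cols(df, c("name", "chrom", "cM", "bp"), "marker map")
  if (is.null(df$n_alleles)) df$n_alleles <- 2L
  if (is.null(df$allele_freqs)) df$allele_freqs <- "."
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Extract one marker from a marker map
#'
#' @param map a marker map data.frame from [read_marker_map()].
#' @param name marker name.
#' @return a [marker_locus()].
#' @export
map_marker <- function(map, name) {
  r <- map[map$name == name, ]
  if (!nrow(r))
    stop_lx("lx_unknown_marker", "marker '%s' not found in map", name)
  r <- r[1, ]
  freqs <- if (is.na(r$allele_freqs) || r$allele_freqs == ".") NULL
           else as.numeric(strsplit(r$allele_freqs, ",")[[1]])
  marker_locus(r$name, r$chrom, r$cM, r$bp,
               n_alleles = if (is.null(freqs)) r$n_alleles else length(freqs),
               allele_freqs = freqs)
}

#' Genotype calls for one marker on a pedigree
#'
#' @param marker a [marker_locus()].
#' @param calls data.frame with columns `id`, `allele1`, `allele2`; allele 0
#'   or `NA` means missing (both alleles must then be missing).  Allele pairs
#'   are unordered.
#' @param ped optional [pedigree()]; if given, every genotyped id must be a
#'   member.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(marker, calls, ped = NULL) {
  stopifnot(inherits(marker, "marker_locus"), is.data.frame(calls))
  stopifnot_cols(calls, c("id", "allele1", "allele2"), "genotype table")
  calls$id <- as.character(calls$id)
  for (col in c("allele1", "allele2")) {
    calls[[col]] <- suppressWarnings(as.integer(calls[[col]]))
    calls[[col]][calls[[col]] == 0L] <- NA_integer_
  }
  half <- xor(is.na(calls$allele1), is.na(calls$allele2))
  if (any(half))
    stop_lx("lx_bad_genotype", "individual %s: half-missing genotype",
            calls$id[which(half)[1]])
  rng <- c(calls$allele1, calls$allele2)
  bad <- !is.na(rng) & (rng < 1L | rng > marker$n_alleles)
  if (any(bad))
    stop_lx("lx_bad_genotype",
            "allele index out of range 1..%d for marker %s",
            marker$n_alleles, marker$name)
  if (dup <- anyDuplicated(calls$id))
    stop_lx("lx_duplicate_id", "duplicate genotype row for individual %s",
            calls$id[dup])
  if (!is.null(ped)) {
    unknown <- setdiff(calls$id, ped$members$id)
    if (length(unknown))
      stop_lx("lx_unknown_individual",
              "genotyped individual(s) not in pedigree: %s",
              paste(unknown, collapse = ", "))
  }
  structure(list(marker = marker, calls = calls), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  typed <- sum(!is.na(x$calls$allele1))
  cat(sprintf("Genotypes at %s: %d individuals typed (of %d listed)\n",
              x$marker$name, typed, nrow(x$calls)))
  invisible(x)
}

#' Read genotype calls from a TSV file
#'
#' Tab-separated columns `id`, `allele1`, `allele2` with 0 meaning missing.
#'
#' @inheritParams genotype_table
#' @param path file path.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, marker, ped = NULL) {
  if (!file.exists(path))
    stop_lx("lx_missing_file", "genotype file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  genotype_table(marker, df, ped)
}

#' Write genotype calls to a TSV file
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  out <- gt$calls
  out$allele1[is.na(out$allele1)] <- 0L
  out$allele2[is.na(out$allele2)] <- 0L
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
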