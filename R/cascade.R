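#' Variant identity keys
#'
#' Variant identity throughout the filter cascade is the 4-tuple
#' (chromosome, position, ref, alt), with the chromosome's `chr` prefix
#' normalised away; indels are identified by their left-aligned 1-based
#' anchor position.
#'
#' @param records variant table with `chromosome`, `position`, `ref`, `alt`.
#' @return character vector of keys, one per row.
#' @export
variant_key <- function(records) {
  stopifnot_cols(records, c("chromosome", "position", "ref", "alt"),
                 "variant table")
  paste(norm_chrom(records$chromosome), records$position,
        records$ref, records$alt, sep = ":")
}

#' A named set of known variants
#'
#' Membership lists in the style of public SNP databases (dbSNP, 1000
#' Genomes, HapMap, a population genome) or of a sequenced control exome,
#' used by [subtract_known()].
#'
#' @param name set name.
#' @param records data.frame with `chromosome`, `position`, `ref`, `alt`.
#' @return object of class `known_variant_set`.
#' @export
known_variant_set <- function(name, records) {
  stopifnot(is_string(name))
  structure(list(name = name, keys = unique(variant_key(records))),
            class = "known_variant_set")
}

#' @export
print.known_variant_set <- function(x, ...) {
  cat(sprintf("Known-variant set '%s': %d variants\n", x$name, length(x$keys)))
  invisible(x)
}

#' Read a known-variant set from a 4-column TSV
#'
#' @param path TSV with columns `chromosome`, `position`, `ref`, `alt`.
#' @param name set name (default: file base name).
#' @return a [known_variant_set()].
#' @export
read_known_set <- function(path, name = NULL) {
  if (!file.exists(path))
    stop_lx("lx_missing_file", "known-set file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          quote = "")
  known_variant_set(name %||% sub("\\.[^.]*$", "", basename(path)), df)
}

#' Keep functional (NS/SS/Indel) variants
#'
#' The first cascade stage keeps variants plausibly affecting the protein:
#' nonsynonymous or splice-site SNVs, and all insertions/deletions.
#' Synonymous and other-class SNVs are removed.
#'
#' @param records variant table with populated `functional_class`.
#' @return the functional subset of `records`.
#' @export
functional_filter <- function(records) {
  stopifnot_cols(records, c("functional_class", "var_type"), "variant table")
  miss <- is.na(records$functional_class) | records$functional_class %in% c("", ".")
  indel <- records$var_type %in% c("insertion", "deletion")
  if (any(miss & !indel))
    stop_lx("lx_missing_annotation",
            "functional_class missing for %d SNV record(s) (first at row %d)",
            sum(miss & !indel), which(miss & !indel)[1])
  keep <- indel | records$functional_class %in% c("nonsynonymous", "splice_site")
  records[keep, , drop = FALSE]
}

#' Remove variants present in known-variant sets
#'
#' Drops every record whose (chromosome, position, ref, alt) key appears in
#' any of the supplied sets; order of sets is immaterial.
#'
#' @param records variant table.
#' @param sets list of [known_variant_set()] objects (or a single one).
#' @return the surviving records.
#' @export
subtract_known <- function(records, sets) {
  if (inherits(sets, "known_variant_set")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1), "known_variant_set")))
  if (!length(sets) || !nrow(records)) return(records)
  known <- unique(unlist(lapply(sets, `[[`, "keys")))
  records[!variant_key(records) %in% known, , drop = FALSE]
}

#' Variants shared by a set of samples
#'
#' Key-wise intersection over (chromosome, position, ref, alt) requiring a
#' non-reference genotype call (`het` or `alt_hom`; or simple presence when
#' a table has no `genotype` column) in every listed sample.  Returned
#' records carry the first listed sample's annotations.
#'
#' @param per_sample_records named list mapping sample id to its variant
#'   table.
#' @param samples character vector of sample ids to intersect (>= 1).
#' @return the shared records.
#' @export
shared_by <- function(per_sample_records, samples) {
  stopifnot(length(samples) >= 1L)
  unknown <- setdiff(samples, names(per_sample_records))
  if (length(unknown))
    stop_lx("lx_unknown_sample", "unknown sample id(s): %s",
            paste(unknown, collapse = ", "))
  nonref_keys <- function(df) {
    if (!nrow(df)) return(character(0))
    keys <- variant_key(df)
    if (!is.null(df$genotype)) keys <- keys[df$genotype %in% c("het", "alt_hom")]
    unique(keys)
  }
  shared <- Reduce(intersect, lapply(per_sample_records[samples], nonref_keys))
  first <- per_sample_records[[samples[1]]]
  first[variant_key(first) %in% shared, , drop = FALSE]
}

#' Translate a codon-change string to an amino-acid substitution
#'
#' Codon-change strings pair the reference and variant codons with the
#' changed base in lowercase, e.g. `"GTG-aTG"`.  Both codons are translated
#' under the standard genetic code and rendered as
#' `<refAA><residue_index><altAA>`, with a stop codon written `X` (so
#' `"GAG-tAG"` at residue 217 gives `"E217X"`).  Codons differing at more
#' than one position are rejected; identical codons give a synonymous
#' annotation such as `"K5K"`.
#'
#' @param codon_change string `"<ref codon>-<alt codon>"` over `ACGTacgt`.
#' @param residue_index 1-based residue number in the protein.
#' @return the substitution string.
#' @export
translate_codon_change <- function(codon_change, residue_index) {
  stopifnot(is_string(codon_change), length(residue_index) == 1L,
            residue_index >= 1)
  parts <- strsplit(codon_change, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || any(nchar(parts) != 3L) ||
      any(grepl("[^ACGTacgt]", parts)))
    stop_lx("lx_bad_codon",
            "codon change must be two 3-base codons over ACGTacgt joined by '-', got '%s'",
            codon_change)
  ref <- toupper(parts[1]); alt <- toupper(parts[2])
  ndiff <- sum(strsplit(ref, "")[[1]] != strsplit(alt, "")[[1]])
  if (ndiff > 1L)
    stop_lx("lx_bad_codon", "codons '%s' differ at %d positions; at most 1 allowed",
            codon_change, ndiff)
  aa <- function(codon) {
    a <- Biostrings::GENETIC_CODE[[codon]]
    if (a == "*") "X" else a
  }
  paste0(aa(ref), as.integer(residue_index), aa(alt))
}

#' Check co-segregation of a variant with the phenotype
#'
#' Under the dominant heterozygous model a variant co-segregates iff every
#' typed affected member carries it heterozygously and every typed
#' unaffected member *not* below the onset age does not carry it.  Carriers
#' below the onset age are permitted (they may simply not have presented
#' yet), and untyped members are ignored.
#'
#' @param ped a [pedigree()].
#' @param carrier_status named character vector (or list) mapping member id
#'   to `carrier_het`, `carrier_hom`, `noncarrier` or `untyped`.
#' @return list with `verdict` (`"cosegregates"` or `"fails"`) and
#'   `violations` (ids of members breaking the rule), class
#'   `cosegregation`.
#' @export
cosegregation_check <- function(ped, carrier_status) {
  status <- unlist(carrier_status)
  unknown <- setdiff(names(status), ped$members$id)
  if (length(unknown))
    stop_lx("lx_unknown_individual", "carrier status for non-member(s): %s",
            paste(unknown, collapse = ", "))
  bad <- setdiff(status, c("carrier_het", "carrier_hom", "noncarrier", "untyped"))
  if (length(bad))
    stop_lx("lx_bad_status", "invalid carrier status value(s): %s",
            paste(bad, collapse = ", "))
  m <- ped$members
  violations <- character(0)
  for (i in seq_len(nrow(m))) {
    s <- status[m$id[i]]
    if (is.na(s) || s == "untyped") next
    if (m$phenotype[i] == "affected" && s != "carrier_het")
      violations <- c(violations, m$id[i])
    if (m$phenotype[i] == "unaffected" && !m$below_onset_age[i] &&
        s != "noncarrier")
      violations <- c(violations, m$id[i])
  }
  structure(list(verdict = if (length(violations)) "fails" else "cosegregates",
                 violations = violations),
            class = "cosegregation")
}

#' @export
print.cosegregation <- function(x, ...) {
  if (x$verdict == "cosegregates") {
    cat("Variant co-segregates with the phenotype\n")
  } else {
    cat(sprintf("Co-segregation FAILS; violating member(s): %s\n",
                paste(x$violations, collapse = ", ")))
  }
  invisible(x)
}

#' Run the candidate-variant filter cascade
#'
#' Applies the three cascade stages in order -- functional (NS/SS/Indel)
#' filtering, subtraction of public known-variant sets, subtraction of the
#' control exome -- to each sample's table, and reports, for every stage and
#' every requested sample combination, the number of shared variants
#' exome-wide (`whole`) and inside the linked interval (`locus`).  The
#' final candidates are the last stage's shared set for the largest
#' combination, restricted to the interval.  Variant QC
#' ([apply_qc()]) is expected to have run upstream.
#'
#' @param per_sample_records named list mapping affected-sample id to its
#'   (QC-passed) variant table.
#' @param sets list of public [known_variant_set()]s.
#' @param control_set [known_variant_set()] built from the control exome
#'   (or `NULL` to skip the control stage).
#' @param interval a [define_interval()] result.
#' @param sample_combinations list of character vectors of sample ids; the
#'   default is each single sample followed by the cumulative combinations.
#' @return list of class `cascade_result` with elements `ledger` (a
#'   `filter_ledger` data.frame: stage, combination, whole, locus) and
#'   `final` (the candidate records).
#' @export
run_cascade <- function(per_sample_records, sets, control_set, interval,
                        sample_combinations = NULL) {
  samples <- names(per_sample_records)
  stopifnot(length(samples) >= 1L)
  if (is.null(sample_combinations)) {
    singles <- as.list(samples)
    cumul <- lapply(seq_along(samples)[-1], function(i) samples[1:i])
    sample_combinations <- c(singles, cumul)
  }
  stage_tabs <- list()
  stage_tabs[["NS/SS/Indel"]] <- lapply(per_sample_records, functional_filter)
  stage_tabs[["Not in public sets"]] <-
    lapply(stage_tabs[["NS/SS/Indel"]], subtract_known, sets = sets)
  if (!is.null(control_set))
    stage_tabs[["Not in public sets + control"]] <-
      lapply(stage_tabs[["Not in public sets"]], subtract_known,
             sets = list(control_set))
  rows <- list()
  for (stage in names(stage_tabs)) {
    for (combo in sample_combinations) {
      shared <- shared_by(stage_tabs[[stage]], combo)
      rows[[length(rows) + 1L]] <- data.frame(
        stage = stage,
        combination = paste(combo, collapse = "+"),
        whole = nrow(shared),
        locus = nrow(in_interval(shared, interval)),
        stringsAsFactors = FALSE)
    }
  }
  ledger <- do.call(rbind, rows)
  class(ledger) <- c("filter_ledger", "data.frame")
  sizes <- lengths(sample_combinations)
  largest <- sample_combinations[[which.max(sizes)]]
  last_stage <- stage_tabs[[length(stage_tabs)]]
  final <- in_interval(shared_by(last_stage, largest), interval)
  structure(list(ledger = ledger, final = final), class = "cascade_result")
}

#' @export
print.filter_ledger <- function(x, ...) {
  wide <- stats::reshape(
    transform(as.data.frame(x), cell = paste0(whole, "/", locus),
              whole = NULL, locus = NULL),
    idvar = "stage", timevar = "combination", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  cat("Filter cascade (whole-exome count / in-locus count):\n")
  print(wide, row.names = FALSE)
  invisible(x)
}

#' @export
print.cascade_result <- function(x, ...) {
  print(x$ledger)
  cat(sprintf("\nFinal candidate(s) in the linked interval: %d\n",
              nrow(x$final)))
  if (nrow(x$final)) {
    cols <- intersect(c("chromosome", "position", "ref", "alt", "gene"),
                      names(x$final))
    print(x$final[, cols], row.names = FALSE)
  }
  invisible(x)
}

#' Write a filter ledger as TSV or JSON
#'
#' @param ledger the `ledger` element of a [run_cascade()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ledger_tsv <- function(ledger, path) {
  utils::write.table(as.data.frame(ledger), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_ledger_tsv
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(as.data.frame(ledger), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
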