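# Packaged machine-readable fixtures: the 9q marker map, the eight shared
# candidate variants, and an F013-shaped pedigree skeleton.

lx_extdata <- function(file) {
  path <- system.file("extdata", file, package = "linkexome")
  if (path == "") path <- file.path("inst", "extdata", file)  # pre-install
  path
}

#' F013-shaped pedigree skeleton
#'
#' A five-generation autosomal-dominant hearing-loss pedigree reproducing
#' the published census of family F013 -- 53 members, 11 affected, 5
#' unaffected members younger than the average onset age (flagged, hence
#' phenotype-unknown in likelihoods) -- and the member ids named in the
#' source's subject lists (II:2, III:1-5, IV:3, IV:5, IV:17, IV:31, V:1,
#' ...).  The topology linking them is a synthetic construction consistent
#' with those constraints, not the original family structure; see the
#' fixture file header.
#'
#' @return a [pedigree()] of 53 members.
#' @export
f013_pedigree <- function() {
  read_pedigree(lx_extdata("f013_synthetic.ped"))
}

#' Chromosome 9q microsatellite marker map (DFNA56 scan)
#'
#' The 21 markers of the fine-mapping scan with their genetic (cM) and
#' physical (bp) positions.  Allele counts and frequencies are synthetic
#' (8 equal-frequency alleles per marker): the source used equal
#' frequencies and does not report allele counts.
#'
#' @return a marker map data.frame (see [read_marker_map()]).
#' @export
dfna56_marker_map <- function() {
  read_marker_map(lx_extdata("dfna56_marker_map.tsv"))
}

#' The DFNA56 critical interval
#'
#' The linked interval between the flanking markers D9S1677 and D9S1838 on
#' chromosome 9q31.3-q34.3, spanning 28.54 Mb.
#'
#' @return a [define_interval()] result.
#' @export
dfna56_interval <- function() {
  define_interval(dfna56_marker_map(), "D9S1677", "D9S1838")
}

#' The eight shared candidate variants
#'
#' The candidate NS/SS/Indel variants shared by the three sequenced
#' affected individuals after database and control subtraction, with
#' codon-change and amino-acid substitution annotations.  Exactly one lies
#' inside the DFNA56 interval (the TNC missense variant on chromosome 9).
#'
#' @return a variant data.frame of 8 rows.
#' @export
candidate_variants <- function() {
  df <- utils::read.table(lx_extdata("candidate_variants.tsv"), header = TRUE,
                          sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  df
}

#' All packaged fixtures
#'
#' @return list with elements `pedigree`, `marker_map`, `interval` and
#'   `candidates`.
#' @export
dfna56_fixtures <- function() {
  list(pedigree = f013_pedigree(),
       marker_map = dfna56_marker_map(),
       interval = dfna56_interval(),
       candidates = candidate_variants())
}
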