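#' Define the linked interval from flanking markers
#'
#' The critical disease region is delimited by the two markers flanking the
#' disease haplotype; the interval runs from the smaller to the larger
#' physical position, closed on both ends and 1-based.  Argument order does
#' not matter.
#'
#' @param map a marker map from [read_marker_map()].
#' @param left_marker,right_marker names of the flanking markers (must lie
#'   on the same chromosome).
#' @return object of class `linked_interval` with fields `chromosome`,
#'   `start_bp`, `end_bp`, `left_marker`, `right_marker`.
#' @examples
#' map <- read_marker_map(system.file("extdata", "dfna56_marker_map.tsv",
#'                                    package = "linkexome"))
#' iv <- define_interval(map, "D9S1677", "D9S1838")
#' interval_span_mb(iv)   # 28.54
#' @export
define_interval <- function(map, left_marker, right_marker) {
  a <- map_marker(map, left_marker)
  b <- map_marker(map, right_marker)
  if (norm_chrom(a$chromosome) != norm_chrom(b$chromosome))
    stop_lx("lx_different_chromosomes",
            "markers %s (chr%s) and %s (chr%s) are on different chromosomes",
            a$name, norm_chrom(a$chromosome), b$name, norm_chrom(b$chromosome))
  if (a$physical_pos > b$physical_pos) { tmp <- a; a <- b; b <- tmp }
  structure(list(chromosome = a$chromosome,
                 start_bp = a$physical_pos,
                 end_bp = b$physical_pos,
                 left_marker = a$name,
                 right_marker = b$name),
            class = "linked_interval")
}

#' Span of a linked interval
#'
#' The physical distance between the flanking markers, `end_bp - start_bp`.
#'
#' @param interval a [define_interval()] result.
#' @return span in base pairs ([interval_span_bp()]) or megabases rounded to
#'   two decimals ([interval_span_mb()]).
#' @export
interval_span_bp <- function(interval) {
  stopifnot(inherits(interval, "linked_interval"))
  interval$end_bp - interval$start_bp
}

#' @rdname interval_span_bp
#' @export
interval_span_mb <- function(interval) {
  round(interval_span_bp(interval) / 1e6, 2)
}

#' @export
print.linked_interval <- function(x, ...) {
  cat(sprintf("Linked interval chr%s:%.0f-%.0f (%s .. %s), spanning %.2f Mb\n",
              norm_chrom(x$chromosome), x$start_bp, x$end_bp,
              x$left_marker, x$right_marker, interval_span_mb(x)))
  invisible(x)
}

#' Restrict variant records to a linked interval
#'
#' Keeps records whose chromosome matches (chr-prefix insensitive) and whose
#' position lies inside the closed, 1-based interval.
#'
#' @param records a variant record data.frame (see [validate_variants()]).
#' @param interval a [define_interval()] result.
#' @return the subset of `records` inside the interval.
#' @export
in_interval <- function(records, interval) {
  stopifnot(inherits(interval, "linked_interval"))
  stopifnot_cols(records, c("chromosome", "position"), "variant table")
  keep <- norm_chrom(records$chromosome) == norm_chrom(interval$chromosome) &
    records$position >= interval$start_bp &
    records$position <= interval$end_bp
  records[keep, , drop = FALSE]
}

#' Write a linked interval as BED and/or JSON
#'
#' BED output is 0-based half-open (`start_bp - 1`, `end_bp`), converted
#' from the internal 1-based closed representation.
#'
#' @param interval a [define_interval()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interval_bed <- function(interval, path) {
  line <- sprintf("%s\t%.0f\t%.0f\t%s-%s", interval$chromosome,
                  interval$start_bp - 1, interval$end_bp,
                  interval$left_marker, interval$right_marker)
  writeLines(line, path)
  invisible(path)
}

#' @rdname write_interval_bed
#' @export
write_interval_json <- function(interval, path) {
  jsonlite::write_json(unclass(interval), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
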