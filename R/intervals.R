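#' Genomic interval arithmetic
#'
#' All coordinates inside the package are 0-based half-open (BED
#' convention): an interval covers positions `start, start+1, ..., end-1`
#' and has `length = end - start > 0`. Human-facing region strings
#' ("chr6:52153426-52153442", UCSC style) are 1-based inclusive and are
#' converted on parse/format.
#'
#' @name intervals
NULL

validate_intervals <- function(chrom, start, end, what = "interval") {
  if (any(is.na(chrom) | is.na(start) | is.na(end))) {
    stop("malformed ", what, ": missing chrom/start/end", call. = FALSE)
  }
  if (any(start < 0)) {
    stop("malformed ", what, ": negative start", call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    stop(
      "malformed ", what, " (start >= end) at entry ", bad[1], ": ",
      chrom[bad[1]], ":", start[bad[1]], "-", end[bad[1]],
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Overlap length between two sets of intervals
#'
#' Vectorised over rows: element `i` of the result is the overlap, in bp,
#' between interval `i` of `a` and interval `i` of `b` under half-open
#' semantics. Intervals on different chromosomes, disjoint intervals, and
#' abutting intervals (`a$end == b$start`) all give 0.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end` (0-based
#'   half-open). Both must have the same number of rows, or one of them a
#'   single row (recycled).
#' @return Integer vector of overlap lengths (>= 0).
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 10, end = 20)
#' b <- tibble::tibble(chrom = "chr1", start = 15, end = 30)
#' interval_overlap(a, b) # 5
#' @export
interval_overlap <- function(a, b) {
  validate_intervals(a$chrom, a$start, a$end, "interval in `a`")
  validate_intervals(b$chrom, b$start, b$end, "interval in `b`")
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  ov <- pmax(ov, 0L)
  ov[as.character(a$chrom) != as.character(b$chrom)] <- 0L
  as.integer(ov)
}

#' Midpoint of an interval
#'
#' Deterministic for even lengths: the lower of the two central positions,
#' `floor((start + end - 1) / 2)`, in 0-based coordinates.
#'
#' @param start,end Numeric vectors, 0-based half-open bounds.
#' @return Integer vector of 0-based positions.
#' @examples
#' interval_midpoint(10, 20) # 14
#' interval_midpoint(0, 2)   # 0
#' @export
interval_midpoint <- function(start, end) {
  validate_intervals(rep("*", length(start)), start, end)
  as.integer(floor((start + end - 1) / 2))
}

#' Parse UCSC-style region strings
#'
#' Accepts "chrN:A-B" with either a hyphen or an en-dash as the range
#' separator and with optional thousands commas; positions are read as
#' 1-based inclusive and converted to 0-based half-open.
#'
#' @param x Character vector of region strings.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' parse_region("chr6:52153426-52153442")
#' @export
parse_region <- function(x) {
  x_norm <- stringr::str_replace_all(x, "–", "-")
  x_norm <- stringr::str_remove_all(x_norm, ",")
  m <- stringr::str_match(x_norm, "^([^:]+):(\\d+)-(\\d+)$")
  if (any(is.na(m[, 1]))) {
    bad <- x[which(is.na(m[, 1]))[1]]
    stop("cannot parse region string: '", bad, "'", call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = m[, 2],
    start = as.numeric(m[, 3]) - 1,
    end = as.numeric(m[, 4])
  )
  validate_intervals(out$chrom, out$start, out$end, "region string")
  out
}

#' Format intervals as 1-based inclusive region strings
#'
#' @param chrom,start,end Interval columns (0-based half-open).
#' @return Character vector "chrom:start-end" (1-based inclusive, hyphen).
#' @export
format_region <- function(chrom, start, end) {
  validate_intervals(chrom, start, end)
  paste0(chrom, ":", format(start + 1, scientific = FALSE, trim = TRUE),
         "-", format(end, scientific = FALSE, trim = TRUE))
}
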