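#' Genomic interval (1-based, closed)
#'
#' All coordinates in this package are 1-based and inclusive at both ends,
#' matching HGVS g. notation; conversion to/from the half-open 0-based BED
#' convention happens only in [read_bed()] / [write_bed()].
#'
#' @param chrom chromosome name
#' @param start 1-based inclusive start
#' @param end 1-based inclusive end; must be >= start
#' @return an object of class `interval`
#' @export
interval <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1, length(start) == 1, length(end) == 1)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("invalid interval: start must be <= end (got ", start, " > ", end, ")")
  }
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "interval")
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%d bp)\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              interval_length(x)))
  invisible(x)
}

#' Length of an interval in base pairs
#' @param x an [interval()]
#' @return `end - start + 1`
#' @export
interval_length <- function(x) {
  as.integer(x$end - x$start + 1)
}

#' Does a position (or closed span) overlap an interval?
#' @param x an [interval()]
#' @param pos 1-based position of the first base of the span
#' @param width span width in bases (default 1)
#' @return logical
#' @export
interval_contains <- function(x, pos, width = 1L) {
  pos <= x$end & (pos + width - 1) >= x$start
}

as_granges <- function(ints) {
  if (inherits(ints, "interval")) ints <- list(ints)
  GenomicRanges::GRanges(
    seqnames = vapply(ints, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(ints, `[[`, 0, "start"),
      end = vapply(ints, `[[`, 0, "end")
    )
  )
}

#' Distance from a position to an interval
#'
#' Zero if the position lies inside the closed interval, otherwise the
#' distance in bp to the nearest interval edge. Used e.g. to measure how far
#' a promoter SNV sits from a duplicated span.
#'
#' @param pos 1-based genomic position
#' @param int an [interval()] on the same chromosome
#' @param chrom optional chromosome of `pos`; when given it must equal
#'   `int$chrom`
#' @return non-negative integer distance in bp
#' @export
variant_distance <- function(pos, int, chrom = NULL) {
  if (!is.null(chrom) && !identical(as.character(chrom), int$chrom)) {
    stop("position and interval are on different chromosomes")
  }
  if (interval_contains(int, pos)) return(0L)
  as.integer(min(abs(pos - int$start), abs(pos - int$end)))
}

#' Intersect overlapping loci from independent mapping studies
#'
#' The maximal interval shared by all inputs, e.g. overlapping
#' disease-associated loci mapped in different families.
#'
#' @param loci a list of [interval()] objects on one chromosome, pairwise
#'   overlapping
#' @return the common [interval()]
#' @export
intersect_loci <- function(loci) {
  stopifnot(length(loci) >= 1)
  chroms <- unique(vapply(loci, `[[`, "", "chrom"))
  if (length(chroms) != 1) stop("loci lie on different chromosomes: ",
                                paste(chroms, collapse = ", "))
  start <- max(vapply(loci, `[[`, 0, "start"))
  end <- min(vapply(loci, `[[`, 0, "end"))
  if (start > end) stop("loci are disjoint; no common interval")
  interval(chroms, start, end)
}

#' Read a BED3+ file into a list of intervals
#'
#' BED records are 0-based half-open; they are converted to the internal
#' 1-based closed convention (`start + 1`, `end`). Records with
#' `start >= end` are rejected with a warning rather than aborting the read.
#'
#' @param path BED file path
#' @return list of [interval()]
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) return(list())
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "[\t ]+")[[1]]
    if (length(f) < 3) stop("malformed BED record at line ", i)
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop("non-numeric BED coordinates at line ", i)
    if (s >= e) {
      warning("rejecting BED record with start >= end at line ", i)
      next
    }
    out[[length(out) + 1]] <- interval(f[1], s + 1, e)
  }
  out
}

#' Write intervals as BED3
#'
#' Inverse of [read_bed()]: internal 1-based closed coordinates become
#' 0-based half-open.
#'
#' @param ints list of [interval()]
#' @param path output path
#' @export
write_bed <- function(ints, path) {
  if (inherits(ints, "interval")) ints <- list(ints)
  lines <- vapply(ints, function(x) {
    sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start - 1), as.integer(x$end))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
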