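#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb seqlevels seqnames
NULL

## Recognised transposable-element classes. Simple repeats and low-complexity
## regions are carried as classes without superfamilies.
TE_CLASSES <- c("DNA", "LINE", "LTR", "RC_Helitron", "Penelope", "SINE",
                "Simple_repeat", "Low_complexity", "Unknown")

## Classes that never carry a superfamily label.
.NO_SUPERFAMILY <- c("Simple_repeat", "Low_complexity", "Unknown")

#' Construct a genome index
#'
#' A genome index is the minimal description of an assembly used throughout
#' the package: an ordered table of chromosome (or scaffold) names and their
#' lengths in base pairs. No sequence is ever needed; all analyses operate on
#' intervals.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths (bp, >= 1).
#' @return A `data.frame` with columns `chrom` and `length`.
#' @examples
#' genome_index(c("chrI", "chrII"), c(15e6, 12e6))
#' @export
genome_index <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("duplicated chromosome names in genome index")
  if (any(is.na(length)) || any(length < 1))
    stop("chromosome lengths must be >= 1")
  data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
}

#' Construct an interval table
#'
#' Intervals are stored 0-based, half-open (the BED convention), so that
#' `end - start` is always the interval length and abutting intervals share a
#' single coordinate. Strand is deliberately absent: every overlap analysis in
#' the package is strand-agnostic.
#'
#' @param chrom,start,end vectors defining the intervals.
#' @param index optional genome index; when supplied, intervals are validated
#'   against chromosome names and lengths.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
intervals <- function(chrom, start, end, index = NULL) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  validate_intervals(x, index)
  x
}

#' Validate an interval table
#'
#' Checks `0 <= start < end` and, when an index is bound, that chromosomes
#' exist and `end <= chrom length`. Out-of-range records are rejected, never
#' clipped, so that fixture/index mismatches surface early.
#'
#' @param x interval data.frame (`chrom`, `start`, `end`).
#' @param index optional genome index.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, index = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  if (!is.null(index)) {
    miss <- setdiff(unique(x$chrom), index$chrom)
    if (length(miss))
      stop("chromosome(s) not in genome index: ", paste(miss, collapse = ", "))
    len <- index$length[match(x$chrom, index$chrom)]
    over <- which(x$end > len)
    if (length(over))
      stop("interval end beyond chromosome length at row(s) ",
           paste(utils::head(over, 5), collapse = ", "))
  }
  invisible(x)
}

## Internal: interval data.frame (0-based half-open) -> GRanges (1-based
## closed). seqlevels are pinned to the index when given so set operations
## never warn about level mismatches.
.as_gr <- function(x, index = NULL) {
  lv <- if (is.null(index)) sort(unique(as.character(x$chrom))) else index$chrom
  if (nrow(x) == 0)
    return(GenomicRanges::GRanges(seqnames = factor(character(), levels = lv),
                                  ranges = IRanges::IRanges()))
  GenomicRanges::GRanges(seqnames = factor(as.character(x$chrom), levels = lv),
                         ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

## Internal: GRanges -> 0-based half-open data.frame, sorted by chrom then start.
.gr_to_df <- function(gr) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = as.numeric(GenomicRanges::start(gr)) - 1,
                   end = as.numeric(GenomicRanges::end(gr)),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
}

#' Tile a genome into consecutive fixed-width windows
#'
#' Each chromosome is tiled from coordinate 0 in non-overlapping windows of
#' `window_size` bp; a trailing partial window is retained (callers may filter
#' by length). The total length of all windows therefore equals the total
#' genome length.
#'
#' @param index genome index.
#' @param window_size window width in bp (>= 1).
#' @return Interval data.frame with one row per window, ordered along each
#'   chromosome, plus a `window` column giving the 1-based global window index.
#' @examples
#' idx <- genome_index("c1", 2500)
#' make_windows(idx, 1000)  # (0,1000), (1000,2000), (2000,2500)
#' @export
make_windows <- function(index, window_size) {
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size < 1)
    stop("window_size must be a single integer >= 1")
  window_size <- as.integer(window_size)
  lens <- stats::setNames(index$length, index$chrom)
  tiles <- GenomicRanges::tileGenome(lens, tilewidth = window_size,
                                     cut.last.tile.in.chrom = TRUE)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(tiles)),
                   start = GenomicRanges::start(tiles) - 1,
                   end = GenomicRanges::end(tiles),
                   stringsAsFactors = FALSE)
  df$window <- seq_len(nrow(df))
  attr(df, "window_size") <- window_size
  df
}

#' Merge overlapping and abutting intervals
#'
#' Returns the minimal sorted set of disjoint intervals covering the same
#' bases. Touching intervals (`end == start`) are merged: a base-level mask
#' has no meaningful zero-gap distinction.
#'
#' @param x interval data.frame.
#' @return Merged interval data.frame sorted by chromosome then start.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  .gr_to_df(GenomicRanges::reduce(.as_gr(x)))
}

#' Total intersection length of two interval sets
#'
#' Both sets are merged first, so nested or duplicated records are counted
#' once; the operation is commutative.
#'
#' @param a,b interval data.frames.
#' @return Number of bases present in both sets.
#' @export
intersect_length <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  lv <- sort(unique(c(a$chrom, b$chrom)))
  fake_index <- data.frame(chrom = lv, stringsAsFactors = FALSE)
  ga <- GenomicRanges::reduce(.as_gr(a, fake_index))
  gb <- GenomicRanges::reduce(.as_gr(b, fake_index))
  sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(ga, gb))))
}

#' Fraction of a target interval covered by a mask
#'
#' The mask is merged first; the result is covered bases over target length.
#'
#' @param target single-row interval data.frame (or list with chrom/start/end).
#' @param mask interval data.frame.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(target, mask) {
  t <- data.frame(chrom = as.character(target$chrom[1]),
                  start = as.numeric(target$start[1]),
                  end = as.numeric(target$end[1]), stringsAsFactors = FALSE)
  validate_intervals(t)
  intersect_length(t, mask) / (t$end - t$start)
}

## Internal workhorse: per-window covered base counts against a merged mask,
## computed from a 0/1 coverage Rle with viewSums so the counts are
## integer-exact (fast for many windows).
.window_covered_bases <- function(windows, mask, index) {
  gm <- GenomicRanges::reduce(.as_gr(mask, index))
  cov <- GenomicRanges::coverage(gm, width = stats::setNames(index$length, index$chrom))
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    i <- which(windows$chrom == ch)
    v <- IRanges::Views(cov[[ch]], start = windows$start[i] + 1, end = windows$end[i])
    out[i] <- IRanges::viewSums(v)
  }
  out
}

#' Total bases masked by an annotation set
#'
#' The length of the merged union of all element intervals; nested and
#' duplicated elements are counted once.
#'
#' @param aset repeat annotation data.frame (see [repeat_annotation()]).
#' @return Masked bases (bp).
#' @export
total_masked_bases <- function(aset) {
  m <- merge_intervals(aset[, c("chrom", "start", "end")])
  sum(m$end - m$start)
}

#' Construct a repeat annotation set
#'
#' One annotation set holds the output of one repeat finder ("source"):
#' strand-agnostic intervals labelled with a TE class and, where the class
#' admits one, a superfamily (RepeatMasker-style, e.g. class `LINE`,
#' superfamily `CR1`).
#'
#' @param chrom,start,end element intervals (0-based half-open).
#' @param te_class character vector of classes (one of
#'   `r paste(TE_CLASSES, collapse = ", ")`).
#' @param superfamily character vector; must be empty (`""`) for classes
#'   Simple_repeat, Low_complexity and Unknown.
#' @param source single tool name.
#' @param index optional genome index for validation.
#' @return A `data.frame` with columns chrom, start, end, te_class,
#'   superfamily, source.
#' @export
repeat_annotation <- function(chrom, start, end, te_class = "Unknown",
                              superfamily = "", source = "unknown",
                              index = NULL) {
  n <- max(length(chrom), length(start), length(end))
  x <- data.frame(chrom = rep_len(as.character(chrom), n),
                  start = rep_len(as.numeric(start), n),
                  end = rep_len(as.numeric(end), n),
                  te_class = rep_len(as.character(te_class), n),
                  superfamily = rep_len(as.character(superfamily), n),
                  source = rep_len(as.character(source), n),
                  stringsAsFactors = FALSE)
  validate_annotation(x, index)
  x
}

#' Validate a repeat annotation set
#' @param x annotation data.frame.
#' @param index optional genome index.
#' @return `x`, invisibly.
#' @export
validate_annotation <- function(x, index = NULL) {
  validate_intervals(x, index)
  bad <- setdiff(unique(x$te_class), TE_CLASSES)
  if (length(bad))
    stop("unknown TE class(es): ", paste(bad, collapse = ", "))
  clash <- which(x$te_class %in% .NO_SUPERFAMILY & nzchar(x$superfamily))
  if (length(clash))
    stop("superfamily label on class without superfamilies at row(s) ",
         paste(utils::head(clash, 5), collapse = ", "))
  invisible(x)
}
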