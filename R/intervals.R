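#' Interval algebra
#'
#' Thin, strand-blind wrappers around GenomicRanges set operations with the
#' conventions used throughout this package: half-open set semantics (so
#' bookended intervals do not overlap), any-overlap (>= 1 bp) as the
#' co-location criterion, and deterministic (chrom, start, end, name)
#' ordering.
#'
#' @name interval-algebra
NULL

#' Merge overlapping or nearby intervals
#'
#' Unions intervals that overlap or lie within `max_gap` bp of each other.
#' Bookended intervals (gap 0) are always merged. The result is flattened
#' (no overlapping or bookended members) and sorted.
#'
#' @param gr `GRanges`.
#' @param max_gap maximum gap in bp to merge across (default 0).
#' @return Flattened, sorted `GRanges`.
#' @export
merge_intervals <- function(gr, max_gap = 0) {
  stopifnot(max_gap >= 0)
  GenomicRanges::reduce(sort_intervals(gr), min.gapwidth = max_gap + 1L,
                        ignore.strand = TRUE)
}

#' Subset of `a` overlapping `b` by at least 1 bp
#'
#' @param a,b `GRanges`.
#' @return The members of `a` (original order, no duplicates) with >= 1 bp
#'   overlap in `b`.
#' @export
overlapping_regions <- function(a, b) {
  a[GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE) > 0L]
}

#' Subset of `a` with zero overlap in `b`
#'
#' Complement of [overlapping_regions()]: together they partition `a`.
#'
#' @param a,b `GRanges`.
#' @export
exclusive_regions <- function(a, b) {
  a[GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE) == 0L]
}

#' Extend each interval by a flank and clip to chromosome bounds
#'
#' Each interval becomes `[max(0, start - flank), min(length, end + flank))`.
#' Per-interval identity is preserved (no flattening), so downstream
#' gene linking can attribute genes to the original region.
#'
#' @param gr `GRanges`.
#' @param flank extension in bp on both sides (>= 0).
#' @param sizes named chromosome lengths.
#' @return `GRanges` of the same length and order.
#' @export
extend_clip <- function(gr, flank, sizes) {
  stopifnot(flank >= 0)
  ch <- chrom_of(gr)
  missing <- setdiff(unique(ch), names(sizes))
  if (length(missing))
    stop("chromosome absent from sizes: ", missing[1], call. = FALSE)
  s0 <- pmax(0L, start0(gr) - as.integer(flank))
  e0 <- pmin(as.integer(sizes[ch]), end0(gr) + as.integer(flank))
  out <- gr
  BiocGenerics::start(out) <- s0 + 1L
  BiocGenerics::end(out) <- e0
  out
}

#' Overlap statistics between two region sets
#'
#' Counts, one-directional overlap percentages in both directions, and
#' base-pair Jaccard index on the flattened sets.
#'
#' @param a,b `GRanges`.
#' @return List with `n_a`, `n_b`, `n_a_in_b`, `pct_a_in_b`, `n_b_in_a`,
#'   `pct_b_in_a`, `jaccard_bp`.
#' @export
overlap_stats <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  n_a_in_b <- length(overlapping_regions(a, b))
  n_b_in_a <- length(overlapping_regions(b, a))
  fa <- merge_intervals(a); fb <- merge_intervals(b)
  shared <- sum(BiocGenerics::width(
    GenomicRanges::intersect(fa, fb, ignore.strand = TRUE)))
  uni <- sum(BiocGenerics::width(
    GenomicRanges::union(fa, fb, ignore.strand = TRUE)))
  list(n_a = n_a, n_b = n_b,
       n_a_in_b = n_a_in_b,
       pct_a_in_b = if (n_a > 0) 100 * n_a_in_b / n_a else 0,
       n_b_in_a = n_b_in_a,
       pct_b_in_a = if (n_b > 0) 100 * n_b_in_a / n_b else 0,
       jaccard_bp = if (uni > 0) shared / uni else 0)
}
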