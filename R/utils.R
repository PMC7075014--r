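#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors Rle runValue queryHits subjectHits mcols mcols<-
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths seqlengths<-
#' @importFrom stats p.adjust ppois dpois phyper runif rpois setNames
#' @importFrom utils write.table head
NULL

# Evaluate `code` with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Construct a GRanges from 0-based half-open coordinates
#'
#' All on-disk formats handled by this package (BED, narrowPeak, broadPeak,
#' bedGraph) use 0-based half-open coordinates; in memory the package uses
#' `GRanges` (1-based closed). This constructor and the accessors
#' [start0()]/[end0()] translate between the two conventions exactly.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open span; `start < end` required.
#' @param name optional record labels.
#' @param score optional numeric scores.
#' @param strand strand as `+`, `-` or `.` (unstranded).
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A `GRanges`.
#' @export
as_granges0 <- function(chrom, start, end, name = NULL, score = NULL,
                        strand = ".", seqlengths = NULL) {
  if (any(start < 0) || any(start >= end))
    stop("invalid interval: require 0 <= start < end", call. = FALSE)
  if (length(chrom) == 0L) return(GenomicRanges::GRanges())
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = strand)
  if (!is.null(name)) mcols(gr)$name <- as.character(name)
  if (!is.null(score)) mcols(gr)$score <- as.numeric(score)
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' @rdname as_granges0
#' @param gr a `GRanges`.
#' @export
start0 <- function(gr) BiocGenerics::start(gr) - 1L

#' @rdname as_granges0
#' @export
end0 <- function(gr) BiocGenerics::end(gr)

#' @importFrom BiocGenerics start end width strand
NULL

chrom_of <- function(gr) as.character(seqnames(gr))

# deterministic (chrom, start, end, name) sort order used everywhere
sort_intervals <- function(gr) {
  nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else rep("", length(gr))
  gr[order(chrom_of(gr), BiocGenerics::start(gr), BiocGenerics::end(gr), nm)]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
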