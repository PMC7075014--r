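#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one place. Defaults follow the
#' published ATAC workflow this package reproduces: insertion smoothing
#' `shift = -100`, `extsize = 200`; broad-domain weak cutoff 0.1; region
#' selection threshold `score_threshold = 15` on the log2-sum score; gene
#' window `gene_window = 10000` bp. Bin size (50 bp), pseudocount (1.0,
#' applied after per-million scaling), promoter window (1 kb) and the
#' narrow q cutoff (0.05) are conventions of this implementation.
#'
#' @param shift,extsize insertion smoothing (bp).
#' @param binsize shared bin grid (bp).
#' @param pseudocount added to both conditions before the log2 ratio.
#' @param score_threshold minimum log2-sum score to call a region "more
#'   accessible" in the test condition.
#' @param gene_window region extension for gene linking (bp).
#' @param promoter_window half-width of the promoter around the TSS (bp).
#' @param qcut narrow-peak q cutoff.
#' @param broad_cutoff weak-bin q cutoff for broad domains.
#' @param link_gap broad-domain linking gap (bp; default 4 bins).
#' @param local_window Poisson local-background window (bp).
#' @param excluded_chroms chromosomes dropped outright.
#' @param seed seed echoed into reports (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(shift = -100, extsize = 200, binsize = 50,
                            pseudocount = 1.0, score_threshold = 15,
                            gene_window = 10000, promoter_window = 1000,
                            qcut = 0.05, broad_cutoff = 0.1,
                            link_gap = 4 * binsize, local_window = 10000,
                            excluded_chroms = "chrM", seed = 1) {
  stopifnot(extsize > 0, binsize > 0, pseudocount > 0, gene_window >= 0,
            promoter_window >= 0, qcut > 0, broad_cutoff > 0, link_gap >= 0)
  structure(list(shift = shift, extsize = extsize, binsize = binsize,
                 pseudocount = pseudocount, score_threshold = score_threshold,
                 gene_window = gene_window, promoter_window = promoter_window,
                 qcut = qcut, broad_cutoff = broad_cutoff,
                 link_gap = link_gap, local_window = local_window,
                 excluded_chroms = excluded_chroms, seed = seed),
            class = "pipeline_config")
}

#' Scale two tracks to a common sequencing depth
#'
#' Signal-per-million normalization: each track is scaled so its total
#' signal equals `target` (1e6), leaving relative bin profiles unchanged.
#'
#' @param a,b raw-count [CoverageTrack]s on identical grids.
#' @param target common total signal (default 1e6).
#' @return List of the two scaled tracks (`kind = "normalized"`).
#' @export
depth_normalize <- function(a, b, target = 1e6) {
  if (!same_grid(a, b)) stop("grid mismatch", call. = FALSE)
  ta <- track_total_signal(a); tb <- track_total_signal(b)
  if (ta <= 0 || tb <= 0) stop("zero-signal track", call. = FALSE)
  list(a = scale_track(a, target / ta), b = scale_track(b, target / tb))
}

#' Genome-wide binned log2 ratio between conditions
#'
#' Per bin, `log2((mut + pseudocount) / (ctrl + pseudocount))`, defined on
#' every bin of the genome. Swapping the arguments negates the track.
#'
#' @param mut,ctrl depth-normalized [CoverageTrack]s on identical grids.
#' @param pseudocount positive stabiliser (default 1).
#' @return A `log2_ratio` [CoverageTrack].
#' @export
log2_ratio_track <- function(mut, ctrl, pseudocount = 1) {
  if (!same_grid(mut, ctrl)) stop("grid mismatch", call. = FALSE)
  stopifnot(pseudocount > 0)
  vals <- lapply(names(mut$values), function(ch)
    log2((mut$values[[ch]] + pseudocount) /
           (ctrl$values[[ch]] + pseudocount)))
  names(vals) <- names(mut$values)
  coverage_track(vals, mut$binsize, mut$seqlengths, kind = "log2_ratio")
}

#' Per-region log2-sum differential score
#'
#' For each region, sums the full value of every bin overlapping the region
#' by at least 1 bp — the `bedtools map -o sum` convention (no pro-rating of
#' partially overlapped bins). The higher the score, the more accessible
#' the region is in the numerator condition.
#'
#' @param ratio a `log2_ratio` [CoverageTrack].
#' @param regions `GRanges` (typically the test-condition peak set).
#' @return `regions` with a `log2_sum_score` metadata column, order
#'   preserved.
#' @export
region_sum_scores <- function(ratio, regions) {
  bs <- ratio$binsize
  ch <- chrom_of(regions)
  missing <- setdiff(unique(ch), names(ratio$values))
  if (length(missing))
    stop("chromosome absent from track: ", missing[1], call. = FALSE)
  scores <- vapply(seq_along(regions), function(i) {
    v <- ratio$values[[ch[i]]]
    b1 <- start0(regions)[i] %/% bs + 1L
    b2 <- min(as.integer(ceiling(end0(regions)[i] / bs)), length(v))
    sum(v[b1:b2])
  }, numeric(1))
  out <- regions
  mcols(out)$log2_sum_score <- scores
  out
}

#' Select regions more accessible in the test condition
#'
#' Keeps regions with `log2_sum_score >= tau` and ranks them by descending
#' score (coordinate order breaks ties). The threshold is inclusive.
#'
#' @param scored `GRanges` from [region_sum_scores()].
#' @param tau score threshold (default 15).
#' @return Ranked `GRanges` subset.
#' @export
select_more_accessible <- function(scored, tau = 15) {
  stopifnot(is.finite(tau))
  sc <- mcols(scored)$log2_sum_score
  if (is.null(sc)) stop("regions carry no log2_sum_score", call. = FALSE)
  keep <- scored[sc >= tau]
  ks <- mcols(keep)$log2_sum_score
  keep[order(-ks, chrom_of(keep), BiocGenerics::start(keep),
             BiocGenerics::end(keep))]
}

#' Regions accessible only in the test condition
#'
#' Peaks of the test condition with zero overlap (half-open semantics) in
#' the reference peak set.
#'
#' @param mut_peaks,ctrl_peaks called peak sets (`GRanges`).
#' @return `GRanges` subset of `mut_peaks`.
#' @export
mutant_exclusive_regions <- function(mut_peaks, ctrl_peaks) {
  exclusive_regions(mut_peaks, ctrl_peaks)
}
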