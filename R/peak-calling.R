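#' Insertion-site pileup with shift/extension smoothing
#'
#' Each read contributes its 5' cut position (start on `+`, `end - 1` on
#' `-`, 0-based). A cut at `t` covers `[t + shift, t + shift + extsize)`,
#' clipped to the chromosome; with the ATAC convention `shift = -100`,
#' `extsize = 200` this is a 200-bp window centred on the Tn5 insertion.
#' Bins accumulate covered bases divided by `binsize`, so an unclipped cut
#' adds `extsize / binsize` units of signal in total.
#'
#' @param reads stranded `GRanges` of fragments (strand `*` is treated
#'   as `+`).
#' @param sizes named chromosome lengths.
#' @param shift signed shift in bp applied to the cut before extension.
#' @param extsize extension length in bp (> 0).
#' @param binsize bin width in bp.
#' @return A raw-count [CoverageTrack].
#' @export
insertion_pileup <- function(reads, sizes, shift = -100, extsize = 200,
                             binsize = 50) {
  stopifnot(extsize > 0, binsize > 0)
  vals <- lapply(names(sizes), function(ch)
    numeric(n_bins(sizes[[ch]], binsize)))
  names(vals) <- names(sizes)
  if (length(reads) > 0L) {
    ch <- chrom_of(reads)
    missing <- setdiff(unique(ch), names(sizes))
    if (length(missing))
      stop("chromosome absent from sizes: ", missing[1], call. = FALSE)
    neg <- as.character(strand(reads)) == "-"
    cut0 <- ifelse(neg, end0(reads) - 1L, start0(reads))
    len <- as.numeric(sizes[ch])
    if (any(cut0 < 0 | cut0 >= len))
      stop("read cut site beyond chromosome end", call. = FALSE)
    w_s0 <- pmax(0, cut0 + shift)
    w_e0 <- pmin(len, cut0 + shift + extsize)
    keep <- w_e0 > w_s0
    for (c1 in unique(ch)) {
      i <- which(ch == c1 & keep)
      if (!length(i)) next
      clen <- sizes[[c1]]
      cov <- IRanges::coverage(
        IRanges::IRanges(start = w_s0[i] + 1L, end = w_e0[i]), width = clen)
      nb <- n_bins(clen, binsize)
      w <- rep(binsize, nb); w[nb] <- clen - (nb - 1L) * binsize
      vw <- IRanges::Views(cov, IRanges::successiveIRanges(w))
      vals[[c1]] <- as.numeric(IRanges::viewSums(vw)) / binsize
    }
  }
  coverage_track(vals, binsize, sizes, kind = "raw")
}

#' Pool replicate read sets
#' @param read_sets list of `GRanges`.
#' @return Single concatenated `GRanges` (order-stable).
#' @export
aggregate_replicates <- function(read_sets) {
  stopifnot(length(read_sets) >= 1L)
  if (length(read_sets) == 1L) return(read_sets[[1]])
  do.call(c, unname(read_sets))
}

# centred running mean over a window of `w` bins, renormalised at the edges
.running_mean <- function(v, w) {
  n <- length(v)
  if (w >= n) return(rep(mean(v), n))
  half <- (w - 1) %/% 2
  cs <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + (w - 1L - half))
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Per-bin Poisson p-values against a local background
#'
#' The no-control mode of a MACS2-style caller: for a bin with count `k`,
#' `p = P(Poisson(lambda_local) >= k)` with
#' `lambda_local = max(lambda_genome, lambda_window)`, both estimated from
#' the same track. `lambda_genome` is the mean bin count over the effective
#' genome; `lambda_window` is the running mean over `local_window` bp.
#' Fractional bin counts (from partially overlapping smoothing windows) are
#' handled as `P(X >= k) = P(X > ceiling(k) - 1)`, which is conservative.
#' When a `control` track is supplied (ChIP input) it is scaled to the
#' treatment total and provides both lambda estimates instead.
#'
#' @param track raw-count [CoverageTrack] (the treatment).
#' @param local_window width in bp of the local background window.
#' @param effective_len effective genome length in bp; defaults to the sum
#'   of chromosome lengths of the track.
#' @param control optional raw-count [CoverageTrack] on the same grid.
#' @return List with per-chromosome `pvalues` and `lambda` vectors.
#' @export
poisson_bin_pvalues <- function(track, local_window = 10000,
                                effective_len = NULL, control = NULL) {
  if (track$kind != "raw")
    stop("poisson_bin_pvalues expects a raw-count track", call. = FALSE)
  bs <- track$binsize
  total <- track_total_signal(track)
  if (is.null(effective_len)) effective_len <- sum(track$seqlengths)
  bg <- track
  if (!is.null(control)) {
    if (!same_grid(track, control)) stop("grid mismatch", call. = FALSE)
    ctot <- track_total_signal(control)
    if (ctot <= 0) stop("zero-signal control track", call. = FALSE)
    bg <- scale_track(control, total / ctot, kind = "raw")
  }
  lambda_genome <- track_total_signal(bg) * bs / effective_len
  w_bins <- max(1L, as.integer(round(local_window / bs)))
  pvals <- list(); lambdas <- list()
  for (ch in names(track$values)) {
    k <- track$values[[ch]]
    if (total <= 0) {
      pvals[[ch]] <- rep(1, length(k)); lambdas[[ch]] <- rep(0, length(k))
      next
    }
    lam <- pmax(lambda_genome, .running_mean(bg$values[[ch]], w_bins))
    p <- stats::ppois(ceiling(k) - 1, lam, lower.tail = FALSE)
    p[k <= 0] <- 1
    pvals[[ch]] <- pmin(1, pmax(p, .Machine$double.xmin))
    lambdas[[ch]] <- lam
  }
  list(pvalues = pvals, lambda = lambdas)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Order-preserving wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}

# shared run assembly: contiguous TRUE runs of `flag` per chromosome
.runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Call narrow peaks from an insertion pileup
#'
#' Bins with BH q-value <= `qcut` (q-values computed jointly over all bins
#' of the genome) are merged into contiguous runs (bookended bins join);
#' each run becomes a peak annotated with its summit (centre of the
#' leftmost maximal-pileup bin), minimum p and q, and fold enrichment
#' (summit pileup over local lambda). Peaks shorter than `min_len` are
#' dropped; peaks overlapping the blacklist are removed.
#'
#' @param track raw-count [CoverageTrack] from [insertion_pileup()].
#' @param qcut q-value cutoff (default 0.05).
#' @param local_window,effective_len passed to [poisson_bin_pvalues()].
#' @param min_len minimum peak length in bp (default one bin).
#' @param blacklist optional `GRanges` of excluded regions.
#' @return `GRanges` with metadata `name`, `summit0` (absolute 0-based bp),
#'   `pvalue`, `qvalue`, `fold_enrichment`, plus narrowPeak-style
#'   `signalValue`, `pValue`, `qValue` (-log10), `peak` (summit offset).
#' @export
call_narrow_peaks <- function(track, qcut = 0.05, local_window = 10000,
                              effective_len = NULL, min_len = NULL,
                              blacklist = NULL) {
  bs <- track$binsize
  if (is.null(min_len)) min_len <- bs
  pv <- poisson_bin_pvalues(track, local_window = local_window,
                            effective_len = effective_len)
  chroms <- names(track$values)
  p_all <- unlist(pv$pvalues, use.names = FALSE)
  q_all <- bh_qvalues(p_all)
  q_by <- list(); off <- 0L
  for (ch in chroms) {
    n <- length(pv$pvalues[[ch]])
    q_by[[ch]] <- q_all[(off + 1L):(off + n)]
    off <- off + n
  }
  out <- list()
  for (ch in chroms) {
    q <- q_by[[ch]]; p <- pv$pvalues[[ch]]
    v <- track$values[[ch]]; lam <- pv$lambda[[ch]]
    len <- track$seqlengths[[ch]]
    runs <- .runs_of(q <= qcut)
    if (nrow(runs) == 0L) next
    for (r in seq_len(nrow(runs))) {
      i1 <- runs[r, 1]; i2 <- runs[r, 2]
      s0 <- (i1 - 1L) * bs
      e0 <- min(i2 * bs, len)
      if (e0 - s0 < min_len) next
      j <- i1 - 1L + which.max(v[i1:i2])   # leftmost max bin
      bin_s0 <- (j - 1L) * bs
      summit0 <- min(bin_s0 + bs %/% 2L, e0 - 1L)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, s0 = s0, e0 = e0, summit0 = summit0,
        pvalue = min(p[i1:i2]), qvalue = min(q[i1:i2]),
        fold = v[j] / max(lam[j], .Machine$double.eps))
    }
  }
  if (length(out) == 0L) return(.empty_peaks(narrow = TRUE))
  tab <- do.call(rbind, out)
  gr <- as_granges0(tab$chrom, tab$s0, tab$e0)
  mcols(gr)$name <- sprintf("peak_%d", seq_along(gr))
  mcols(gr)$score <- round(pmin(1000, -10 * log10(tab$qvalue)))
  mcols(gr)$summit0 <- tab$summit0
  mcols(gr)$pvalue <- tab$pvalue
  mcols(gr)$qvalue <- tab$qvalue
  mcols(gr)$fold_enrichment <- tab$fold
  mcols(gr)$signalValue <- tab$fold
  mcols(gr)$pValue <- -log10(tab$pvalue)
  mcols(gr)$qValue <- -log10(tab$qvalue)
  mcols(gr)$peak <- tab$summit0 - tab$s0
  if (!is.null(blacklist))
    gr <- filter_excluded(gr, blacklist, excluded_chroms = character())$intervals
  gr
}

.empty_peaks <- function(narrow = TRUE) {
  gr <- GenomicRanges::GRanges()
  mcols(gr)$name <- character(0)
  mcols(gr)$score <- numeric(0)
  if (narrow) mcols(gr)$summit0 <- integer(0)
  mcols(gr)$pvalue <- numeric(0)
  mcols(gr)$qvalue <- numeric(0)
  mcols(gr)$fold_enrichment <- numeric(0)
  gr
}

#' Call broad domains (repressive histone marks)
#'
#' Implements broad-cutoff linking: bins significant at `broad_cutoff`
#' (weak) form candidate runs; runs containing at least one bin significant
#' at `qcut` (strong) are kept, linked across gaps of up to `link_gap` bp,
#' and reported with the q-value of their strongest constituent bin.
#' An optional matched input `control` supplies the local background.
#'
#' @param track raw-count [CoverageTrack] (the immunoprecipitate).
#' @param control optional raw-count input track on the same grid.
#' @param qcut strong-bin q cutoff (default 0.05).
#' @param broad_cutoff weak-bin q cutoff (default 0.1).
#' @param link_gap maximum gap in bp linked across (default 4 bins).
#' @param local_window,effective_len passed to [poisson_bin_pvalues()].
#' @param blacklist optional `GRanges` of excluded regions.
#' @return `GRanges` with metadata `name`, `qvalue`.
#' @export
call_broad_domains <- function(track, control = NULL, qcut = 0.05,
                               broad_cutoff = 0.1, link_gap = NULL,
                               local_window = 10000, effective_len = NULL,
                               blacklist = NULL) {
  bs <- track$binsize
  if (is.null(link_gap)) link_gap <- 4L * bs
  pv <- poisson_bin_pvalues(track, local_window = local_window,
                            effective_len = effective_len, control = control)
  chroms <- names(track$values)
  p_all <- unlist(pv$pvalues[chroms], use.names = FALSE)
  q_all <- bh_qvalues(p_all)
  cand <- list(); off <- 0L
  for (ch in chroms) {
    n <- length(pv$pvalues[[ch]])
    q <- q_all[(off + 1L):(off + n)]; off <- off + n
    len <- track$seqlengths[[ch]]
    runs <- .runs_of(q <= broad_cutoff)
    if (nrow(runs) == 0L) next
    for (r in seq_len(nrow(runs))) {
      i1 <- runs[r, 1]; i2 <- runs[r, 2]
      qmin <- min(q[i1:i2])
      if (qmin > qcut) next            # needs a strong core
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = ch, s0 = (i1 - 1L) * bs, e0 = min(i2 * bs, len), qvalue = qmin)
    }
  }
  if (length(cand) == 0L) return(.empty_peaks(narrow = FALSE))
  tab <- do.call(rbind, cand)
  gr <- as_granges0(tab$chrom, tab$s0, tab$e0)
  mcols(gr)$qvalue <- tab$qvalue
  merged <- merge_intervals(gr, max_gap = link_gap)
  hits <- GenomicRanges::findOverlaps(merged, gr, ignore.strand = TRUE)
  qmin <- vapply(split(mcols(gr)$qvalue[subjectHits(hits)], queryHits(hits)),
                 min, numeric(1))
  out <- merged
  mcols(out)$name <- sprintf("domain_%d", seq_along(out))
  mcols(out)$score <- round(pmin(1000, -10 * log10(qmin)))
  mcols(out)$qvalue <- as.numeric(qmin)
  mcols(out)$signalValue <- rep(0, length(out))
  mcols(out)$pValue <- rep(-1, length(out))
  mcols(out)$qValue <- -log10(qmin)
  if (!is.null(blacklist))
    out <- filter_excluded(out, blacklist,
                           excluded_chroms = character())$intervals
  out
}
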