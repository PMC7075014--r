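n_bins <- function(len, binsize) as.integer(ceiling(len / binsize))

#' Fixed-width binned coverage track
#'
#' Per-chromosome numeric vectors on a common bin grid. Bin `i` of a
#' chromosome covers `[(i-1)*binsize, i*binsize)` in 0-based coordinates;
#' the last bin is clipped at the chromosome end.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param binsize bin width in bp.
#' @param seqlengths named chromosome lengths; vector lengths must equal
#'   `ceiling(length / binsize)`.
#' @param kind `"raw"` (insertion pileup counts), `"normalized"` (depth
#'   scaled) or `"log2_ratio"`.
#' @return A `CoverageTrack` (S3).
#' @export
coverage_track <- function(values, binsize, seqlengths,
                           kind = c("raw", "normalized", "log2_ratio")) {
  kind <- match.arg(kind)
  stopifnot(is.list(values), binsize > 0,
            identical(sort(names(values)), sort(names(seqlengths))))
  for (ch in names(values)) {
    if (length(values[[ch]]) != n_bins(seqlengths[[ch]], binsize))
      stop("bin vector length mismatch on ", ch, call. = FALSE)
    if (any(!is.finite(values[[ch]])))
      stop("non-finite bin value on ", ch, call. = FALSE)
    if (kind == "raw" && any(values[[ch]] < 0))
      stop("negative raw count on ", ch, call. = FALSE)
  }
  structure(list(values = values[names(seqlengths)],
                 binsize = as.integer(binsize),
                 seqlengths = seqlengths, kind = kind),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack [%s]: %d chromosomes, binsize %d bp, total %.4g\n",
              x$kind, length(x$values), x$binsize, track_total_signal(x)))
  invisible(x)
}

#' Total signal of a track (sum of all bin values)
#' @param track a [CoverageTrack].
#' @export
track_total_signal <- function(track) {
  sum(vapply(track$values, sum, numeric(1)))
}

#' Multiply every bin value by a constant
#' @param track a [CoverageTrack].
#' @param factor positive scale factor.
#' @param kind kind of the returned track.
#' @export
scale_track <- function(track, factor, kind = "normalized") {
  coverage_track(lapply(track$values, `*`, factor), track$binsize,
                 track$seqlengths, kind = kind)
}

same_grid <- function(a, b) {
  identical(a$binsize, b$binsize) &&
    identical(names(a$values), names(b$values)) &&
    identical(a$seqlengths, b$seqlengths)
}

#' Write a track as bedGraph (adjacent equal-valued bins merged, zeros skipped)
#' @param track a [CoverageTrack].
#' @param path output path.
#' @param keep_zero write zero-valued runs too (default FALSE).
#' @export
write_track <- function(track, path, keep_zero = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$binsize
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    len <- track$seqlengths[[ch]]
    r <- rle(v)
    ends0 <- pmin(cumsum(r$lengths) * bs, len)
    starts0 <- c(0, ends0[-length(ends0)])
    keep <- if (keep_zero) rep(TRUE, length(r$values)) else r$values != 0
    if (any(keep))
      writeLines(paste(ch, starts0[keep], ends0[keep],
                       .fmt_num(r$values[keep]), sep = "\t"), con)
  }
  invisible(path)
}

# mean track value over [s0, e0) treating out-of-chromosome bases as 0
window_mean <- function(track, chrom, s0, e0) {
  if (e0 <= s0) return(0)
  v <- track$values[[chrom]]
  if (is.null(v)) stop("chromosome absent from track: ", chrom, call. = FALSE)
  bs <- track$binsize
  len <- track$seqlengths[[chrom]]
  cs0 <- max(0, s0); ce0 <- min(len, e0)
  if (ce0 <= cs0) return(0)
  b1 <- floor(cs0 / bs) + 1L
  b2 <- ceiling(ce0 / bs)
  idx <- b1:b2
  bin_s <- (idx - 1) * bs
  bin_e <- pmin(idx * bs, len)
  ov <- pmin(bin_e, ce0) - pmax(bin_s, cs0)
  sum(v[idx] * ov) / (e0 - s0)
}
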