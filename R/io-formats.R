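#' Read a chrom.sizes file
#'
#' Two-column tab-separated file of chromosome name and length in bp.
#'
#' @param path file path.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric"))
  if (any(duplicated(tab[[1]]))) stop("duplicated chromosome names in ", path,
                                      call. = FALSE)
  if (any(tab[[2]] <= 0)) stop("non-positive chromosome length in ", path,
                               call. = FALSE)
  stats::setNames(as.integer(tab[[2]]), tab[[1]])
}

#' Write a chrom.sizes file
#' @param sizes named vector of chromosome lengths.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.integer(sizes)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

.read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines[nzchar(lines)]
}

.is_int <- function(x) grepl("^-?[0-9]+$", x)

#' Read BED / narrowPeak / broadPeak intervals
#'
#' Reads any BED-family dialect (3+ tab-separated columns, 0-based half-open
#' coordinates). narrowPeak (BED6+4) and broadPeak (BED6+3) extra columns are
#' preserved as metadata columns `signalValue`, `pValue`, `qValue` and (narrow
#' only) `peak`, matching the ENCODE column names; p/q are on the -log10 scale
#' those formats use. Malformed records raise an error naming the line.
#'
#' @param path file path.
#' @return `GRanges` in file order. A `.` strand becomes `*`.
#' @export
read_intervals <- function(path) {
  lines <- .read_tab_lines(path)
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop("line ", which(ncols < 3L)[1], ": fewer than 3 columns", call. = FALSE)
  nc <- min(ncols)
  m <- matrix(unlist(lapply(fields, `[`, seq_len(nc))), ncol = nc, byrow = TRUE)
  bad <- !.is_int(m[, 2]) | !.is_int(m[, 3])
  if (any(bad))
    stop("line ", which(bad)[1], ": non-integer coordinate", call. = FALSE)
  s <- as.integer(m[, 2]); e <- as.integer(m[, 3])
  bad <- s < 0L | s >= e
  if (any(bad))
    stop("line ", which(bad)[1], ": require 0 <= start < end", call. = FALSE)
  strand <- if (nc >= 6L) m[, 6] else rep(".", nrow(m))
  bad <- !strand %in% c("+", "-", ".")
  if (any(bad))
    stop("line ", which(bad)[1], ": unknown strand symbol '",
         strand[which(bad)[1]], "'", call. = FALSE)
  gr <- as_granges0(m[, 1], s, e, strand = strand)
  if (nc >= 4L) mcols(gr)$name <- m[, 4]
  if (nc >= 5L) mcols(gr)$score <- suppressWarnings(as.numeric(m[, 5]))
  if (nc >= 9L) {
    mcols(gr)$signalValue <- as.numeric(m[, 7])
    mcols(gr)$pValue <- as.numeric(m[, 8])
    mcols(gr)$qValue <- as.numeric(m[, 9])
  }
  if (nc >= 10L) mcols(gr)$peak <- as.integer(m[, 10])
  gr
}

.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "." else format(v, digits = 10, trim = TRUE)
  }, character(1))
}

#' Write intervals in a BED-family dialect
#'
#' Round-trips with [read_intervals()] on all shared fields.
#'
#' @param gr `GRanges`, optionally with `name`, `score`, `signalValue`,
#'   `pValue`, `qValue`, `peak` metadata columns.
#' @param path output path.
#' @param dialect one of `"BED"`, `"narrowPeak"`, `"broadPeak"`. BED writes
#'   3--6 columns depending on which metadata are present.
#' @export
write_intervals <- function(gr, path, dialect = c("BED", "narrowPeak",
                                                  "broadPeak")) {
  dialect <- match.arg(dialect)
  n <- length(gr)
  if (n == 0L) { file.create(path); return(invisible(path)) }
  mc <- mcols(gr)
  nm <- if (!is.null(mc$name)) as.character(mc$name) else rep(".", n)
  sc <- if (!is.null(mc$score)) .fmt_num(mc$score) else rep("0", n)
  st <- as.character(strand(gr)); st[st == "*"] <- "."
  cols <- list(chrom_of(gr), start0(gr), end0(gr))
  if (dialect == "BED") {
    has6 <- any(st != ".")
    has5 <- has6 || !is.null(mc$score)
    has4 <- has5 || !is.null(mc$name)
    if (has4) cols <- c(cols, list(nm))
    if (has5) cols <- c(cols, list(sc))
    if (has6) cols <- c(cols, list(st))
  } else {
    sv <- if (!is.null(mc$signalValue)) .fmt_num(mc$signalValue) else rep("0", n)
    pv <- if (!is.null(mc$pValue)) .fmt_num(mc$pValue) else rep("-1", n)
    qv <- if (!is.null(mc$qValue)) .fmt_num(mc$qValue) else rep("-1", n)
    cols <- c(cols, list(nm, sc, st, sv, pv, qv))
    if (dialect == "narrowPeak") {
      pk <- if (!is.null(mc$peak)) as.integer(mc$peak) else rep(-1L, n)
      cols <- c(cols, list(pk))
    }
  }
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read a bedGraph onto a fixed bin grid
#'
#' Resamples arbitrary-width bedGraph records onto `binsize`-bp bins by
#' length-weighted mean; uncovered bases contribute 0. Records must be
#' non-overlapping within each chromosome.
#'
#' @param path bedGraph path (4 columns: chrom, start, end, value).
#' @param sizes named chromosome lengths (see [read_chrom_sizes()]).
#' @param binsize bin width in bp (> 0).
#' @param kind stored track kind; see [coverage_track()].
#' @return A [CoverageTrack].
#' @export
read_track <- function(path, sizes, binsize, kind = "raw") {
  stopifnot(binsize > 0)
  lines <- .read_tab_lines(path)
  vals <- lapply(seq_along(sizes), function(i)
    numeric(n_bins(sizes[[i]], binsize)))
  names(vals) <- names(sizes)
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4L))
      stop("line ", which(lengths(fields) < 4L)[1], ": bedGraph needs 4 columns",
           call. = FALSE)
    m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4L, byrow = TRUE)
    chrom <- m[, 1]; s <- as.numeric(m[, 2]); e <- as.numeric(m[, 3])
    v <- as.numeric(m[, 4])
    unknown <- !chrom %in% names(sizes)
    if (any(unknown))
      stop("chromosome absent from sizes: ", chrom[which(unknown)[1]],
           call. = FALSE)
    if (any(s < 0 | s >= e)) stop("invalid bedGraph interval", call. = FALSE)
    if (any(e > sizes[chrom]))
      stop("bedGraph record beyond chromosome end", call. = FALSE)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      o <- i[order(s[i])]
      if (any(s[o][-1] < e[o][-length(o)]))
        stop("overlapping bedGraph records on ", ch, call. = FALSE)
      len <- sizes[[ch]]
      # base-level Rle (gaps = 0), then length-weighted bin means
      starts <- s[o]; ends <- e[o]; vv <- v[o]
      gap_len <- c(starts, len) - c(0, ends)
      lens <- as.integer(rbind(gap_len[seq_along(vv)], ends - starts))
      rvals <- as.numeric(rbind(numeric(length(vv)), vv))
      lens <- c(lens, gap_len[length(gap_len)])
      rvals <- c(rvals, 0)
      keep <- lens > 0
      rle <- S4Vectors::Rle(rvals[keep], lens[keep])
      nb <- n_bins(len, binsize)
      w <- rep(binsize, nb); w[nb] <- len - (nb - 1L) * binsize
      vw <- IRanges::Views(rle, IRanges::successiveIRanges(w))
      vals[[ch]] <- as.numeric(IRanges::viewMeans(vw))
    }
  }
  coverage_track(vals, binsize, sizes, kind = kind)
}

#' Read gene models from BED12 or BED6
#'
#' BED12 supplies exon blocks and CDS (thickStart/thickEnd; equal values mean
#' a non-coding transcript). BED6 genes are treated as single-exon, non-coding
#' spans. The TSS is `start` on `+` and `end - 1` on `-` (0-based).
#'
#' @param path file path.
#' @return `GRanges` of transcript spans with metadata columns `gene_id`,
#'   `cds_start0`/`cds_end0` (NA when non-coding) and `exon_starts0`/
#'   `exon_ends0` (`IntegerList`, absolute 0-based half-open).
#' @export
read_gene_models <- function(path) {
  lines <- .read_tab_lines(path)
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- min(lengths(fields))
  if (nc < 6L) stop("gene models need >= 6 columns (BED6 or BED12)",
                    call. = FALSE)
  m <- matrix(unlist(lapply(fields, `[`, seq_len(min(nc, 12L)))),
              ncol = min(nc, 12L), byrow = TRUE)
  strand <- m[, 6]
  bad <- !strand %in% c("+", "-")
  if (any(bad))
    stop("line ", which(bad)[1], ": unknown strand symbol '",
         strand[which(bad)[1]], "' (gene models must be stranded)",
         call. = FALSE)
  s <- as.integer(m[, 2]); e <- as.integer(m[, 3])
  if (any(s >= e)) stop("line ", which(s >= e)[1], ": txStart >= txEnd",
                        call. = FALSE)
  n <- nrow(m)
  if (ncol(m) >= 12L) {
    cds_s <- as.integer(m[, 7]); cds_e <- as.integer(m[, 8])
    none <- cds_s == cds_e
    cds_s[none] <- NA_integer_; cds_e[none] <- NA_integer_
    sizes_l <- lapply(strsplit(m[, 11], ",", fixed = TRUE), as.integer)
    offs_l <- lapply(strsplit(m[, 12], ",", fixed = TRUE), as.integer)
    ex_s <- vector("list", n); ex_e <- vector("list", n)
    for (i in seq_len(n)) {
      es <- s[i] + offs_l[[i]]
      ee <- es + sizes_l[[i]]
      if (is.unsorted(es, strictly = TRUE) || any(ee[-length(ee)] > es[-1]))
        stop("line ", i, ": exons unsorted or overlapping", call. = FALSE)
      if (any(es < s[i]) || any(ee > e[i]))
        stop("line ", i, ": exon outside transcript span", call. = FALSE)
      ex_s[[i]] <- es; ex_e[[i]] <- ee
    }
  } else {
    cds_s <- rep(NA_integer_, n); cds_e <- rep(NA_integer_, n)
    ex_s <- as.list(s); ex_e <- as.list(e)
  }
  gr <- as_granges0(m[, 1], s, e, strand = strand)
  mcols(gr)$gene_id <- m[, 4]
  mcols(gr)$cds_start0 <- cds_s
  mcols(gr)$cds_end0 <- cds_e
  mcols(gr)$exon_starts0 <- IRanges::IntegerList(ex_s)
  mcols(gr)$exon_ends0 <- IRanges::IntegerList(ex_e)
  gr
}

#' Write gene models as BED12
#' @param genes `GRanges` as returned by [read_gene_models()].
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  n <- length(genes)
  if (n == 0L) { file.create(path); return(invisible(path)) }
  mc <- mcols(genes)
  s <- start0(genes); e <- end0(genes)
  cds_s <- ifelse(is.na(mc$cds_start0), s, mc$cds_start0)
  cds_e <- ifelse(is.na(mc$cds_end0), s, mc$cds_end0)
  ex_s <- as.list(mc$exon_starts0); ex_e <- as.list(mc$exon_ends0)
  lines <- vapply(seq_len(n), function(i) {
    sizes <- ex_e[[i]] - ex_s[[i]]
    offs <- ex_s[[i]] - s[i]
    paste(chrom_of(genes)[i], s[i], e[i], mc$gene_id[i], 0,
          as.character(strand(genes))[i], cds_s[i], cds_e[i], "0",
          length(sizes), paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offs, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Transcription start sites (0-based)
#' @param genes gene models (`GRanges` with strand).
#' @return Integer vector: `start` on `+`, `end - 1` on `-`.
#' @export
tss0 <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start0(genes), end0(genes) - 1L)
}

#' Remove reads/regions on excluded chromosomes or overlapping a blacklist
#'
#' Mirrors the standard ATAC-seq hygiene step: drop everything aligned to the
#' mitochondrial genome and to artifact-prone blacklist regions. Any overlap
#' of >= 1 bp with a blacklist interval removes the record; bookended
#' intervals (half-open touch) do not overlap.
#'
#' @param gr `GRanges` records (reads or peaks).
#' @param blacklist `GRanges` of excluded regions, or NULL.
#' @param excluded_chroms character vector of chromosome names to drop
#'   entirely (default `"chrM"`).
#' @return List with `intervals` (survivors, input order preserved),
#'   `n_removed`, `n_excluded_chrom`, `n_blacklist`.
#' @export
filter_excluded <- function(gr, blacklist = NULL,
                            excluded_chroms = "chrM") {
  drop_chrom <- chrom_of(gr) %in% excluded_chroms
  drop_bl <- rep(FALSE, length(gr))
  if (!is.null(blacklist) && length(blacklist) > 0L) {
    drop_bl <- GenomicRanges::countOverlaps(gr, blacklist,
                                            ignore.strand = TRUE) > 0L
  }
  drop <- drop_chrom | drop_bl
  list(intervals = gr[!drop],
       n_removed = sum(drop),
       n_excluded_chrom = sum(drop_chrom),
       n_blacklist = sum(drop_bl & !drop_chrom))
}

#' Read a differential-expression table
#'
#' Tab-separated with header; columns `gene_id`, `log2fc`, `padj` (an
#' optional `direction` column is validated against the fold-change sign).
#'
#' @param path file path.
#' @return data.frame with `gene_id`, `log2fc`, `padj`, `direction`
#'   (`"up"`/`"down"` in the test condition).
#' @export
read_de_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(tab)))
    stop("DE table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(duplicated(tab$gene_id))) stop("duplicated gene_id in DE table",
                                         call. = FALSE)
  if (any(tab$padj < 0 | tab$padj > 1)) stop("padj outside [0, 1]",
                                             call. = FALSE)
  dir <- ifelse(tab$log2fc > 0, "up", "down")
  if (!is.null(tab$direction) && any(tab$direction != dir))
    stop("direction column inconsistent with log2fc sign", call. = FALSE)
  tab$direction <- dir
  tab[, c("gene_id", "log2fc", "padj", "direction")]
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- .read_tab_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
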