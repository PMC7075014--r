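FEATURE_CLASSES <- c("promoter", "utr5", "utr3", "exon", "intron",
                     "distal_intergenic")

# Pooled class region sets, in priority order. UTRs need CDS coordinates;
# non-coding genes contribute exon/intron only.
.feature_sets <- function(genes, promoter_window) {
  mc <- mcols(genes)
  ch <- chrom_of(genes)
  tss <- tss0(genes)
  prom <- as_granges0(ch, pmax(0, tss - promoter_window),
                      tss + promoter_window)
  nex <- lengths(mc$exon_starts0)
  exons <- as_granges0(rep(ch, nex),
                       unlist(mc$exon_starts0), unlist(mc$exon_ends0))
  coding <- !is.na(mc$cds_start0)
  plus <- as.character(strand(genes)) == "+"
  u5 <- list(); u3 <- list()
  add_span <- function(lst, ch, s, e) {
    if (e > s) c(lst, list(c(ch = ch, s = s, e = e))) else lst
  }
  for (i in which(coding)) {
    s <- start0(genes)[i]; e <- end0(genes)[i]
    cs <- mc$cds_start0[i]; ce <- mc$cds_end0[i]
    if (plus[i]) {
      u5 <- add_span(u5, ch[i], s, cs); u3 <- add_span(u3, ch[i], ce, e)
    } else {
      u5 <- add_span(u5, ch[i], ce, e); u3 <- add_span(u3, ch[i], s, cs)
    }
  }
  span_gr <- function(lst) {
    if (!length(lst)) return(GenomicRanges::GRanges())
    m <- do.call(rbind, lst)
    as_granges0(m[, 1], as.integer(m[, 2]), as.integer(m[, 3]))
  }
  exred <- GenomicRanges::reduce(exons, ignore.strand = TRUE)
  utr5 <- GenomicRanges::intersect(exred, merge_intervals(span_gr(u5)),
                                   ignore.strand = TRUE)
  utr3 <- GenomicRanges::intersect(exred, merge_intervals(span_gr(u3)),
                                   ignore.strand = TRUE)
  bodies <- GenomicRanges::reduce(as_granges0(ch, start0(genes), end0(genes)),
                                  ignore.strand = TRUE)
  introns <- GenomicRanges::setdiff(bodies, exred, ignore.strand = TRUE)
  list(promoter = GenomicRanges::reduce(prom, ignore.strand = TRUE),
       utr5 = utr5, utr3 = utr3, exon = exred, intron = introns)
}

#' Classify regions by genomic feature
#'
#' Each region is assigned the highest-priority feature class it overlaps
#' (>= 1 bp): promoter > 5'UTR > 3'UTR > exon > intron > distal intergenic.
#' The promoter is `[TSS - promoter_window, TSS + promoter_window)`,
#' strand-aware through the TSS definition.
#'
#' @param regions `GRanges`.
#' @param genes gene models (see [read_gene_models()]).
#' @param promoter_window half-width in bp (default 1000).
#' @return Factor over the six feature classes, one value per region.
#' @export
classify_regions <- function(regions, genes, promoter_window = 1000) {
  sets <- .feature_sets(genes, promoter_window)
  cls <- rep("distal_intergenic", length(regions))
  un <- rep(TRUE, length(regions))
  for (nm in names(sets)) {
    if (!any(un)) break
    hit <- GenomicRanges::countOverlaps(regions, sets[[nm]],
                                        ignore.strand = TRUE) > 0L
    cls[un & hit] <- nm
    un <- un & !hit
  }
  factor(cls, levels = FEATURE_CLASSES)
}

#' Genomic feature distribution of regions vs. whole-genome baseline
#'
#' The region column gives the fraction of regions in each class; the
#' baseline column classifies every base of the genome by the same priority
#' rule and reports per-base fractions. Both columns sum to 1.
#'
#' @param regions non-empty `GRanges`.
#' @param genes gene models.
#' @param sizes named chromosome lengths.
#' @param promoter_window half-width in bp.
#' @return data.frame with `class`, `region_prop`, `genome_prop`.
#' @export
genomic_distribution <- function(regions, genes, sizes,
                                 promoter_window = 1000) {
  if (length(regions) == 0L) stop("empty region list", call. = FALSE)
  cls <- classify_regions(regions, genes, promoter_window)
  region_prop <- as.numeric(table(cls)) / length(regions)
  sets <- .feature_sets(genes, promoter_window)
  genome <- as_granges0(names(sizes), rep(0L, length(sizes)),
                        as.integer(sizes))
  total <- sum(as.numeric(sizes))
  assigned <- GenomicRanges::GRanges()
  base_counts <- numeric(0)
  for (nm in names(sets)) {
    clipped <- GenomicRanges::intersect(
      GenomicRanges::reduce(sets[[nm]], ignore.strand = TRUE), genome,
      ignore.strand = TRUE)
    own <- GenomicRanges::setdiff(clipped, assigned, ignore.strand = TRUE)
    base_counts[nm] <- sum(as.numeric(BiocGenerics::width(own)))
    assigned <- GenomicRanges::union(assigned, own, ignore.strand = TRUE)
  }
  base_counts["distal_intergenic"] <- total - sum(base_counts)
  data.frame(class = factor(FEATURE_CLASSES, levels = FEATURE_CLASSES),
             region_prop = region_prop,
             genome_prop = as.numeric(base_counts[FEATURE_CLASSES]) / total)
}

#' Link regions to genes within a window
#'
#' A region links a gene when the region extended by `w` bp on both sides
#' overlaps the gene's transcript span by >= 1 bp (equivalently, region and
#' gene lie within `w` bp of each other). One row per (region, gene) pair.
#'
#' @param regions `GRanges`.
#' @param genes gene models.
#' @param w window in bp (default 10000).
#' @return data.frame with `region_idx`, `chrom`, `start0`, `end0`,
#'   `gene_id`, `distance` (bp between region and gene span, 0 when they
#'   overlap).
#' @export
link_genes <- function(regions, genes, w = 10000) {
  stopifnot(w >= 0)
  # extension is unclipped on the right (overhang cannot create spurious
  # gene overlaps), so drop seqinfo to keep GRanges validity happy
  ext <- GenomicRanges::GRanges(
    seqnames = chrom_of(regions),
    ranges = IRanges::IRanges(
      start = pmax(1L, BiocGenerics::start(regions) - as.integer(w)),
      end = BiocGenerics::end(regions) + as.integer(w)))
  hits <- GenomicRanges::findOverlaps(ext, genes, ignore.strand = TRUE)
  qi <- queryHits(hits); si <- subjectHits(hits)
  dist <- GenomicRanges::distance(regions[qi], genes[si],
                                  ignore.strand = TRUE)
  data.frame(region_idx = qi,
             chrom = chrom_of(regions)[qi],
             start0 = start0(regions)[qi],
             end0 = end0(regions)[qi],
             gene_id = mcols(genes)$gene_id[si],
             distance = as.integer(dist),
             stringsAsFactors = FALSE)
}

#' Regions co-located with differentially expressed genes
#'
#' Subsets scored regions to those linked (via [link_genes()]) to at least
#' one gene present in the differential-expression table, and reports the
#' paired (region, gene) rows.
#'
#' @param scored `GRanges` with `log2_sum_score` (from
#'   [region_sum_scores()]).
#' @param de data.frame from [read_de_table()].
#' @param genes gene models.
#' @param w linking window in bp.
#' @return List with `regions` (`GRanges` subset, input order) and `table`
#'   (region, gene_id, log2_sum_score, log2fc, direction, distance).
#' @export
colocate_de <- function(scored, de, genes, w = 10000) {
  if (nrow(de) == 0L) stop("empty DE table", call. = FALSE)
  known <- de$gene_id %in% mcols(genes)$gene_id
  if (any(!known))
    warning("DE gene ids absent from gene models: ",
            paste(utils::head(de$gene_id[!known], 5), collapse = ", "),
            if (sum(!known) > 5) " ..." else "")
  links <- link_genes(scored, genes, w)
  links <- links[links$gene_id %in% de$gene_id, , drop = FALSE]
  i <- match(links$gene_id, de$gene_id)
  tab <- data.frame(links,
                    log2_sum_score =
                      mcols(scored)$log2_sum_score[links$region_idx],
                    log2fc = de$log2fc[i], direction = de$direction[i],
                    stringsAsFactors = FALSE)
  list(regions = scored[sort(unique(links$region_idx))], table = tab)
}

#' Regions overlapping chromatin-mark domains or TF peaks
#'
#' Any-overlap subset with the per-region overlapping base count.
#'
#' @param regions `GRanges`.
#' @param domains `GRanges` (broad domains or a peak set).
#' @return `GRanges` subset of `regions` with an `overlap_bp` metadata
#'   column.
#' @export
colocate_marks <- function(regions, domains) {
  hits <- GenomicRanges::findOverlaps(regions, domains, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    out <- regions[integer(0)]
    mcols(out)$overlap_bp <- integer(0)
    return(out)
  }
  ov <- BiocGenerics::width(IRanges::pintersect(
    GenomicRanges::ranges(regions)[queryHits(hits)],
    GenomicRanges::ranges(domains)[subjectHits(hits)]))
  bp <- vapply(split(ov, queryHits(hits)), sum, numeric(1))
  idx <- sort(unique(queryHits(hits)))
  out <- regions[idx]
  mcols(out)$overlap_bp <- as.integer(bp[as.character(idx)])
  out
}

.check_universe <- function(set, universe, what) {
  off <- setdiff(set, universe)
  if (length(off))
    stop(what, " not in universe: ",
         paste(utils::head(off, 5), collapse = ", "),
         if (length(off) > 5) " ..." else "", call. = FALSE)
}

#' Overlap of two gene sets with a hypergeometric tail p-value
#'
#' `p = P(X >= n_overlap)` where `X ~ Hypergeometric(|universe|, |b|, |a|)`
#' — the chance of drawing at least the observed overlap when `|a|` genes
#' are sampled from the universe.
#'
#' @param a,b character vectors of gene ids (subsets of `universe`).
#' @param universe character vector of all eligible gene ids.
#' @return List with `n_a`, `n_b`, `n_overlap`, `fraction_of_a`, `p_value`.
#' @export
signature_overlap <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  .check_universe(a, universe, "set a genes")
  .check_universe(b, universe, "set b genes")
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(b), length(universe) - length(b),
                     length(a), lower.tail = FALSE)
  list(n_a = length(a), n_b = length(b), n_overlap = k,
       fraction_of_a = if (length(a) > 0) k / length(a) else 0,
       p_value = p)
}

#' Gene-set enrichment against a user-supplied library
#'
#' Hypergeometric over-representation test of a query gene list against
#' each set of a GMT-style library, with odds ratios from the 2x2 table and
#' BH-adjusted q-values. Rows are sorted by p-value then set name.
#'
#' @param query character vector of gene ids (non-empty).
#' @param library named list of character vectors (see [read_gmt()]).
#' @param universe character vector of all eligible gene ids.
#' @return data.frame with `set`, `n_set`, `n_overlap`, `odds_ratio`,
#'   `p_value`, `q_value`.
#' @export
geneset_enrichment <- function(query, library, universe) {
  if (length(query) == 0L) stop("empty query gene list", call. = FALSE)
  if (length(library) == 0L) stop("empty library", call. = FALSE)
  query <- unique(query); universe <- unique(universe)
  .check_universe(query, universe, "query genes")
  rows <- lapply(names(library), function(nm) {
    s <- intersect(unique(library[[nm]]), universe)
    k <- length(intersect(query, s))
    n_q <- length(query); n_s <- length(s); U <- length(universe)
    or <- (k * (U - n_q - n_s + k)) / max(1e-300, (n_q - k) * (n_s - k))
    if ((n_q - k) == 0 || (n_s - k) == 0) or <- Inf
    if (k == 0) or <- 0
    p <- stats::phyper(k - 1, n_s, U - n_s, n_q, lower.tail = FALSE)
    data.frame(set = nm, n_set = n_s, n_overlap = k, odds_ratio = or,
               p_value = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q_value <- bh_qvalues(tab$p_value)
  tab[order(tab$p_value, tab$set), , drop = FALSE]
}

#' Coverage matrix around regions (heat-map input)
#'
#' `center` mode: `nbins` equal windows across
#' `[midpoint - flank, midpoint + flank)`. `scale` mode: the region body
#' rescaled to `nbins` windows. Cells are mean track signal per window
#' (bases beyond the chromosome contribute 0). Rows are ordered by
#' descending `log2_sum_score` when present (or by `scores`), else input
#' order.
#'
#' @param track a [CoverageTrack].
#' @param regions `GRanges`.
#' @param mode `"center"` or `"scale"`.
#' @param flank half-width in bp (center mode).
#' @param nbins number of windows per row.
#' @param scores optional numeric vector used to order rows (descending).
#' @param row_normalize divide each row by its maximum absolute value.
#' @return List with `matrix` (rows = regions in plotted order) and
#'   `regions` (the reordered `GRanges`).
#' @export
coverage_matrix <- function(track, regions, mode = c("center", "scale"),
                            flank = 2000, nbins = 50, scores = NULL,
                            row_normalize = FALSE) {
  mode <- match.arg(mode)
  stopifnot(nbins > 0)
  if (is.null(scores)) scores <- mcols(regions)$log2_sum_score
  ord <- if (!is.null(scores))
    order(-scores, chrom_of(regions), BiocGenerics::start(regions))
  else seq_along(regions)
  regions <- regions[ord]
  n <- length(regions)
  m <- matrix(0, nrow = n, ncol = nbins)
  for (i in seq_len(n)) {
    ch <- chrom_of(regions)[i]
    if (mode == "center") {
      mid <- (start0(regions)[i] + end0(regions)[i]) %/% 2
      edges <- floor(seq(mid - flank, mid + flank, length.out = nbins + 1))
    } else {
      edges <- floor(seq(start0(regions)[i], end0(regions)[i],
                         length.out = nbins + 1))
    }
    m[i, ] <- vapply(seq_len(nbins), function(j)
      window_mean(track, ch, edges[j], edges[j + 1]), numeric(1))
  }
  if (row_normalize) {
    mx <- apply(abs(m), 1, max)
    mx[mx == 0] <- 1
    m <- m / mx
  }
  colnames(m) <- if (mode == "center")
    floor(seq(-flank, flank, length.out = nbins + 1))[seq_len(nbins)]
  else sprintf("%.3f", seq(0, 1, length.out = nbins + 1)[seq_len(nbins)])
  list(matrix = m, regions = regions)
}
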