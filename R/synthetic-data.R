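#' Configuration for the synthetic-data generator
#'
#' Defines the simulated study: a small two-chromosome genome, planted
#' accessible regions of four categories (`shared`, `mutant_only`,
#' `control_only`, `fold_changed`), Tn5 insertion sampling with Poisson
#' background, broad repressive-mark domains over a fraction of the
#' fold-changed regions, point-source TF peaks, and a matched DE table plus
#' a "multilineage"-style gene signature. All outputs are a pure function
#' of this configuration (including `seed`).
#'
#' Depths are expressed relative to the background rate; the default is
#' symmetric (`depth_mutant = depth_control = 1`). Setting
#' `depth_mutant = 1/25` emulates the severe cell-number asymmetry of a
#' ~1,000- vs ~25,000-cell experiment.
#'
#' @param seed mandatory integer seed.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_genes genes to place (error if they do not fit).
#' @param n_shared,n_mutant_only,n_control_only,n_fold_changed planted
#'   region counts per category.
#' @param region_len_range planted region length range in bp.
#' @param background_rate Tn5 cuts per bp at depth 1.
#' @param enrichment fold elevation of the cut rate inside planted
#'   accessible regions (in the condition(s) where they are open).
#' @param delta extra log2 fold change of fold_changed regions in the
#'   mutant (mutant rate = background * enrichment * 2^delta).
#' @param depth_mutant,depth_control per-condition depth factors.
#' @param fragment_len emitted fragment length in bp (the pileup only uses
#'   the 5' cut).
#' @param frac_fold_changed_at_promoters fraction of fold_changed regions
#'   planted straddling a TSS.
#' @param domain_fraction fraction of fold_changed regions covered by a
#'   planted broad repressive-mark domain.
#' @param domain_len_range broad-domain length range in bp.
#' @param chip_depth depth factor of the ChIP libraries (deep,
#'   ChIPmentation-style input).
#' @param chip_enrichment fold elevation of the mark rate inside domains.
#' @param tf_fraction fraction of fold_changed regions carrying a planted
#'   TF binding site.
#' @param tf_peak_len TF site width in bp (point source, <= 300).
#' @param tf_enrichment fold elevation at TF sites.
#' @param de_prob probability that a gene near a mutant_only/fold_changed
#'   region is called differentially expressed (up).
#' @param n_de total DE table size (padded with random genes).
#' @param sig_overlap_fraction per-DE-gene probability of membership in the
#'   planted signature (so the expected signature/DE overlap fraction).
#' @param gene_window window used when marking DE genes near regions.
#' @param n_blacklist,blacklist_len decoy blacklist regions.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed,
                             chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                             n_genes = 200,
                             n_shared = 20, n_mutant_only = 20,
                             n_control_only = 0, n_fold_changed = 20,
                             region_len_range = c(300, 500),
                             background_rate = 0.002,
                             enrichment = 22, delta = 3,
                             depth_mutant = 1, depth_control = 1,
                             fragment_len = 100,
                             frac_fold_changed_at_promoters = 0.5,
                             domain_fraction = 0.5,
                             domain_len_range = c(5000, 10000),
                             chip_depth = 5, chip_enrichment = 8,
                             tf_fraction = 0.5, tf_peak_len = 200,
                             tf_enrichment = 20,
                             de_prob = 0.9, n_de = 60,
                             sig_overlap_fraction = 0.30,
                             gene_window = 10000,
                             n_blacklist = 2, blacklist_len = 2000) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(background_rate > 0, enrichment >= 1, depth_mutant > 0,
            depth_control > 0, chip_depth > 0, all(chrom_lengths > 0))
  cfg <- as.list(environment())
  structure(cfg, class = "generator_config")
}

# uniform integers on [lo, hi] that tolerate lo == hi (sample() would
# misread a scalar as 1:n)
.rint <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

# deterministic non-overlapping placement of n lengths on [0, L) with a
# minimum gap; returns start positions
.place_spans <- function(lens, L, min_gap) {
  n <- length(lens)
  need <- sum(lens) + (n + 1) * min_gap
  if (need > L) stop("genome too small to place requested features",
                     call. = FALSE)
  slack <- L - need
  extra <- as.vector(stats::rmultinom(1, slack, rep(1, n + 1)))
  gaps <- min_gap + extra
  starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(lens[-n]))
  as.integer(starts)
}

#' Build a deterministic toy genome with gene models
#'
#' Genes are non-overlapping, on both strands, each with >= 2 exons and a
#' CDS, so every feature class (promoter, UTRs, exon, intron, intergenic)
#' is represented.
#'
#' @param config a [generator_config()].
#' @return List with `sizes` (named lengths) and `genes` (`GRanges` in the
#'   [read_gene_models()] layout).
#' @export
make_toy_genome <- function(config) {
  with_seed(config$seed, {
    sizes <- stats::setNames(as.integer(config$chrom_lengths),
                             names(config$chrom_lengths))
    n_per <- round(config$n_genes * config$chrom_lengths /
                     sum(config$chrom_lengths))
    n_per[length(n_per)] <- config$n_genes - sum(n_per[-length(n_per)])
    rows <- list()
    for (ci in seq_along(sizes)) {
      n <- n_per[ci]
      if (n == 0L) next
      lens <- sample(2000:5000, n, replace = TRUE)
      starts <- .place_spans(lens, sizes[[ci]], min_gap = 1000)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      if (length(unique(strands)) == 1L) strands[1] <- setdiff(c("+", "-"),
                                                              strands[1])
      for (i in seq_len(n)) {
        k <- sample(2:4, 1)
        nseg <- 2L * k - 1L
        segs <- 60 + as.vector(stats::rmultinom(1, lens[i] - nseg * 60,
                                                rep(1, nseg)))
        bounds <- starts[i] + cumsum(c(0, segs))
        ex_idx <- seq(1, nseg, by = 2)
        ex_s <- bounds[ex_idx]; ex_e <- bounds[ex_idx + 1]
        cds_s <- ex_s[1] + segs[1] %/% 2L
        cds_e <- ex_e[k] - segs[nseg] %/% 2L
        rows[[length(rows) + 1L]] <- list(
          chrom = names(sizes)[ci], s = starts[i], e = starts[i] + lens[i],
          strand = strands[i], cds_s = cds_s, cds_e = cds_e,
          ex_s = ex_s, ex_e = ex_e)
      }
    }
    genes <- as_granges0(
      vapply(rows, `[[`, character(1), "chrom"),
      vapply(rows, `[[`, numeric(1), "s"),
      vapply(rows, `[[`, numeric(1), "e"),
      strand = vapply(rows, `[[`, character(1), "strand"))
    mcols(genes)$gene_id <- sprintf("gene_%04d", seq_along(genes))
    mcols(genes)$cds_start0 <- vapply(rows, `[[`, numeric(1), "cds_s")
    mcols(genes)$cds_end0 <- vapply(rows, `[[`, numeric(1), "cds_e")
    mcols(genes)$exon_starts0 <- IRanges::IntegerList(
      lapply(rows, function(r) as.integer(r$ex_s)))
    mcols(genes)$exon_ends0 <- IRanges::IntegerList(
      lapply(rows, function(r) as.integer(r$ex_e)))
    list(sizes = sizes, genes = genes)
  })
}

# category -> cut-rate multipliers (mutant, control)
.category_mult <- function(category, E, delta) {
  switch(category,
         shared = c(E, E),
         mutant_only = c(E, 1),
         control_only = c(1, E),
         fold_changed = c(E * 2^delta, E))
}

.place_planted <- function(config, genome) {
  sizes <- genome$sizes
  cats <- rep(c("shared", "mutant_only", "control_only", "fold_changed"),
              c(config$n_shared, config$n_mutant_only,
                config$n_control_only, config$n_fold_changed))
  n <- length(cats)
  lens <- .rint(config$region_len_range[1], config$region_len_range[2], n)
  chroms <- character(n); starts <- integer(n)
  placed <- GenomicRanges::GRanges()
  # a fraction of fold_changed regions straddle a TSS
  fc_idx <- which(cats == "fold_changed")
  n_prom <- round(config$frac_fold_changed_at_promoters * length(fc_idx))
  prom_idx <- if (n_prom > 0) fc_idx[seq_len(n_prom)] else integer(0)
  prom_genes <- if (n_prom > 0)
    sample(seq_along(genome$genes), n_prom) else integer(0)
  for (j in seq_along(prom_idx)) {
    i <- prom_idx[j]
    g <- prom_genes[j]
    t0 <- tss0(genome$genes)[g]
    chroms[i] <- chrom_of(genome$genes)[g]
    starts[i] <- max(0L, t0 - lens[i] %/% 2L)
  }
  if (length(prom_idx))
    placed <- as_granges0(chroms[prom_idx], starts[prom_idx],
                          starts[prom_idx] + lens[prom_idx],
                          seqlengths = sizes)
  todo <- setdiff(seq_len(n), prom_idx)
  for (i in todo) {
    ok <- FALSE
    for (try in 1:200) {
      ch <- sample(names(sizes), 1, prob = as.numeric(sizes))
      s <- floor(stats::runif(1, 0, sizes[[ch]] - lens[i]))
      # keep planted regions clear of each other's 10-kb local-background
      # window so every region is an independent detection problem
      cand <- as_granges0(ch, max(0, s - 8000), min(sizes[[ch]],
                                                    s + lens[i] + 8000),
                          seqlengths = sizes)
      if (length(placed) == 0L ||
          length(overlapping_regions(cand, placed)) == 0L) {
        chroms[i] <- ch; starts[i] <- s; ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place planted regions", call. = FALSE)
    placed <- c(placed, as_granges0(chroms[i], starts[i],
                                    starts[i] + lens[i],
                                    seqlengths = sizes))
  }
  truth <- as_granges0(chroms, starts, starts + lens, seqlengths = sizes)
  mult <- t(vapply(cats, .category_mult, numeric(2), E = config$enrichment,
                   delta = config$delta))
  mcols(truth)$name <- sprintf("planted_%02d", seq_len(n))
  mcols(truth)$category <- cats
  mcols(truth)$mult_mut <- mult[, 1]
  mcols(truth)$mult_ctrl <- mult[, 2]
  mcols(truth)$delta <- log2(mult[, 1] / mult[, 2])
  truth
}

# Poisson cut sampling: homogeneous background at rate*depth plus planted
# elevations; returns stranded fragment GRanges
.sample_reads <- function(sizes, base_rate, depth, truth, mult_col,
                          fragment_len) {
  cuts <- integer(0); chs <- character(0)
  for (ch in names(sizes)) {
    L <- sizes[[ch]]
    nb <- stats::rpois(1, base_rate * depth * L)
    pos <- if (nb > 0) as.integer(floor(stats::runif(nb, 0, L))) else integer(0)
    cuts <- c(cuts, pos); chs <- c(chs, rep(ch, nb))
  }
  if (!is.null(truth) && length(truth) > 0) {
    mult <- mcols(truth)[[mult_col]]
    for (i in seq_along(truth)) {
      if (mult[i] <= 1) next
      len <- end0(truth)[i] - start0(truth)[i]
      ne <- stats::rpois(1, base_rate * depth * (mult[i] - 1) * len)
      if (ne > 0) {
        pos <- start0(truth)[i] +
          as.integer(floor(stats::runif(ne, 0, len)))
        cuts <- c(cuts, pos); chs <- c(chs, rep(chrom_of(truth)[i], ne))
      }
    }
  }
  n <- length(cuts)
  if (n == 0L) return(GenomicRanges::GRanges())
  str <- sample(c("+", "-"), n, replace = TRUE)
  L <- as.integer(sizes[chs])
  s0 <- ifelse(str == "+", cuts, pmax(0L, cuts + 1L - fragment_len))
  e0 <- ifelse(str == "+", pmin(L, cuts + fragment_len), cuts + 1L)
  as_granges0(chs, s0, e0, strand = str)
}

#' Simulate two-condition ATAC insertion data with planted truth
#'
#' Background cut sites follow a homogeneous Poisson process at
#' `background_rate * depth`; inside planted regions the rate is multiplied
#' per category (see [generator_config()]). Reads are emitted as stranded
#' fragments whose 5' end is the cut site.
#'
#' @param config a [generator_config()].
#' @param genome from [make_toy_genome()].
#' @return List with `mut`, `ctrl` (read `GRanges`) and `truth` (planted
#'   regions with category, rate multipliers and per-bin log2 effect).
#' @export
simulate_atac <- function(config, genome) {
  with_seed(config$seed + 1000L, {
    truth <- .place_planted(config, genome)
    mut <- .sample_reads(genome$sizes, config$background_rate,
                         config$depth_mutant, truth, "mult_mut",
                         config$fragment_len)
    ctrl <- .sample_reads(genome$sizes, config$background_rate,
                          config$depth_control, truth, "mult_ctrl",
                          config$fragment_len)
    list(mut = mut, ctrl = ctrl, truth = truth)
  })
}

#' Simulate ChIPmentation-style mark and TF reads
#'
#' Broad repressive-mark domains (multi-kb rate elevations) are planted
#' over a fraction of the fold_changed regions; TF point sources
#' (<= 300 bp) at a fraction of them. A matched input library (background
#' only, same depth) is emitted for background estimation.
#'
#' @param config a [generator_config()].
#' @param genome from [make_toy_genome()].
#' @param truth planted regions from [simulate_atac()].
#' @return List with `k27_reads`, `k27_input`, `tf_reads` (`GRanges`) and
#'   the planted `domains` and `tf_sites` (`GRanges`).
#' @export
simulate_chip <- function(config, genome, truth) {
  with_seed(config$seed + 2000L, {
    sizes <- genome$sizes
    fc <- truth[mcols(truth)$category == "fold_changed"]
    nd <- round(config$domain_fraction * length(fc))
    dom <- GenomicRanges::GRanges()
    if (nd > 0) {
      pick <- sort(sample(seq_along(fc), nd))
      dl <- .rint(config$domain_len_range[1], config$domain_len_range[2], nd)
      mid <- (start0(fc)[pick] + end0(fc)[pick]) %/% 2L
      ch <- chrom_of(fc)[pick]
      dom <- as_granges0(ch, pmax(0L, mid - dl %/% 2L),
                         pmin(as.integer(sizes[ch]), mid + dl %/% 2L))
      mcols(dom)$name <- sprintf("domain_truth_%02d", seq_len(nd))
      mcols(dom)$mult <- rep(config$chip_enrichment, nd)
    }
    nt <- round(config$tf_fraction * length(fc))
    tf_sites <- GenomicRanges::GRanges()
    if (nt > 0) {
      pick <- sort(sample(seq_along(fc), nt))
      mid <- (start0(fc)[pick] + end0(fc)[pick]) %/% 2L
      ch <- chrom_of(fc)[pick]
      half <- config$tf_peak_len %/% 2L
      tf_sites <- as_granges0(ch, pmax(0L, mid - half),
                              pmin(as.integer(sizes[ch]), mid + half))
      mcols(tf_sites)$name <- sprintf("tf_truth_%02d", seq_len(nt))
      mcols(tf_sites)$mult <- rep(config$tf_enrichment, nt)
    }
    k27 <- .sample_reads(sizes, config$background_rate, config$chip_depth,
                         dom, "mult", config$fragment_len)
    input <- .sample_reads(sizes, config$background_rate, config$chip_depth,
                           NULL, NULL, config$fragment_len)
    tf <- .sample_reads(sizes, config$background_rate, config$chip_depth,
                        tf_sites, "mult", config$fragment_len)
    list(k27_reads = k27, k27_input = input, tf_reads = tf,
         domains = dom, tf_sites = tf_sites)
  })
}

#' Build a matched DE table and gene signatures
#'
#' Genes whose transcript span lies within `gene_window` of a planted
#' mutant_only or fold_changed region are marked DE (up) with probability
#' `de_prob`; the table is padded with random genes of random direction to
#' `n_de` rows. A "multilineage"-style signature includes each DE gene with
#' probability `sig_overlap_fraction`, plus as many random non-DE genes.
#'
#' @param genome from [make_toy_genome()].
#' @param truth planted regions from [simulate_atac()].
#' @param config a [generator_config()].
#' @return List with `de` (data.frame gene_id/log2fc/padj/direction),
#'   `signatures` (named list), and `de_planted` (the planted DE-up gene
#'   ids near regions).
#' @export
make_de_table <- function(genome, truth, config) {
  with_seed(config$seed + 3000L, {
    genes <- genome$genes
    affected <- truth[mcols(truth)$category %in%
                        c("mutant_only", "fold_changed")]
    near <- unique(link_genes(affected, genes, config$gene_window)$gene_id)
    planted <- near[stats::runif(length(near)) < config$de_prob]
    all_ids <- mcols(genes)$gene_id
    pool <- setdiff(all_ids, planted)
    n_pad <- max(0L, min(config$n_de - length(planted), length(pool)))
    pad <- if (n_pad > 0) sample(pool, n_pad) else character(0)
    ids <- c(planted, pad)
    dir <- c(rep("up", length(planted)),
             sample(c("up", "down"), n_pad, replace = TRUE))
    lfc <- ifelse(dir == "up", 1, -1) * stats::runif(length(ids), 1, 4)
    de <- data.frame(gene_id = ids, log2fc = lfc,
                     padj = 10^stats::runif(length(ids), -8, -2),
                     direction = dir, stringsAsFactors = FALSE)
    in_sig <- de$gene_id[stats::runif(nrow(de)) <
                           config$sig_overlap_fraction]
    non_de <- setdiff(all_ids, de$gene_id)
    extra <- sample(non_de, min(length(in_sig), length(non_de)))
    sigs <- list(multilineage = sort(unique(c(in_sig, extra))))
    list(de = de, signatures = sigs, de_planted = planted)
  })
}

.place_blacklist <- function(config, genome, truth) {
  with_seed(config$seed + 4000L, {
    sizes <- genome$sizes
    out <- GenomicRanges::GRanges()
    avoid <- extend_clip(truth, 2000, sizes)
    for (i in seq_len(config$n_blacklist)) {
      for (try in 1:200) {
        ch <- sample(names(sizes), 1)
        s <- floor(stats::runif(1, 0, sizes[[ch]] - config$blacklist_len))
        cand <- as_granges0(ch, s, s + config$blacklist_len,
                            seqlengths = sizes)
        if (length(overlapping_regions(cand, avoid)) == 0L &&
            (length(out) == 0L ||
             length(overlapping_regions(cand, out)) == 0L)) {
          out <- c(out, cand); break
        }
      }
    }
    if (length(out)) mcols(out)$name <- sprintf("blacklist_%d",
                                                seq_along(out))
    out
  })
}

#' Generate the complete synthetic fixture in memory
#'
#' @param config a [generator_config()].
#' @return List with `genome`, `truth`, `reads` (mut/ctrl), `chip`,
#'   `de` tables/signatures and `blacklist`.
#' @export
simulate_fixture <- function(config) {
  genome <- make_toy_genome(config)
  atac <- simulate_atac(config, genome)
  chip <- simulate_chip(config, genome, atac$truth)
  det <- make_de_table(genome, atac$truth, config)
  bl <- .place_blacklist(config, genome, atac$truth)
  list(genome = genome, truth = atac$truth,
       reads = list(mut = atac$mut, ctrl = atac$ctrl),
       chip = chip, de = det, blacklist = bl)
}

#' Write the synthetic fixture to a directory
#'
#' Emits the full plain-text input set of the pipeline: reads, gene models,
#' chromosome sizes, blacklist, DE table, signatures and the planted truth.
#' Byte-identical across runs for a fixed config.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of file paths plus the in-memory
#'   fixture.
#' @export
write_fixture <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- simulate_fixture(config)
  p <- function(f) file.path(dir, f)
  write_intervals(fx$reads$mut, p("reads_mut.bed"), "BED")
  write_intervals(fx$reads$ctrl, p("reads_ctrl.bed"), "BED")
  write_intervals(fx$chip$k27_reads, p("k27_reads.bed"), "BED")
  write_intervals(fx$chip$k27_input, p("k27_input.bed"), "BED")
  write_intervals(fx$chip$tf_reads, p("nfyb_reads.bed"), "BED")
  write_gene_models(fx$genome$genes, p("genes.bed12"))
  write_chrom_sizes(fx$genome$sizes, p("genome.chrom.sizes"))
  write_intervals(fx$blacklist, p("blacklist.bed"), "BED")
  truth_df <- data.frame(chrom = chrom_of(fx$truth),
                         start0 = start0(fx$truth), end0 = end0(fx$truth),
                         name = mcols(fx$truth)$name,
                         category = mcols(fx$truth)$category,
                         delta = mcols(fx$truth)$delta,
                         mult_mut = mcols(fx$truth)$mult_mut,
                         mult_ctrl = mcols(fx$truth)$mult_ctrl)
  utils::write.table(truth_df, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fx$de$de, p("de_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(fx$de$signatures, p("signatures.gmt"))
  files <- list(reads_mut = p("reads_mut.bed"),
                reads_ctrl = p("reads_ctrl.bed"),
                k27_reads = p("k27_reads.bed"),
                k27_input = p("k27_input.bed"),
                tf_reads = p("nfyb_reads.bed"),
                genes = p("genes.bed12"),
                chrom_sizes = p("genome.chrom.sizes"),
                blacklist = p("blacklist.bed"),
                truth = p("truth.tsv"),
                de_table = p("de_table.tsv"),
                signatures = p("signatures.gmt"))
  invisible(c(files, list(fixture = fx)))
}
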