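suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# random interval set on one chromosome, 0-based half-open, coords < max_coord
rand_set <- function(n, max_coord = 1e5, max_len = 500, chrom = "chr1") {
  s <- floor(runif(n, 0, max_coord - max_len))
  len <- ceiling(runif(n, 1, max_len))
  as_granges0(rep(chrom, n), s, pmin(max_coord, s + len))
}

# per-base boolean coverage of a set (positions 1..max_coord = bases 0..max-1)
base_mask <- function(gr, max_coord = 1e5) {
  m <- logical(max_coord)
  s <- start0(gr); e <- end0(gr)
  for (i in seq_along(gr)) m[(s[i] + 1):e[i]] <- TRUE
  m
}

# oracle: which intervals of a overlap >= 1 covered base of b
oracle_hits <- function(a, b, max_coord = 1e5) {
  mb <- base_mask(b, max_coord)
  vapply(seq_along(a), function(i)
    any(mb[(start0(a)[i] + 1):end0(a)[i]]), logical(1))
}

# oracle flatten: maximal runs of covered bases as a 2-col matrix (start0, end0)
oracle_flatten <- function(gr, max_coord = 1e5) {
  m <- base_mask(gr, max_coord)
  r <- rle(m)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  cbind(s[r$values], e[r$values])
}

# brute-force any-overlap bin sum (the bedtools map -o sum convention)
oracle_bin_sum <- function(values, binsize, s0, e0) {
  bs <- (seq_along(values) - 1) * binsize
  be <- bs + binsize
  sum(values[bs < e0 & be > s0])
}

# exact hypergeometric upper tail by enumeration
oracle_hyper_tail <- function(k, n_b, U, n_a) {
  sum(vapply(k:min(n_a, n_b), function(j)
    choose(n_b, j) * choose(U - n_b, n_a - j) / choose(U, n_a), numeric(1)))
}

# small deterministic gene model set built in code (no files)
toy_genes <- function() {
  g <- as_granges0(c("chr1", "chr1"), c(1000, 6000), c(3000, 8000),
                   strand = c("+", "-"))
  mcols(g)$gene_id <- c("gA", "gB")
  mcols(g)$cds_start0 <- c(1200, 6300)
  mcols(g)$cds_end0 <- c(2800, 7700)
  mcols(g)$exon_starts0 <- IRanges::IntegerList(list(c(1000L, 2000L),
                                                     c(6000L, 7000L)))
  mcols(g)$exon_ends0 <- IRanges::IntegerList(list(c(1500L, 3000L),
                                                   c(6500L, 8000L)))
  g
}

# small constant-backbone track built directly from bin values
toy_track <- function(values, binsize = 50, chrom = "chr1",
                      kind = "raw") {
  len <- length(values) * binsize
  coverage_track(stats::setNames(list(values), chrom), binsize,
                 stats::setNames(as.integer(len), chrom), kind = kind)
}

# tiny generator configuration for fast pipeline-level tests
small_config <- function(seed, ...) {
  defaults <- list(seed = seed, chrom_lengths = c(chr1 = 5e5),
                   n_genes = 40, n_shared = 5, n_mutant_only = 5,
                   n_fold_changed = 5, n_de = 20)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

write_small_fixture <- function(seed, dir = tempfile("fx"), ...) {
  write_fixture(small_config(seed, ...), dir)
}

manifest_of <- function(fx) {
  fx[c("reads_mut", "reads_ctrl", "chrom_sizes", "genes", "blacklist",
       "k27_reads", "k27_input", "tf_reads", "de_table", "signatures")]
}
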