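test_that("insertion pileup covers a shifted/extended window around each cut", {
  sizes <- c(chr1 = 10000L)
  # + read cut at 1000: window [900, 1100)
  r <- as_granges0("chr1", 1000, 1100, strand = "+")
  tr <- insertion_pileup(r, sizes, shift = -100, extsize = 200, binsize = 50)
  v <- tr$values$chr1
  expect_equal(which(v > 0), 19:22)            # bins covering [900, 1100)
  expect_equal(sum(v) * 50, 200)

  # - read: cut at end - 1
  rm <- as_granges0("chr1", 900, 1001, strand = "-")
  trm <- insertion_pileup(rm, sizes, -100, 200, 50)
  expect_equal(which(trm$values$chr1 > 0), 19:22)

  # left clipping at the chromosome start
  r2 <- as_granges0("chr1", 50, 150, strand = "+")
  tr2 <- insertion_pileup(r2, sizes, -100, 200, 50)
  expect_equal(sum(tr2$values$chr1) * 50, 150)
  expect_equal(which(tr2$values$chr1 > 0), 1:3)

  # 10 identical cuts: conservation of added mass
  r3 <- rep(as_granges0("chr1", 5000, 5100, strand = "+"), 10)
  tr3 <- insertion_pileup(r3, sizes, -100, 200, 50)
  expect_equal(sum(tr3$values$chr1), 10 * 200 / 50)

  expect_error(insertion_pileup(as_granges0("chr1", 10000, 10001,
                                            strand = "+"), sizes),
               "beyond")
})

test_that("pileup mass conservation holds exactly for random reads", {
  withr::with_seed(41, {
    sizes <- c(chr1 = 20000L)
    cuts <- sample.int(20000, 300) - 1L
    reads <- as_granges0("chr1", cuts, pmin(20000, cuts + 80), strand = "+")
    tr <- insertion_pileup(reads, sizes, -100, 200, 50)
    clipped <- sum(pmax(0, 100 - cuts)) + sum(pmax(0, (cuts + 100) - 20000))
    expect_equal(sum(tr$values$chr1) * 50, 300 * 200 - clipped)
  })
})

test_that("Poisson tail probabilities match direct series summation", {
  # single-bin spike on a flat background, window spanning the chromosome
  v <- rep(3, 200); v[100] <- 12
  tr <- toy_track(v, binsize = 50)
  pv <- poisson_bin_pvalues(tr, local_window = 200 * 50)
  lam <- mean(v)
  series <- sum(dpois(12:300, lam))
  expect_equal(pv$pvalues$chr1[100], series, tolerance = 1e-12)
  expect_equal(pv$lambda$chr1[100], lam, tolerance = 1e-12)

  # k = 0 bins have p = 1; uniform track gives identical p everywhere
  v0 <- rep(2, 100); v0[7] <- 0
  pv0 <- poisson_bin_pvalues(toy_track(v0), local_window = 5000)
  expect_equal(pv0$pvalues$chr1[7], 1)
  pu <- poisson_bin_pvalues(toy_track(rep(4, 100)), local_window = 5000)
  expect_equal(length(unique(pu$pvalues$chr1)), 1L)

  # zero-signal track: all p = 1
  pz <- poisson_bin_pvalues(toy_track(rep(0, 50)))
  expect_true(all(pz$pvalues$chr1 == 1))
})

test_that("BH adjustment reproduces hand-computed q-values", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_qvalues(0.05), 0.05)
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(bh_qvalues(numeric(0)), numeric(0))
  # order preserved
  p <- c(0.04, 0.001, 0.2)
  expect_equal(order(bh_qvalues(p)), order(p))
})

test_that("a planted cut cluster yields exactly one peak over the planted interval", {
  withr::with_seed(7, {
    L <- 1e6; sizes <- c(chr1 = L)
    n <- rpois(1, 0.005 * L)
    cuts <- c(floor(runif(n, 0, L)), floor(runif(400, 400000, 400200)))
    reads <- as_granges0("chr1", cuts, pmin(L, cuts + 100), strand = "+")
    tr <- insertion_pileup(reads, sizes)
    # null calibration on the background portion
    null_reads <- reads[seq_len(n)]
    pnull <- poisson_bin_pvalues(insertion_pileup(null_reads, sizes))
    expect_lt(mean(pnull$pvalues$chr1 < 0.01), 0.015)

    peaks <- call_narrow_peaks(tr)
    planted <- as_granges0("chr1", 400000, 400200)
    expect_equal(length(overlapping_regions(peaks, planted)), 1L)
    hit <- overlapping_regions(peaks, planted)
    expect_lte(mcols(hit)$qvalue, 0.05)
    expect_true(mcols(hit)$summit0 >= start0(hit) &&
                  mcols(hit)$summit0 < end0(hit))
    expect_gt(mcols(hit)$fold_enrichment, 5)
  })
})

test_that("empty input produces no peaks", {
  tr <- toy_track(rep(0, 100))
  expect_equal(length(call_narrow_peaks(tr)), 0L)
})

test_that("peak calling is invariant to chromosome order", {
  withr::with_seed(42, {
    fx <- simulate_fixture(small_config(3, chrom_lengths = c(chr1 = 2e5,
                                                             chr2 = 2e5)))
    szs <- fx$genome$sizes
    p1 <- call_narrow_peaks(insertion_pileup(fx$reads$mut, szs))
    p2 <- call_narrow_peaks(insertion_pileup(fx$reads$mut, rev(szs)))
    key <- function(p) paste(as.character(seqnames(p)), start0(p), end0(p))
    expect_setequal(key(p1), key(p2))
  })
})

test_that("broad domains need a strong core and link across small gaps", {
  # strong cores 40 bins apart on a flat background; a weak-only bump
  v <- rep(1, 2000)
  v[500:509] <- 25            # strong run A
  v[516:525] <- 25            # strong run B, 6-bin gap from A
  v[1000:1019] <- 4.2         # moderate elevation, no strong core
  tr <- toy_track(v, binsize = 50)
  ctrl <- toy_track(rep(1, 2000), binsize = 50)

  doms_nolink <- call_broad_domains(tr, control = ctrl, link_gap = 0,
                                    local_window = 1e5)
  doms_linked <- call_broad_domains(tr, control = ctrl, link_gap = 6 * 50,
                                    local_window = 1e5)
  strongA <- as_granges0("chr1", 499 * 50, 510 * 50)
  strongB <- as_granges0("chr1", 515 * 50, 526 * 50)
  weak <- as_granges0("chr1", 999 * 50, 1020 * 50)
  expect_equal(length(overlapping_regions(doms_nolink, strongA)), 1L)
  expect_equal(length(overlapping_regions(doms_nolink, strongB)), 1L)
  # the two strong runs are separate without linking, joined with it
  n_over_nolink <- length(overlapping_regions(
    doms_nolink, merge_intervals(c(strongA, strongB), max_gap = 1e4)))
  n_over_link <- length(overlapping_regions(
    doms_linked, merge_intervals(c(strongA, strongB), max_gap = 1e4)))
  expect_equal(n_over_nolink, 2L)
  expect_equal(n_over_link, 1L)
  # moderate-only elevation never becomes a domain
  expect_equal(length(overlapping_regions(doms_linked, weak)), 0L)
  expect_equal(length(overlapping_regions(doms_nolink, weak)), 0L)
})

test_that("the broad cutoff extends domains through weak flanking bins", {
  # core at 25, flanks at a level significant at 0.1 but not at the strong
  # cutoff; compare domain width with and without the weak tier
  v <- rep(1, 4000)
  v[2000:2009] <- 25
  v[1995:1999] <- 7
  v[2010:2014] <- 7
  tr <- toy_track(v, binsize = 50)
  ctrl <- toy_track(rep(1, 4000), binsize = 50)
  wide <- call_broad_domains(tr, control = ctrl, qcut = 1e-6,
                             broad_cutoff = 0.1, link_gap = 0,
                             local_window = 2e5)
  narrow <- call_broad_domains(tr, control = ctrl, qcut = 1e-6,
                               broad_cutoff = 1e-6, link_gap = 0,
                               local_window = 2e5)
  expect_equal(length(wide), 1L)
  expect_equal(length(narrow), 1L)
  expect_gt(BiocGenerics::width(wide), BiocGenerics::width(narrow))
  # the weak flanks are inside the broad domain
  expect_lte(start0(wide), (1995 - 1) * 50)
  expect_gte(end0(wide), 2014 * 50)
})

test_that("replicate aggregation concatenates and conserves pileup mass", {
  a <- as_granges0("chr1", 1:10 * 100, 1:10 * 100 + 50, strand = "+")
  b <- as_granges0("chr1", 1:15 * 200, 1:15 * 200 + 50, strand = "+")
  pooled <- aggregate_replicates(list(a, b))
  expect_equal(length(pooled), 25L)
  expect_identical(aggregate_replicates(list(a)), a)

  sizes <- c(chr1 = 10000L)
  pa <- insertion_pileup(a, sizes); pb <- insertion_pileup(b, sizes)
  pp <- insertion_pileup(pooled, sizes)
  expect_equal(pp$values$chr1, pa$values$chr1 + pb$values$chr1,
               tolerance = 1e-12)
})
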