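test_that("feature classification applies the priority rule", {
  g <- toy_genes()
  # straddles the TSS of gA (TSS = 1000)
  expect_equal(as.character(classify_regions(
    as_granges0("chr1", 950, 1050), g, 1000)), "promoter")
  # overlaps promoter of gA and the body of gB: promoter wins
  expect_equal(as.character(classify_regions(
    as_granges0("chr1", 1900, 6200), g, 1000)), "promoter")
  # far from every gene
  expect_equal(as.character(classify_regions(
    as_granges0("chr1", 30000, 30100), g, 1000)), "distal_intergenic")
  # inside the intron of gA (exons end 1500 / start 2000), promoter window
  # small enough not to reach
  expect_equal(as.character(classify_regions(
    as_granges0("chr1", 1600, 1700), g, 100)), "intron")
  # 5' UTR of gA: exonic part before cdsStart 1200
  expect_equal(as.character(classify_regions(
    as_granges0("chr1", 1100, 1150), g, 50)), "utr5")
  # 3' UTR of gA: exonic part after cdsEnd 2800
  expect_equal(as.character(classify_regions(
    as_granges0("chr1", 2850, 2900), g, 50)), "utr3")
})

test_that("feature distribution proportions sum to one and match a per-base oracle", {
  sizes <- c(chr1 = 10000L)
  pw <- 100L
  g <- as_granges0("chr1", 2000, 3000, strand = "+")
  mcols(g)$gene_id <- "g1"
  mcols(g)$cds_start0 <- 2200L
  mcols(g)$cds_end0 <- 2800L
  mcols(g)$exon_starts0 <- IRanges::IntegerList(list(c(2000L, 2600L)))
  mcols(g)$exon_ends0 <- IRanges::IntegerList(list(c(2400L, 3000L)))

  regions <- as_granges0("chr1", c(1950, 5000, 2450), c(2050, 5100, 2550))
  dist <- genomic_distribution(regions, g, sizes, pw)
  expect_equal(sum(dist$region_prop), 1, tolerance = 1e-9)
  expect_equal(sum(dist$genome_prop), 1, tolerance = 1e-9)

  # per-base oracle classification of the whole toy chromosome
  base_cls <- rep("distal_intergenic", 10000)
  in_span <- function(i0, s, e) i0 >= s & i0 < e
  i0 <- 0:9999
  exon1 <- in_span(i0, 2000, 2400); exon2 <- in_span(i0, 2600, 3000)
  exonic <- exon1 | exon2
  base_cls[in_span(i0, 2000, 3000) & !exonic] <- "intron"
  base_cls[exonic] <- "exon"
  base_cls[exonic & in_span(i0, 2000, 2200)] <- "utr5"   # before cdsStart, + strand
  base_cls[exonic & in_span(i0, 2800, 3000)] <- "utr3"
  base_cls[in_span(i0, 2000 - pw, 2000 + pw)] <- "promoter"
  oracle <- table(factor(base_cls, levels = levels(dist$class))) / 10000
  expect_equal(dist$genome_prop, as.numeric(oracle), tolerance = 1e-9)

  expect_error(genomic_distribution(GRanges(), g, sizes, pw), "empty")
})

test_that("regions at TSSs are all classified as promoter", {
  g <- toy_genes()
  at_tss <- as_granges0("chr1", tss0(g), tss0(g) + 10)
  d <- genomic_distribution(at_tss, g, c(chr1 = 50000L), 1000)
  expect_equal(d$region_prop[d$class == "promoter"], 1)
})

test_that("gene linking respects the window boundary exactly", {
  g <- toy_genes()   # gA spans [1000, 3000)
  # region 5 kb upstream of gA with w = 10 kb: linked
  r <- as_granges0("chr1", 0, 500)
  expect_true("gA" %in% link_genes(r, g, 10000)$gene_id)
  # gap of exactly w: not linked; gap w - 1: linked
  r2 <- as_granges0("chr1", 13000, 13500)   # gap to gA end = 10000
  expect_false("gA" %in% link_genes(r2, g, 10000)$gene_id)
  r3 <- as_granges0("chr1", 12999, 13500)
  expect_true("gA" %in% link_genes(r3, g, 10000)$gene_id)
  # inside a gene with w = 0: linked, distance 0
  r4 <- as_granges0("chr1", 1500, 1600)
  l4 <- link_genes(r4, g, 0)
  expect_equal(l4$gene_id, "gA")
  expect_equal(l4$distance, 0L)
})

test_that("region-extension linking equals gene-extension linking", {
  withr::with_seed(61, {
    sizes <- c(chr1 = 1e5)
    for (i in 1:20) {
      regions <- rand_set(15, max_coord = 9e4)
      genes <- rand_set(10, max_coord = 9e4, max_len = 3000)
      w <- sample(c(0, 100, 5000), 1)
      g <- genes; mcols(g)$gene_id <- sprintf("g%d", seq_along(g))
      via_regions <- link_genes(regions, g, w)
      ext_genes <- extend_clip(g, w, sizes)
      hits <- findOverlaps(regions, ext_genes, ignore.strand = TRUE)
      expect_equal(sort(paste(via_regions$region_idx, via_regions$gene_id)),
                   sort(paste(queryHits(hits),
                              mcols(g)$gene_id[subjectHits(hits)])))
    }
  })
})

test_that("DE co-location returns the planted region-gene pairs", {
  g <- toy_genes()
  scored <- as_granges0("chr1", c(500, 4000, 20000), c(700, 4200, 20200))
  mcols(scored)$log2_sum_score <- c(20, 17, 16)
  de <- data.frame(gene_id = c("gA", "gZ"), log2fc = c(2, -1),
                   padj = c(0.001, 0.01), direction = c("up", "down"))
  expect_warning(res <- colocate_de(scored, de, g, 10000), "gZ")
  expect_equal(length(res$regions), 2L)       # both near gA within 10 kb
  expect_true(all(res$table$gene_id == "gA"))
  expect_true(all(res$table$direction == "up"))

  de_none <- data.frame(gene_id = "gB", log2fc = 1, padj = 0.01,
                        direction = "up")
  far <- as_granges0("chr1", 40000, 40100)
  mcols(far)$log2_sum_score <- 20
  expect_equal(length(colocate_de(far, de_none, g, 10000)$regions), 0L)
})

test_that("mark co-location reports per-region overlap base counts", {
  regions <- as_granges0("chr1", c(100, 1000, 5000), c(200, 1200, 5100))
  domains <- as_granges0("chr1", c(0, 1100), c(500, 1150))
  res <- colocate_marks(regions, domains)
  expect_equal(length(res), 2L)
  expect_equal(mcols(res)$overlap_bp, c(100L, 50L))  # full containment, partial
  expect_equal(length(colocate_marks(regions, GRanges())), 0L)

  withr::with_seed(62, {
    a <- rand_set(30); b <- rand_set(30)
    res <- colocate_marks(a, b)
    expect_equal(length(res), sum(oracle_hits(a, b)))
  })
})

test_that("signature overlap gives exact hypergeometric tail probabilities", {
  U <- sprintf("g%03d", 1:100)
  a <- U[1:10]; b <- U[8:12]          # overlap = 3
  res <- signature_overlap(a, b, U)
  expect_equal(res$n_overlap, 3L)
  expect_equal(res$p_value, oracle_hyper_tail(3, 5, 100, 10),
               tolerance = 1e-12)

  res2 <- signature_overlap(a, a, U)
  expect_equal(res2$n_overlap, 10L)
  expect_equal(res2$fraction_of_a, 1)

  res3 <- signature_overlap(U[1:10], U[11:15], U)
  expect_equal(res3$n_overlap, 0L)
  expect_equal(res3$p_value, 1, tolerance = 1e-12)

  expect_error(signature_overlap(c(a, "outsider"), b, U), "outsider")
})

test_that("gene-set enrichment computes odds ratios and sorted exact p-values", {
  U <- sprintf("g%03d", 1:100)
  query <- U[1:10]
  lib <- list(hit = c(U[1:3], U[50:51]),     # 3 in query, 2 outside
              miss = U[60:64],
              all_query = query)
  res <- geneset_enrichment(query, lib, U)
  expect_equal(res$set[1], "all_query")
  row <- res[res$set == "hit", ]
  expect_equal(row$n_overlap, 3L)
  expect_equal(row$odds_ratio, (3 * 88) / (7 * 2))
  expect_equal(row$p_value, oracle_hyper_tail(3, 5, 100, 10),
               tolerance = 1e-12)
  expect_equal(res[res$set == "miss", ]$odds_ratio, 0)
  expect_equal(res$q_value, bh_qvalues(res$p_value))
  expect_error(geneset_enrichment(character(0), lib, U), "empty")
})

test_that("coverage matrices average the track over the requested windows", {
  z <- toy_track(rep(0, 100), kind = "log2_ratio")
  regions <- as_granges0("chr1", c(1000, 3000), c(1200, 3400))
  m0 <- coverage_matrix(z, regions, "center", flank = 400, nbins = 8)
  expect_true(all(m0$matrix == 0))

  cst <- toy_track(rep(3.5, 100), kind = "log2_ratio")
  m1 <- coverage_matrix(cst, regions, "scale", nbins = 10)
  expect_true(all(abs(m1$matrix - 3.5) < 1e-9))

  # single cell equals a brute-force per-base mean
  vals <- round(runif(100, 0, 4), 3)
  tr <- toy_track(vals, binsize = 50)
  reg <- as_granges0("chr1", 1000, 1100)   # midpoint 1050
  m2 <- coverage_matrix(tr, reg, "center", flank = 200, nbins = 1)
  base_vals <- rep(vals, each = 50)
  expect_equal(unname(m2$matrix[1, 1]), mean(base_vals[851:1250]),
               tolerance = 1e-9)

  # row means invariant to bin refinement on a piecewise-constant track
  m4 <- coverage_matrix(tr, reg, "center", flank = 200, nbins = 4)
  m8 <- coverage_matrix(tr, reg, "center", flank = 200, nbins = 8)
  expect_equal(mean(m4$matrix[1, ]), mean(m8$matrix[1, ]), tolerance = 1e-9)

  # rows ordered by descending score
  mcols(regions)$log2_sum_score <- c(1, 99)
  mo <- coverage_matrix(tr, regions, "center", flank = 100, nbins = 2)
  expect_equal(start0(mo$regions), c(3000L, 1000L))

  # windows beyond the chromosome edge contribute zeros, not errors
  edge <- as_granges0("chr1", 0, 50)
  me <- coverage_matrix(tr, edge, "center", flank = 400, nbins = 4)
  expect_equal(unname(me$matrix[1, 1]), 0)
})
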