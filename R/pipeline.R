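.require_fields <- function(manifest, fields) {
  for (f in fields) {
    if (is.null(manifest[[f]]))
      stop("manifest is missing mandatory field '", f, "'", call. = FALSE)
    for (p in manifest[[f]])
      if (!file.exists(p)) stop("input file for '", f, "' not found: ", p,
                                call. = FALSE)
  }
}

.read_condition <- function(paths, blacklist, excluded, label) {
  sets <- lapply(paths, read_intervals)
  reads <- aggregate_replicates(sets)
  filt <- filter_excluded(reads, blacklist, excluded)
  message(sprintf("[%s] %d reads, %d removed (%d excluded chrom, %d blacklist)",
                  label, length(reads), filt$n_removed,
                  filt$n_excluded_chrom, filt$n_blacklist))
  filt$intervals
}

#' Run the full differential-accessibility pipeline
#'
#' Executes every stage in order: read filtering, replicate aggregation,
#' insertion pileup, narrow peak calling in both conditions, overlap
#' statistics, condition-exclusive regions, depth normalization, the
#' genome-wide log2-ratio track, per-region log2-sum scores, threshold
#' selection, genomic feature distributions, gene linking, optional DE /
#' repressive-mark / TF co-location, signature overlap and gene-set
#' enrichment, and heat-map coverage matrices. Deterministic: identical
#' inputs and config give byte-identical outputs.
#'
#' @param manifest named list of input paths. Mandatory: `reads_mut`,
#'   `reads_ctrl` (character vectors of replicate BED files),
#'   `chrom_sizes`, `genes`. Optional: `blacklist`, `k27_reads`,
#'   `k27_input`, `tf_reads`, `de_table`, `signatures`.
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, all tables, tracks, peak
#'   files, matrices, `report.json` and a `manifest.json` index are
#'   written there.
#' @return An `analysis_report` list of headline counts, tables and (when
#'   `outdir` is set) exported file paths.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         outdir = NULL) {
  .require_fields(manifest, c("reads_mut", "reads_ctrl", "chrom_sizes",
                              "genes"))
  sizes <- read_chrom_sizes(manifest$chrom_sizes)
  genes <- read_gene_models(manifest$genes)
  blacklist <- if (!is.null(manifest$blacklist))
    read_intervals(manifest$blacklist) else NULL
  eff_len <- sum(as.numeric(sizes[!names(sizes) %in%
                                    config$excluded_chroms])) -
    if (!is.null(blacklist))
      sum(BiocGenerics::width(merge_intervals(blacklist))) else 0

  mut_reads <- .read_condition(manifest$reads_mut, blacklist,
                               config$excluded_chroms, "mutant")
  ctrl_reads <- .read_condition(manifest$reads_ctrl, blacklist,
                                config$excluded_chroms, "control")

  pile_mut <- insertion_pileup(mut_reads, sizes, config$shift,
                               config$extsize, config$binsize)
  pile_ctrl <- insertion_pileup(ctrl_reads, sizes, config$shift,
                                config$extsize, config$binsize)

  peaks_mut <- call_narrow_peaks(pile_mut, qcut = config$qcut,
                                 local_window = config$local_window,
                                 effective_len = eff_len,
                                 blacklist = blacklist)
  peaks_ctrl <- call_narrow_peaks(pile_ctrl, qcut = config$qcut,
                                  local_window = config$local_window,
                                  effective_len = eff_len,
                                  blacklist = blacklist)
  message(sprintf("[peaks] mutant %d, control %d",
                  length(peaks_mut), length(peaks_ctrl)))

  ostats <- overlap_stats(peaks_mut, peaks_ctrl)
  excl <- mutant_exclusive_regions(peaks_mut, peaks_ctrl)

  norm <- depth_normalize(pile_mut, pile_ctrl)
  ratio <- log2_ratio_track(norm$a, norm$b, config$pseudocount)
  scored <- region_sum_scores(ratio, peaks_mut)
  more_acc <- select_more_accessible(scored, config$score_threshold)
  message(sprintf("[score] %d/%d regions at log2 sum score >= %g",
                  length(more_acc), length(scored), config$score_threshold))

  dist_all <- if (length(scored) > 0)
    genomic_distribution(scored, genes, sizes, config$promoter_window)
  else NULL
  dist_more <- if (length(more_acc) > 0)
    genomic_distribution(more_acc, genes, sizes, config$promoter_window)
  else NULL
  links <- link_genes(more_acc, genes, config$gene_window)

  de <- NULL; de_coloc <- NULL
  if (!is.null(manifest$de_table)) {
    de <- read_de_table(manifest$de_table)
    de_coloc <- colocate_de(more_acc, de, genes, config$gene_window)
    message(sprintf("[DE] %d regions co-located with a DE gene",
                    length(de_coloc$regions)))
  }

  domains <- NULL; k27_coloc <- NULL; dist_k27 <- NULL
  k27_track <- NULL
  if (!is.null(manifest$k27_reads)) {
    k27_reads <- .read_condition(manifest$k27_reads, blacklist,
                                 config$excluded_chroms, "k27")
    k27_track <- insertion_pileup(k27_reads, sizes, config$shift,
                                  config$extsize, config$binsize)
    k27_input <- if (!is.null(manifest$k27_input))
      insertion_pileup(.read_condition(manifest$k27_input, blacklist,
                                       config$excluded_chroms, "k27 input"),
                       sizes, config$shift, config$extsize, config$binsize)
    else NULL
    domains <- call_broad_domains(k27_track, control = k27_input,
                                  qcut = config$qcut,
                                  broad_cutoff = config$broad_cutoff,
                                  link_gap = config$link_gap,
                                  local_window = config$local_window,
                                  effective_len = eff_len,
                                  blacklist = blacklist)
    k27_coloc <- colocate_marks(more_acc, domains)
    if (length(k27_coloc) > 0)
      dist_k27 <- genomic_distribution(k27_coloc, genes, sizes,
                                       config$promoter_window)
    message(sprintf("[k27] %d broad domains, %d co-located regions",
                    length(domains), length(k27_coloc)))
  }

  tf_peaks <- NULL; tf_coloc <- NULL; tf_track <- NULL
  if (!is.null(manifest$tf_reads)) {
    tf_reads <- .read_condition(manifest$tf_reads, blacklist,
                                config$excluded_chroms, "tf")
    tf_track <- insertion_pileup(tf_reads, sizes, config$shift,
                                 config$extsize, config$binsize)
    tf_peaks <- call_narrow_peaks(tf_track, qcut = config$qcut,
                                  local_window = config$local_window,
                                  effective_len = eff_len,
                                  blacklist = blacklist)
    tf_coloc <- colocate_marks(more_acc, tf_peaks)
    message(sprintf("[tf] %d peaks, %d co-located regions",
                    length(tf_peaks), length(tf_coloc)))
  }

  universe <- unique(mcols(genes)$gene_id)
  sig_overlap <- NULL; enrichment <- NULL
  if (!is.null(manifest$signatures)) {
    sigs <- read_gmt(manifest$signatures)
    if (!is.null(de)) {
      de_in_univ <- intersect(de$gene_id, universe)
      sig_overlap <- lapply(sigs, function(s)
        signature_overlap(de_in_univ, intersect(s, universe), universe))
    }
    linked_genes <- unique(links$gene_id)
    if (length(linked_genes) > 0)
      enrichment <- geneset_enrichment(linked_genes, sigs, universe)
  }

  mat_access <- if (length(more_acc) > 0)
    coverage_matrix(ratio, more_acc, mode = "center", flank = 2000,
                    nbins = 40) else NULL
  mat_k27 <- if (!is.null(k27_track) && length(more_acc) > 0)
    coverage_matrix(k27_track, more_acc, mode = "center", flank = 2000,
                    nbins = 40) else NULL
  mat_tf <- if (!is.null(tf_track) && length(more_acc) > 0)
    coverage_matrix(tf_track, more_acc, mode = "center", flank = 2000,
                    nbins = 40) else NULL

  report <- list(
    config = unclass(config),
    n_reads_mutant = length(mut_reads),
    n_reads_control = length(ctrl_reads),
    n_peaks_mutant = length(peaks_mut),
    n_peaks_control = length(peaks_ctrl),
    pct_mutant_in_control = ostats$pct_a_in_b,
    pct_control_in_mutant = ostats$pct_b_in_a,
    jaccard_bp = ostats$jaccard_bp,
    n_mutant_exclusive = length(excl),
    n_scored_regions = length(scored),
    n_more_accessible = length(more_acc),
    n_de_colocated_regions = if (!is.null(de_coloc))
      length(de_coloc$regions) else NA_integer_,
    n_k27_colocated = if (!is.null(k27_coloc)) length(k27_coloc)
    else NA_integer_,
    n_tf_colocated = if (!is.null(tf_coloc)) length(tf_coloc)
    else NA_integer_,
    signature_overlap = sig_overlap,
    distribution_all = dist_all,
    distribution_more_accessible = dist_more,
    distribution_k27_colocated = dist_k27,
    enrichment = enrichment)
  objects <- list(peaks_mut = peaks_mut, peaks_ctrl = peaks_ctrl,
                  exclusive = excl, scored = scored, more_acc = more_acc,
                  ratio = ratio, links = links, de_coloc = de_coloc,
                  domains = domains, k27_coloc = k27_coloc,
                  tf_peaks = tf_peaks, tf_coloc = tf_coloc,
                  matrices = list(accessibility = mat_access,
                                  k27 = mat_k27, tf = mat_tf))
  report$objects <- objects
  class(report) <- "analysis_report"
  stopifnot(report$n_more_accessible <= report$n_scored_regions,
            report$n_mutant_exclusive <= report$n_peaks_mutant)
  if (!is.null(outdir)) report <- .export_report(report, outdir)
  report
}

.scored_to_bed <- function(gr) {
  out <- gr
  mcols(out) <- NULL
  mcols(out)$name <- mcols(gr)$name %||% sprintf("region_%d", seq_along(gr))
  mcols(out)$score <- mcols(gr)$log2_sum_score
  out
}

.write_matrix <- function(mat, path) {
  df <- data.frame(region = paste0(chrom_of(mat$regions), ":",
                                   start0(mat$regions), "-",
                                   end0(mat$regions)),
                   mat$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.export_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  ob <- report$objects
  files <- character(0)
  wf <- function(fun, obj, f, ...) {
    if (is.null(obj)) return(invisible(NULL))
    fun(obj, p(f), ...)
    files[[length(files) + 1L]] <<- f
  }
  wf(write_intervals, ob$peaks_mut, "peaks_mutant.narrowPeak", "narrowPeak")
  wf(write_intervals, ob$peaks_ctrl, "peaks_control.narrowPeak",
     "narrowPeak")
  wf(write_intervals, ob$exclusive, "mutant_exclusive.narrowPeak",
     "narrowPeak")
  wf(write_intervals, .scored_to_bed(ob$scored), "scored_regions.bed", "BED")
  wf(write_intervals, .scored_to_bed(ob$more_acc), "more_accessible.bed",
     "BED")
  wf(write_track, ob$ratio, "log2_ratio.bedGraph")
  if (!is.null(ob$domains))
    wf(write_intervals, ob$domains, "k27_domains.broadPeak", "broadPeak")
  if (!is.null(ob$tf_peaks))
    wf(write_intervals, ob$tf_peaks, "tf_peaks.narrowPeak", "narrowPeak")
  tw <- function(df, f) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[length(files) + 1L]] <<- f
  }
  tw(report$distribution_all, "distribution_all_regions.tsv")
  tw(report$distribution_more_accessible,
     "distribution_more_accessible.tsv")
  tw(report$distribution_k27_colocated, "distribution_k27_colocated.tsv")
  tw(ob$links, "gene_links.tsv")
  if (!is.null(ob$de_coloc)) tw(ob$de_coloc$table, "de_colocated.tsv")
  tw(report$enrichment, "enrichment.tsv")
  for (nm in names(ob$matrices)) {
    if (is.null(ob$matrices[[nm]])) next
    .write_matrix(ob$matrices[[nm]], p(paste0("matrix_", nm, ".tsv")))
    files[[length(files) + 1L]] <- paste0("matrix_", nm, ".tsv")
  }
  json <- report
  json$objects <- NULL
  class(json) <- NULL
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  files[[length(files) + 1L]] <- "report.json"
  jsonlite::write_json(list(outputs = unlist(files)), p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report$files <- file.path(outdir, unlist(files))
  report
}

#' One-line-per-quantity text summary of an analysis report
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @return Character vector of summary lines (also printed).
#' @export
summarize_report <- function(report) {
  cfg <- report$config
  fmt <- function(x, digits = 1) {
    if (is.null(x) || (length(x) == 1 && is.na(x))) "not run"
    else if (is.numeric(x)) format(round(x, digits), nsmall = 0)
    else x
  }
  lines <- c(
    sprintf("parameters: tau=%g w=%g bp psi=%g binsize=%g bp",
            cfg$score_threshold, cfg$gene_window, cfg$pseudocount,
            cfg$binsize),
    sprintf("peaks (mutant): %s", fmt(report$n_peaks_mutant)),
    sprintf("peaks (control): %s", fmt(report$n_peaks_control)),
    sprintf("pct mutant peaks in control: %s", fmt(report$pct_mutant_in_control)),
    sprintf("mutant-exclusive regions: %s", fmt(report$n_mutant_exclusive)),
    sprintf("more-accessible regions (score >= %g): %s",
            cfg$score_threshold, fmt(report$n_more_accessible)),
    sprintf("DE-co-located regions: %s", fmt(report$n_de_colocated_regions)),
    sprintf("k27-co-located regions: %s", fmt(report$n_k27_colocated)),
    sprintf("TF-co-located regions: %s", fmt(report$n_tf_colocated)))
  if (!is.null(report$signature_overlap)) {
    for (nm in names(report$signature_overlap)) {
      so <- report$signature_overlap[[nm]]
      lines <- c(lines, sprintf(
        "signature '%s': %d/%d DE genes (%.1f%%), p = %.3g",
        nm, so$n_overlap, so$n_a, 100 * so$fraction_of_a, so$p_value))
    }
  } else lines <- c(lines, "signature overlap: not run")
  cat(lines, sep = "\n")
  invisible(lines)
}
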