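#' Run the full maternal-decay pipeline on a dataset directory
#'
#' Executes the stages in dependency order on a directory laid out like
#' [write_synthetic_dataset()] output: maternal definition and decay
#' clustering, knockdown/DRB dependence, small-RNA target mapping,
#' CMR-lncRNA screening with genomic-context annotation, saRNA promoter
#' scanning, and the dependence-overlap summaries.  Every output is a
#' TSV with a commented provenance header, plus a run manifest
#' recording parameters, package version and input checksums.  Given
#' identical inputs and parameters the outputs are byte-identical.
#'
#' @param input_dir directory with `expression_control.tsv`,
#'   `expression_kd.tsv`, `expression_drb.tsv`, `smallrnas.tsv`,
#'   `transcripts.fa`, `lncrnas.fa`, `lnc_loci.tsv`, `genes.gff3`,
#'   `genome.fa`, `zga_genes.txt` (and optionally `mirnas.fa`).
#' @param output_dir where outputs are written (created if needed).
#' @param params [classification_params()].
#' @param v,m matcher settings for the transcript screen.
#' @param min_coverage,min_block,max_block_mismatch_frac CMR screen
#'   settings.
#' @param promoter_window,sarna_v saRNA screen settings (exact match by
#'   default).
#' @return invisibly, a list with the main result objects
#'   (`assignments`, `summary`, `target_map`, `cmr_hits`, `contexts`,
#'   `sarna_hits`, `histogram`).
#' @export
run_all <- function(input_dir, output_dir,
                    params = classification_params(),
                    v = 2L, m = 20L,
                    min_coverage = 0.9, min_block = 20L,
                    max_block_mismatch_frac = 0.05,
                    promoter_window = 1000L, sarna_v = 0L) {
  need <- c("expression_control.tsv", "expression_kd.tsv",
            "expression_drb.tsv", "smallrnas.tsv", "transcripts.fa",
            "lncrnas.fa", "lnc_loci.tsv", "genes.gff3", "genome.fa",
            "zga_genes.txt")
  paths <- file.path(input_dir, need)
  if (any(!file.exists(paths)))
    stop("missing input file(s): ",
         paste(paths[!file.exists(paths)], collapse = ", "))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  o <- function(...) file.path(output_dir, ...)
  run_params <- list(maternal_fpkm_threshold = params$maternal_fpkm_threshold,
                     log_delta = params$log_delta,
                     pseudocount = params$pseudocount, v = v, m = m,
                     min_coverage = min_coverage, min_block = min_block,
                     max_block_mismatch_frac = max_block_mismatch_frac,
                     promoter_window = promoter_window, sarna_v = sarna_v)

  ## stage 1: decay classification and dependence
  ctrl <- read_expression_table(file.path(input_dir, "expression_control.tsv"),
                                c("MII", "2C", "4C"))
  kd <- read_expression_table(file.path(input_dir, "expression_kd.tsv"),
                              c("2C", "4C"), condition = "knockdown")
  drb <- read_expression_table(file.path(input_dir, "expression_drb.tsv"),
                               "4C", condition = "DRB")
  maternal <- define_maternal(ctrl, params)
  asg <- classify_decay(ctrl, maternal, params)
  asg <- kd_dependence(ctrl, kd, asg, params)
  asg <- zga_dependence(drb, ctrl, asg, params)
  write_tsv_output(asg, o("decay_assignments.tsv"), run_params)
  write_tsv_output(summarize_assignments(asg), o("decay_summary.tsv"),
                   run_params)

  ## stage 2: small-RNA target mapping on maternal transcripts
  smallrnas <- read_smallrna_table(file.path(input_dir, "smallrnas.tsv"),
                                   c("MII", "zygote", "2C", "4C", "8C"))
  tx <- read_fasta(file.path(input_dir, "transcripts.fa"), "transcript")
  pool <- if ("class" %in% names(smallrnas))
    smallrnas[smallrnas$class != "saRNA", , drop = FALSE] else smallrnas
  tmap <- target_table(pool, tx, maternal, v = v, m = m)
  hits <- attr(tmap, "hits")
  write_tsv_output(hits, o("smallrna_hits.tsv"), run_params)
  write_tsv_output(data.frame(transcript_id = names(tmap),
                              n_smallrnas = lengths(tmap)),
                   o("target_counts.tsv"), run_params)

  ## stage 3: CMR-lncRNA screen against targeted transcripts
  lnc <- read_fasta(file.path(input_dir, "lncrnas.fa"), "lncRNA")
  lnc_nc <- coding_potential_filter(as_named_chr(lnc))
  targeted <- as.character(tx)[intersect(names(tmap), names(tx))]
  cmr <- complementarity_screen(lnc_nc, targeted,
                                min_coverage = min_coverage,
                                min_block = min_block,
                                max_block_mismatch_frac = max_block_mismatch_frac)
  write_tsv_output(cmr[setdiff(names(cmr), "blocks")], o("cmr_hits.tsv"),
                   run_params)
  gm <- read_gene_models(file.path(input_dir, "genes.gff3"))
  loci <- read.delim(file.path(input_dir, "lnc_loci.tsv"), comment.char = "#",
                     stringsAsFactors = FALSE)
  ctxs <- annotate_context(loci, gm)
  write_tsv_output(ctxs, o("lnc_contexts.tsv"), run_params)
  write_tsv_output(attr(ctxs, "fractions"), o("context_fractions.tsv"),
                   run_params)

  ## stage 4: saRNA promoter screen on ZGA genes
  genome <- read_fasta(file.path(input_dir, "genome.fa"), "genome")
  zga_ids <- readLines(file.path(input_dir, "zga_genes.txt"))
  cand <- filter_sarna_candidates(smallrnas)
  prom <- extract_promoters(gm[gm$gene_id %in% zga_ids, , drop = FALSE],
                            genome, window = promoter_window)
  shits <- scan_promoters(cand, prom, v = sarna_v, m = m)
  write_tsv_output(shits, o("sarna_hits.tsv"), run_params)
  write_tsv_output(data.frame(gene_id = names(prom),
                              targeted = names(prom) %in%
                                attr(shits, "targeted_genes")),
                   o("sarna_targeted.tsv"), run_params)
  hist <- positional_distribution(shits, bin_bp = 100L,
                                  window = promoter_window)
  write_tsv_output(hist, o("sarna_histogram.tsv"), run_params)

  ## stage 5: overlap summaries and manifest
  overlap <- zga_ago2_overlap(asg)
  write_tsv_output(data.frame(gene_id = overlap),
                   o("zga_ago2_overlap.tsv"), run_params)
  manifest <- data.frame(
    key = c("package_version",
            paste0("param_", names(run_params)),
            paste0("md5_", need)),
    value = c(as.character(utils::packageVersion("mztdecay")),
              vapply(run_params, function(x) paste(format(x), collapse = ","),
                     character(1)),
              unname(tools::md5sum(paths))),
    stringsAsFactors = FALSE)
  write.table(manifest, o("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(assignments = asg, summary = summarize_assignments(asg),
                 target_map = tmap, cmr_hits = cmr, contexts = ctxs,
                 sarna_hits = shits, histogram = hist,
                 maternal = maternal, overlap = overlap))
}
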