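#' Filter expressed small RNAs for the saRNA screen
#'
#' Retains small RNAs with length in `[min_len, max_len]` (18-30 nt
#' default, the post-trimming window of the screen) and RPM strictly
#' above `min_rpm` at ANY of the named early stages (zygote or 2-cell
#' by default).
#'
#' @param smallrnas data.frame with `id`, `sequence` and per-stage RPM
#'   columns.
#' @param min_len,max_len inclusive length bounds (defaults 18, 30).
#' @param min_rpm strict RPM threshold (default 1).
#' @param stages stage columns tested (default `c("zygote", "2C")`).
#' @return the retained rows.
#' @export
filter_sarna_candidates <- function(smallrnas, min_len = 18L, max_len = 30L,
                                    min_rpm = 1, stages = c("zygote", "2C")) {
  missing_st <- setdiff(stages, names(smallrnas))
  if (length(missing_st))
    stop("stage column(s) absent: ", paste(missing_st, collapse = ", "))
  len <- nchar(smallrnas$sequence)
  expr_ok <- Reduce(`|`, lapply(stages, function(s) smallrnas[[s]] > min_rpm))
  out <- smallrnas[len >= min_len & len <= max_len & expr_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract TSS-upstream promoter windows
#'
#' Strand-aware 1-kb-upstream windows: genomic `[TSS - window, TSS)` on
#' the `+` strand, `(TSS, TSS + window]` reverse-complemented on the
#' `-` strand, so every returned sequence reads 5'->3' towards the TSS
#' with its last base immediately TSS-adjacent.  Windows running off a
#' chromosome edge are truncated and flagged.
#'
#' @param gene_models a [gene_models()] table.
#' @param genome named chromosome sequences (`DNAStringSet` or
#'   character).
#' @param window upstream window size in bp (default 1000).
#' @return named character vector of promoter sequences (names =
#'   gene ids); attribute `truncated` lists genes with shortened
#'   windows, attribute `coords` the genomic window per gene (0-based
#'   half-open).
#' @export
extract_promoters <- function(gene_models, genome, window = 1000L) {
  genome <- as_named_chr(genome)
  keep <- gene_models$chrom %in% names(genome)
  if (any(!keep))
    warning(sum(!keep), " gene(s) absent from genome, skipped")
  gm <- gene_models[keep, , drop = FALSE]
  out <- character(nrow(gm))
  trunc <- logical(nrow(gm))
  starts <- integer(nrow(gm)); ends <- integer(nrow(gm))
  for (i in seq_len(nrow(gm))) {
    chrom_seq <- genome[[gm$chrom[i]]]
    L <- nchar(chrom_seq)
    tss <- gm$tss[i]
    if (gm$strand[i] == "+") {
      s <- max(0L, tss - window); e <- tss
      seq <- substr(chrom_seq, s + 1L, e)
      trunc[i] <- tss - window < 0L
    } else {
      s <- tss + 1L; e <- min(L, tss + 1L + window)
      seq <- revcomp(substr(chrom_seq, s + 1L, e))
      trunc[i] <- tss + 1L + window > L
    }
    out[i] <- seq; starts[i] <- s; ends[i] <- e
  }
  names(out) <- gm$gene_id
  attr(out, "truncated") <- gm$gene_id[trunc]
  attr(out, "coords") <- data.frame(gene_id = gm$gene_id, chrom = gm$chrom,
                                    start = starts, end = ends,
                                    strand = gm$strand,
                                    stringsAsFactors = FALSE)
  out
}

#' Scan promoter windows for candidate saRNAs
#'
#' Reuses the mismatch-bounded matcher ([find_hits()]) against promoter
#' windows.  Offsets are reported as the distance in bp from the TSS to
#' the hit's TSS-proximal end (1 = immediately TSS-adjacent).  Genes
#' with at least one hit form the saRNA-targeted gene set; the targeted
#' fraction is reported against the full supplied gene set.
#'
#' @param candidates filtered small RNAs ([filter_sarna_candidates()]).
#' @param promoters [extract_promoters()] output (named sequences).
#' @param v maximum mismatches (default 0: exact match).
#' @param m multimap cap as in [find_hits()] (default 20).
#' @return data.frame with `smallrna_id`, `gene_id`, `offset_upstream`,
#'   `orientation`, `mismatches`; attributes `targeted_genes`,
#'   `targeted_fraction` and `n_suppressed`.
#' @export
scan_promoters <- function(candidates, promoters, v = 0L, m = 20L) {
  window_len <- nchar(promoters)
  rows <- list()
  n_suppressed <- 0L
  for (i in seq_len(nrow(candidates))) {
    h <- find_hits(candidates[i, , drop = FALSE], promoters, v = v, m = m)
    if (isTRUE(attr(h, "suppressed"))) { n_suppressed <- n_suppressed + 1L; next }
    if (!nrow(h)) next
    qlen <- nchar(candidates$sequence[i])
    wl <- window_len[h$transcript_id]
    rows[[length(rows) + 1L]] <- data.frame(
      smallrna_id = h$smallrna_id,
      gene_id = h$transcript_id,
      offset_upstream = wl - (h$start + qlen) + 1L,
      orientation = h$orientation,
      mismatches = h$mismatches,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits))
    hits <- data.frame(smallrna_id = character(), gene_id = character(),
                       offset_upstream = integer(), orientation = character(),
                       mismatches = integer(), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  targeted <- sort(unique(hits$gene_id))
  attr(hits, "targeted_genes") <- targeted
  attr(hits, "targeted_fraction") <- length(targeted) / max(1L, length(promoters))
  attr(hits, "n_suppressed") <- n_suppressed
  hits
}

#' Positional distribution of saRNA hits upstream of the TSS
#'
#' Histogram of hit offsets in fixed-width bins `[k*bin, (k+1)*bin)`;
#' the bin totals conserve the hit count.
#'
#' @param hits [scan_promoters()] output.
#' @param bin_bp bin width (default 100).
#' @param window full window size determining the bin range (default
#'   the largest offset observed, rounded up to a bin).
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
positional_distribution <- function(hits, bin_bp = 100L, window = NULL) {
  if (nrow(hits) == 0L) {
    warning("no hits")
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  }
  if (is.null(window)) window <- max(hits$offset_upstream)
  # enough bins that every offset falls inside a half-open bin
  window <- as.integer((max(window, max(hits$offset_upstream)) %/% bin_bp + 1L) *
                         bin_bp)
  breaks <- seq(0L, window, by = bin_bp)
  bin <- hits$offset_upstream %/% bin_bp
  tab <- tabulate(bin + 1L, nbins = length(breaks) - 1L)
  data.frame(bin_start = breaks[-length(breaks)],
             bin_end = breaks[-1L],
             count = tab)
}
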