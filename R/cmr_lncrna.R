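#' Longest open reading frame, six frames
#'
#' Longest ATG-to-stop ORF length in codons (start codon counted, stop
#' excluded), scanning all three frames of the sequence and of its
#' reverse complement.  ORFs without an in-frame stop are not counted.
#'
#' @param seq character scalar, DNA alphabet.
#' @return integer codon count (0 when no ORF).
#' @export
longest_orf_codons <- function(seq) {
  seq <- toupper(seq)
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    atg <- as.integer(gregexpr("ATG", s, fixed = TRUE)[[1L]])
    stp <- sort(unlist(lapply(c("TAA", "TAG", "TGA"), function(p)
      as.integer(gregexpr(p, s, fixed = TRUE)[[1L]]))))
    atg <- atg[atg > 0L]; stp <- stp[stp > 0L]
    if (!length(atg) || !length(stp)) next
    for (f in 0:2) {
      a <- atg[(atg - 1L) %% 3L == f]
      st <- stp[(stp - 1L) %% 3L == f]
      if (!length(a) || !length(st)) next
      # nearest in-frame stop strictly downstream of each start
      idx <- findInterval(a, st) + 1L
      ok <- idx <= length(st)
      if (!any(ok)) next
      best <- max(best, (st[idx[ok]] - a[ok]) %/% 3L)
    }
  }
  best
}

#' Filter candidate lncRNAs by coding potential (declared stand-in)
#'
#' A simple ORF-length heuristic standing in for external
#' coding-potential classifiers so the lncRNA screen runs offline:
#' sequences whose longest six-frame ORF is shorter than
#' `max_orf_codons` codons are retained as noncoding.  This does NOT
#' reproduce the scores of dedicated coding-potential tools.
#'
#' @param candidates named sequences (character or `DNAStringSet`).
#' @param max_orf_codons retain sequences with longest ORF strictly
#'   below this many codons (default 100).
#' @return named character vector of retained sequences, with the
#'   per-sequence ORF lengths as attribute `orf_codons`.
#' @export
coding_potential_filter <- function(candidates, max_orf_codons = 100L) {
  seqs <- as_named_chr(candidates)
  orf <- vapply(seqs, longest_orf_codons, integer(1), USE.NAMES = FALSE)
  keep <- orf < max_orf_codons
  out <- seqs[keep]
  attr(out, "orf_codons") <- orf[keep]
  out
}

# maximum-coverage selection of non-overlapping intervals on the lncRNA
# (weighted interval scheduling, weight = interval length)
select_cover <- function(starts, ends) {
  n <- length(starts)
  if (n == 0L) return(integer(0))
  o <- order(ends, starts)
  starts <- starts[o]; ends <- ends[o]
  w <- ends - starts
  # p[i]: last interval (in sorted order) ending <= starts[i]
  p <- findInterval(starts, ends)
  opt <- numeric(n + 1L)
  take <- logical(n)
  for (i in seq_len(n)) {
    with_i <- w[i] + opt[p[i] + 1L]
    if (with_i > opt[i]) { opt[i + 1L] <- with_i; take[i] <- TRUE }
    else opt[i + 1L] <- opt[i]
  }
  sel <- integer(0)
  i <- n
  while (i >= 1L) {
    if (take[i]) { sel <- c(sel, i); i <- p[i] }
    else i <- i - 1L
  }
  o[rev(sel)]
}

#' Screen lncRNAs for long complementary blocks against target mRNAs
#'
#' For each (lncRNA, mRNA) pair the screen finds maximal ungapped
#' antisense blocks -- runs along a diagonal between the reverse
#' complement of the lncRNA and the mRNA -- of length at least
#' `min_block` with a per-block mismatch fraction at most
#' `max_block_mismatch_frac`, selects a non-overlapping set of blocks on
#' the lncRNA maximising covered length, and reports pairs whose
#' coverage (covered lncRNA bases / lncRNA length) strictly exceeds
#' `min_coverage`.  A shared exact antisense k-mer is used as a
#' necessary-condition pre-screen; it cannot change the result because
#' any qualifying block must contain an exact match run of at least
#' `k` bases (pigeonhole over its allowed mismatches).
#'
#' @param lncrnas named candidate lncRNA sequences.
#' @param target_mrnas named mRNA sequences (typically the
#'   endosiRNA-targeted maternal set).
#' @param min_coverage report pairs with coverage strictly above this
#'   (default 0.9).
#' @param min_block minimum block length in nt (default 20).
#' @param max_block_mismatch_frac maximum mismatch fraction inside a
#'   block (default 0.05).
#' @return data.frame with one row per qualifying pair: `lncrna_id`,
#'   `mrna_id`, `coverage`, `n_blocks`, plus a `blocks` list-column of
#'   per-pair data.frames (`lnc_start`, `lnc_end`, `mrna_start`,
#'   `mrna_end`, `mismatches`; 0-based half-open, lncRNA orientation).
#' @export
complementarity_screen <- function(lncrnas, target_mrnas, min_coverage = 0.9,
                                   min_block = 20L,
                                   max_block_mismatch_frac = 0.05) {
  lnc <- as_named_chr(lncrnas)
  mr <- as_named_chr(target_mrnas)
  if (length(mr) == 0L) {
    warning("empty target mRNA set")
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      coverage = numeric(), n_blocks = integer()))
  }
  # pigeonhole pre-screen: a block of length >= min_block with at most
  # floor(min_block * f) mismatches contains an exact run of >= k bases,
  # so scanning only diagonals carrying a shared exact k-mer cannot drop
  # any reportable block
  max_mm <- floor(min_block * max_block_mismatch_frac)
  k <- max(1L, (min_block - max_mm) %/% (max_mm + 1L))
  kmer_tab <- function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(data.frame(kmer = character(), pos = integer()))
    data.frame(kmer = substring(s, 1:n, k:nchar(s)), pos = seq_len(n),
               stringsAsFactors = FALSE)
  }
  mr_tabs <- lapply(mr, kmer_tab)
  mr_all <- data.frame(j = rep(seq_along(mr), vapply(mr_tabs, nrow, 0L)),
                       do.call(rbind, mr_tabs))
  km_index <- split(seq_len(nrow(mr_all)), mr_all$kmer)

  res <- list()
  for (i in seq_along(lnc)) {
    rc <- revcomp(lnc[[i]])
    lk <- kmer_tab(rc)
    shared <- km_index[lk$kmer]
    rows <- unlist(shared, use.names = FALSE)
    if (!length(rows)) next
    lpos <- rep(lk$pos, lengths(shared))
    pairs <- unique(data.frame(j = mr_all$j[rows],
                               d = mr_all$pos[rows] - lpos))
    for (j in unique(pairs$j)) {
      bl <- cpp_diagonal_blocks(rc, mr[[j]], as.integer(min_block),
                                max_block_mismatch_frac,
                                as.integer(pairs$d[pairs$j == j]))
      if (nrow(bl) == 0L) next
      sel <- select_cover(bl$a_start, bl$a_end)
      covered <- sum(bl$a_end[sel] - bl$a_start[sel])
      L <- nchar(lnc[[i]])
      cov <- covered / L
      if (cov > min_coverage) {
        bsel <- bl[sel, , drop = FALSE]
        # map block intervals from reverse-complement coordinates back
        # to the lncRNA's own orientation
        blocks <- data.frame(lnc_start = L - bsel$a_end,
                             lnc_end = L - bsel$a_start,
                             mrna_start = bsel$b_start,
                             mrna_end = bsel$b_end,
                             mismatches = bsel$mismatches)
        blocks <- blocks[order(blocks$lnc_start), , drop = FALSE]
        rownames(blocks) <- NULL
        res[[length(res) + 1L]] <-
          data.frame(lncrna_id = names(lnc)[i], mrna_id = names(mr)[j],
                     coverage = cov, n_blocks = length(sel),
                     blocks = I(list(blocks)), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(lncrna_id = character(), mrna_id = character(),
                      coverage = numeric(), n_blocks = integer())
  rownames(out) <- NULL
  out
}

#' Annotate lncRNA loci by genomic context
#'
#' Each locus is labelled by the feature class containing the majority
#' (> 50%) of its span: `coding_exon` (CDS), `UTR_exon` (exon minus
#' CDS), `intron` (gene span minus exons) or `intergenic`; `mixed` when
#' no class holds a majority.  Loci without coordinates are labelled
#' `unplaced` and excluded from the fraction table.
#'
#' @param loci data.frame with `lncrna_id`, `chrom`, `start`, `end`
#'   (0-based half-open); `chrom` may be `NA` for unplaced loci.
#' @param gene_models a [gene_models()] table (with `cds` list-column
#'   where coding annotation exists).
#' @return `loci` with a `context` column; attribute `fractions` is a
#'   data.frame of per-class fractions over placed loci.
#' @export
annotate_context <- function(loci, gene_models) {
  gr <- function(chrom, start, end) {
    if (length(chrom) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  }
  genes <- gr(gene_models$chrom, gene_models$start, gene_models$end)
  ex_n <- vapply(gene_models$exons, function(e) if (is.null(e)) 0L else nrow(e),
                 integer(1))
  exons <- gr(rep(gene_models$chrom, ex_n),
              unlist(lapply(gene_models$exons, function(e) e[, 1L])),
              unlist(lapply(gene_models$exons, function(e) e[, 2L])))
  cds_list <- if (is.null(gene_models$cds))
    vector("list", nrow(gene_models)) else gene_models$cds
  cds_n <- vapply(cds_list, function(e) if (is.null(e)) 0L else nrow(e),
                  integer(1))
  cds <- gr(rep(gene_models$chrom, cds_n),
            unlist(lapply(cds_list, function(e) if (!is.null(e)) e[, 1L])),
            unlist(lapply(cds_list, function(e) if (!is.null(e)) e[, 2L])))
  coding <- GenomicRanges::reduce(cds)
  utr <- GenomicRanges::setdiff(GenomicRanges::reduce(exons), coding)
  intron <- GenomicRanges::setdiff(GenomicRanges::reduce(genes),
                                   GenomicRanges::reduce(exons))
  classes <- list(coding_exon = coding, UTR_exon = utr, intron = intron)

  placed <- !is.na(loci$chrom)
  context <- rep("unplaced", nrow(loci))
  if (any(placed)) {
    lgr <- gr(loci$chrom[placed], loci$start[placed], loci$end[placed])
    width <- GenomicRanges::width(lgr)
    ov_width <- sapply(classes, function(cl) {
      hits <- GenomicRanges::findOverlaps(lgr, cl)
      w <- rep(0L, length(lgr))
      if (length(hits)) {
        pw <- GenomicRanges::width(GenomicRanges::pintersect(
          lgr[S4Vectors::queryHits(hits)], cl[S4Vectors::subjectHits(hits)]))
        w <- as.integer(tapply(pw, factor(S4Vectors::queryHits(hits),
                                          levels = seq_along(lgr)), sum))
        w[is.na(w)] <- 0L
      }
      w
    })
    ov_width <- matrix(ov_width, nrow = length(lgr),
                       dimnames = list(NULL, names(classes)))
    inter <- width - rowSums(ov_width)
    all_w <- cbind(ov_width, intergenic = inter)
    lab <- colnames(all_w)[max.col(all_w, ties.method = "first")]
    lab[apply(all_w, 1L, max) <= width / 2] <- "mixed"
    context[placed] <- lab
  }
  loci$context <- context
  tab <- table(factor(context[placed],
                      levels = c("intron", "coding_exon", "UTR_exon",
                                 "intergenic", "mixed")))
  attr(loci, "fractions") <- data.frame(context = names(tab),
                                        fraction = as.numeric(tab) / max(1L, sum(tab)),
                                        count = as.integer(tab),
                                        stringsAsFactors = FALSE)
  loci
}
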