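# pad a reverse-complement-space lncRNA so padding cannot extend the
# planted block along its diagonal
anti_pad <- function(len, mrna, diag_off) {
  if (len == 0L) return("")
  ch <- character(len)
  for (q in seq_len(len)) {
    mpos <- q + diag_off
    forbid <- if (mpos >= 1L && mpos <= nchar(mrna))
      substr(mrna, mpos, mpos) else ""
    ch[q] <- setdiff(c("A", "C", "G", "T"), forbid)[1L]
  }
  paste(ch, collapse = "")
}

test_that("ORF filter retains short-ORF sequences and drops long ones", {
  no_atg <- paste(rep("C", 300), collapse = "")
  expect_identical(longest_orf_codons(no_atg), 0L)
  # 150 codons: ATG + 149 x AAA + TAA; embed in a C-only context so no
  # spurious frames appear
  orf <- paste0("ATG", paste(rep("AAA", 149), collapse = ""), "TAA")
  long <- paste0(paste(rep("C", 30), collapse = ""), orf,
                 paste(rep("C", 30), collapse = ""))
  expect_identical(longest_orf_codons(long), 150L)
  kept <- coding_potential_filter(c(a = no_atg, b = long),
                                  max_orf_codons = 100L)
  expect_identical(names(kept), "a")
})

test_that("ORF lengths agree with a brute-force six-frame oracle", {
  set.seed(40)
  for (i in 1:25) {
    s <- rand_dna(sample(60:240, 1))
    expect_identical(longest_orf_codons(s), oracle_longest_orf(s))
  }
})

test_that("complementarity coverage respects the 90% threshold", {
  set.seed(41)
  mrna <- c(M1 = rand_dna(500))
  build_lnc <- function(block_len) {
    ms <- 100L
    block <- substr(mrna[["M1"]], ms + 1L, ms + block_len)
    pad <- 300L - block_len
    rc_lnc <- paste0(block, anti_pad(pad, mrna[["M1"]], ms + block_len))
    rc(rc_lnc)
  }
  hit <- complementarity_screen(c(L280 = build_lnc(280L)), mrna)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$coverage, 280 / 300)
  miss <- complementarity_screen(c(L250 = build_lnc(250L)), mrna)
  expect_identical(nrow(miss), 0L)
})

test_that("reported blocks are consistent with coverage and bounds", {
  set.seed(42)
  s <- small_synth()
  sq <- s$sq
  hits <- complementarity_screen(sq$lncrnas, sq$transcripts)
  expect_true(all(hits$coverage <= 1))
  for (i in seq_len(nrow(hits))) {
    b <- hits$blocks[[i]]
    L <- nchar(sq$lncrnas[[hits$lncrna_id[i]]])
    expect_true(all(b$lnc_start >= 0 & b$lnc_end <= L))
    # non-overlapping on the lncRNA
    if (nrow(b) > 1L)
      expect_true(all(b$lnc_start[-1L] >= b$lnc_end[-nrow(b)]))
    expect_equal(sum(b$lnc_end - b$lnc_start) / L, hits$coverage[i])
  }
})

test_that("planted CMR pairs are recovered and decoys stay clean", {
  s <- small_synth()
  sq <- s$sq
  hits <- complementarity_screen(sq$lncrnas, sq$transcripts)
  truth <- sq$truth$cmr
  above <- truth[truth$true_coverage >= 0.93, ]
  for (i in seq_len(nrow(above))) {
    row <- hits[hits$lncrna_id == above$lncrna_id[i] &
                hits$mrna_id == above$mrna_id[i], ]
    expect_identical(nrow(row), 1L)
    expect_equal(row$coverage, above$true_coverage[i])
  }
  below <- truth$lncrna_id[truth$true_coverage <= 0.87]
  expect_false(any(hits$lncrna_id %in% below))
  expect_false(any(hits$lncrna_id %in% sq$truth$scrambled_ids))
})

test_that("the k-mer diagonal pre-screen does not change results", {
  set.seed(43)
  # compare restricted-diagonal block finding against a full scan on
  # constructed pairs with planted blocks
  for (i in 1:10) {
    mrna <- rand_dna(400)
    ms <- sample(100, 1)
    blk <- substr(mrna, ms, ms + 119L)
    rc_lnc <- paste0(rand_dna(40), blk, rand_dna(40))
    full <- mztdecay:::cpp_diagonal_blocks(rc_lnc, mrna, 20L, 0.05)
    hit1 <- complementarity_screen(c(L = rc(rc_lnc)), c(M = mrna),
                                   min_coverage = 0)
    sel <- mztdecay:::select_cover(full$a_start, full$a_end)
    expect_equal(hit1$coverage[1L],
                 sum(full$a_end[sel] - full$a_start[sel]) / nchar(rc_lnc))
  }
})

test_that("genomic context labels follow the majority rule", {
  gm <- gene_models(data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+",
    start = 1000L, end = 3000L,
    exons = I(list(rbind(c(1000L, 1300L), c(1800L, 2200L), c(2700L, 3000L)))),
    cds = I(list(rbind(c(1800L, 2200L)))),
    stringsAsFactors = FALSE))
  loci <- data.frame(
    lncrna_id = c("in_intron", "in_cds", "in_utr", "outside", "straddle"),
    chrom = "chr1",
    start = c(1400L, 1900L, 1050L, 5000L, 950L),
    end = c(1600L, 2100L, 1250L, 5200L, 1060L),
    stringsAsFactors = FALSE)
  out <- annotate_context(loci, gm)
  expect_identical(out$context,
                   c("intron", "coding_exon", "UTR_exon", "intergenic",
                     "UTR_exon"))
  fr <- attr(out, "fractions")
  expect_equal(sum(fr$fraction), 1)
})

test_that("planted context fractions are reproduced exactly", {
  s <- small_synth()
  sq <- s$sq
  out <- annotate_context(sq$lnc_loci, sq$gene_models)
  truth <- sq$truth$contexts
  expect_identical(out$context,
                   truth$context[match(out$lncrna_id, truth$lncrna_id)])
  fr <- attr(out, "fractions")
  want <- table(factor(truth$context, levels = fr$context)) / nrow(truth)
  expect_equal(fr$fraction, as.numeric(want))
})
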