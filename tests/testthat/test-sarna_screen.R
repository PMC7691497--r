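test_that("saRNA candidate filter applies length and RPM bounds", {
  df <- data.frame(
    id = c("keep", "short", "weak"),
    sequence = c(paste(rep("A", 22), collapse = ""),
                 paste(rep("A", 17), collapse = ""),
                 paste(rep("A", 25), collapse = "")),
    zygote = c(5, 5, 0.5), `2C` = c(0, 5, 0.5),
    check.names = FALSE, stringsAsFactors = FALSE)
  out <- filter_sarna_candidates(df)
  expect_identical(out$id, "keep")
  expect_error(filter_sarna_candidates(df, stages = c("zygote", "8C")), "8C")
  # boundary: RPM exactly 1 is excluded (strict >)
  df$zygote <- c(1, 5, 1); df$`2C` <- c(1, 5, 1)
  expect_identical(nrow(filter_sarna_candidates(df)), 0L)
})

test_that("promoter windows are strand-aware and TSS-adjacent", {
  chrom <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE),
                 collapse = "")
  gm <- gene_models(data.frame(
    gene_id = c("plus", "minus"), chrom = "chr1", strand = c("+", "-"),
    start = c(5000L, 2000L), end = c(6000L, 5001L),
    stringsAsFactors = FALSE))
  pr <- extract_promoters(gm, c(chr1 = chrom), window = 1000L)
  # + strand, TSS = 5000: genomic [4000, 5000)
  expect_identical(pr[["plus"]], substr(chrom, 4001L, 5000L))
  # - strand, TSS = 5000: genomic (5000, 6000], reverse-complemented
  expect_identical(pr[["minus"]], rc(substr(chrom, 5002L, 6001L)))
  co <- attr(pr, "coords")
  expect_identical(co$start[co$gene_id == "plus"], 4000L)
  expect_identical(co$end[co$gene_id == "minus"], 6001L)

  gm2 <- gene_models(data.frame(gene_id = "edge", chrom = "chr1",
                                strand = "+", start = 300L, end = 1300L,
                                stringsAsFactors = FALSE))
  pr2 <- extract_promoters(gm2, c(chr1 = chrom), window = 1000L)
  expect_identical(nchar(pr2[["edge"]]), 300L)
  expect_identical(attr(pr2, "truncated"), "edge")
})

test_that("promoter hits report TSS-proximal offsets", {
  set.seed(50)
  win <- rand_dna(1000)
  cand_seq <- rand_dna(22)
  # place so the hit spans offsets 250-271 upstream of the TSS
  p2 <- 1000L - 250L + 1L; p1 <- p2 - 22L + 1L
  substr(win, p1, p2) <- cand_seq
  cand <- data.frame(id = "c1", sequence = cand_seq,
                     stringsAsFactors = FALSE)
  hits <- scan_promoters(cand, c(gA = win))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$offset_upstream, 250L)
  expect_identical(hits$gene_id, "gA")
  expect_identical(attr(hits, "targeted_genes"), "gA")

  # a match beyond the 1-kb window is never seen
  far <- data.frame(id = "c2", sequence = rand_dna(22),
                    stringsAsFactors = FALSE)
  long_prom <- paste0(far$sequence, rand_dna(1000))  # sits 1.2 kb out
  hits2 <- scan_promoters(far, c(gB = substring(long_prom, 23L, 1022L)))
  expect_identical(nrow(hits2), 0L)
})

test_that("positional histograms bin offsets and conserve counts", {
  hits <- data.frame(smallrna_id = c("a", "b", "c"), gene_id = "g",
                     offset_upstream = c(210L, 250L, 390L),
                     orientation = "sense", mismatches = 0L,
                     stringsAsFactors = FALSE)
  h <- positional_distribution(hits, bin_bp = 100L)
  expect_identical(h$count[h$bin_start == 200L], 2L)
  expect_identical(h$count[h$bin_start == 300L], 1L)
  expect_identical(sum(h$count), nrow(hits))
  one <- positional_distribution(
    data.frame(offset_upstream = rep(50L, 4L)), bin_bp = 100L)
  expect_identical(sum(one$count > 0L), 1L)
  expect_warning(positional_distribution(hits[0L, ]), "no hits")
})

test_that("planted promoter placements are recovered exactly", {
  s <- small_synth()
  sq <- s$sq
  cand <- filter_sarna_candidates(sq$smallrnas)
  prom <- extract_promoters(sq$gene_models, sq$genome)
  hits <- scan_promoters(cand, prom)
  truth <- sq$truth$sarna
  key <- function(d) sort(paste(d$smallrna_id, d$gene_id, d$offset_upstream))
  expect_identical(key(hits), key(truth))
  # every hit round-trips: offset within the window, gene in the ZGA set
  expect_true(all(hits$offset_upstream >= 1L & hits$offset_upstream <= 1000L))
  expect_true(all(hits$gene_id %in% sq$truth$zga_genes))
})
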