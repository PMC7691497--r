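test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 70, n_genes = 100, n_transcripts = 20,
                      n_smallrnas = 60, n_lncrnas = 10, n_scrambled = 5,
                      n_zga_genes = 20, n_sarnas = 10, n_lnc_loci = 8,
                      n_replicates = 4)
  a <- gen_expression(cfg); b <- gen_expression(cfg)
  expect_identical(a, b)
  sa <- gen_sequences(cfg); sb <- gen_sequences(cfg)
  expect_identical(sa, sb)
  ta <- gen_timecourses(cfg); tb <- gen_timecourses(cfg)
  expect_identical(ta, tb)
  # components are independent substreams: a different-kinetics config
  # leaves the sequence component untouched
  cfg2 <- synth_config(seed = 70, n_genes = 100, n_transcripts = 20,
                       n_smallrnas = 60, n_lncrnas = 10, n_scrambled = 5,
                       n_zga_genes = 20, n_sarnas = 10, n_lnc_loci = 8,
                       n_replicates = 9)
  expect_identical(gen_sequences(cfg2), sa)
})

test_that("zero-noise matrices classify back to the planted labels", {
  cfg <- synth_config(seed = 71, n_genes = 500, noise_sd = 0)
  ex <- gen_expression(cfg)
  asg <- classify_decay(ex$control, define_maternal(ex$control))
  expect_identical(as.character(asg$cluster),
                   ex$truth$cluster[match(asg$gene_id, ex$truth$gene_id)])
  # all planted genes clear the maternal threshold
  expect_identical(length(define_maternal(ex$control)), 500L)
})

test_that("degenerate configurations produce empty outputs", {
  cfg <- synth_config(seed = 72, n_genes = 0)
  ex <- gen_expression(cfg)
  expect_identical(nrow(ex$control), 0L)
  expect_identical(nrow(ex$truth), 0L)
  expect_error(synth_config(cluster_proportions = c(I = 0.9, II = 0.9,
                                                    III = 0, none = 0)),
               "sum to 1")
})

test_that("planted 2-mismatch guides need v = 2 and vanish at v = 1", {
  s <- small_synth()
  sq <- s$sq
  truth <- sq$truth$smallrna_targets
  two <- truth[truth$mismatches == 2L, ][1L, ]
  rec <- sq$smallrnas[sq$smallrnas$id == two$smallrna_id, ]
  h2 <- find_hits(rec, sq$transcripts, v = 2L, m = Inf)
  expect_identical(h2$transcript_id, two$transcript_id)
  expect_identical(h2$start, two$start)
  expect_identical(h2$mismatches, 2L)
  h1 <- find_hits(rec, sq$transcripts, v = 1L, m = Inf)
  expect_identical(nrow(h1), 0L)
})

test_that("planted lncRNA coverages straddle the screen threshold", {
  s <- small_synth()
  truth <- s$sq$truth$cmr
  expect_true(any(truth$true_coverage > 0.9))
  expect_true(any(truth$true_coverage < 0.9))
})

test_that("noiseless time courses refit their true constants exactly", {
  cfg <- synth_config(seed = 73, kinetics_cv = 0, n_replicates = 2)
  tc <- gen_timecourses(cfg)
  for (i in seq_along(tc$courses)) {
    est <- fit_decay(tc$courses[[i]])
    expect_equal(est$k, tc$truth$k[i], tolerance = 1e-10)
  }
})

test_that("every generated file parses back through the readers", {
  cfg <- small_synth()$cfg
  d <- withr::local_tempdir()
  write_synthetic_dataset(cfg, d)
  expect_no_warning({
    ctrl <- read_expression_table(file.path(d, "expression_control.tsv"),
                                  c("MII", "2C", "4C"))
    kd <- read_expression_table(file.path(d, "expression_kd.tsv"),
                                c("2C", "4C"))
    drb <- read_expression_table(file.path(d, "expression_drb.tsv"), "4C")
    tx <- read_fasta(file.path(d, "transcripts.fa"), "transcript")
    lnc <- read_fasta(file.path(d, "lncrnas.fa"), "lncRNA")
    gen <- read_fasta(file.path(d, "genome.fa"), "genome")
    gm <- read_gene_models(file.path(d, "genes.gff3"))
    sm <- read_smallrna_table(file.path(d, "smallrnas.tsv"),
                              c("MII", "zygote", "2C", "4C", "8C"))
  })
  # written matrices round-trip against the in-memory generation
  ex <- gen_expression(cfg)
  expect_equal(unclass(ctrl)[, ], unclass(ex$control)[, ])
  sq <- gen_sequences(cfg)
  expect_identical(unname(as.character(tx)), unname(sq$transcripts))
  expect_identical(gm$tss, sq$gene_models$tss)
})
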