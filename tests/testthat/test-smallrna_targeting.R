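test_that("exact antisense complements are found with zero mismatches", {
  set.seed(30)
  tx <- c(t1 = rand_dna(200), t2 = rand_dna(200))
  q <- rc(substr(tx[["t1"]], 50, 70))       # 21-nt window, antisense
  h <- find_hits(q, tx, v = 0L, m = Inf)
  expect_identical(nrow(h), 1L)
  expect_identical(h$transcript_id, "t1")
  expect_identical(h$start, 49L)
  expect_identical(h$orientation, "antisense")
  expect_identical(h$mismatches, 0L)
})

test_that("placements beyond the mismatch bound are rejected", {
  set.seed(31)
  tx <- c(t1 = rand_dna(200))
  win <- substr(tx[["t1"]], 50, 70)
  # force 3 mismatches into the query
  ch <- strsplit(rc(win), "")[[1L]]
  for (p in c(3L, 10L, 17L))
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
  q3 <- paste(ch, collapse = "")
  expect_identical(nrow(find_hits(q3, tx, v = 2L, m = Inf)), 0L)
  h3 <- find_hits(q3, tx, v = 3L, m = Inf)
  expect_identical(h3$mismatches, 3L)
})

test_that("queries over the multimap cap are suppressed entirely", {
  set.seed(39)
  motif <- "ACGTTGCAACGTTGCAACGTT"        # 21 nt
  tx <- setNames(vapply(1:25, function(i)
    paste0(rand_dna(30), motif, rand_dna(30)), ""), sprintf("t%02d", 1:25))
  h <- find_hits(motif, tx, v = 0L, m = 20L)
  expect_identical(nrow(h), 0L)
  expect_true(attr(h, "suppressed"))
  expect_gte(attr(h, "n_placements"), 25L)
  h2 <- find_hits(motif, tx, v = 0L, m = Inf)
  expect_false(attr(h2, "suppressed"))
  expect_gte(nrow(h2), 25L)
})

test_that("matcher agrees with the independent oracle on random instances", {
  set.seed(32)
  tx <- setNames(vapply(1:20, function(i) rand_dna(300), ""),
                 sprintf("t%02d", 1:20))
  for (rep in 1:30) {
    if (rep %% 2 == 0) {
      q <- rand_dna(sample(18:25, 1))
    } else {
      j <- sample(20, 1)
      s <- sample(270, 1)
      len <- sample(18:25, 1)
      q <- rc(substr(tx[[j]], s, s + len - 1L))
      ch <- strsplit(q, "")[[1L]]
      nmut <- sample(0:3, 1)
      for (p in sample(len, nmut))
        ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
      q <- paste(ch, collapse = "")
    }
    v <- sample(0:2, 1)
    m <- sample(c(1L, 20L, Inf), 1)
    got <- find_hits(q, tx, v = v, m = m)
    want <- oracle_find_hits(q, tx, v = v, m = m)
    expect_identical(hit_frame(got), hit_frame(want))
    expect_identical(attr(got, "suppressed"), attr(want, "suppressed"))
  }
})

test_that("N never matches, even against N", {
  tx <- c(t1 = "AAAANAAAAANAAAAAAAAAA")
  q <- rc(tx[["t1"]])
  expect_identical(nrow(find_hits(q, tx, v = 1L, m = Inf)), 0L)
  h <- find_hits(q, tx, v = 2L, m = Inf)   # two N positions = 2 mismatches
  expect_identical(h$mismatches, 2L)
  expect_error(find_hits("ACGX", tx), "outside")
})

test_that("reverse-complementing query and transcripts preserves hit count", {
  set.seed(34)
  for (i in 1:10) {
    tx <- c(a = rand_dna(150), b = rand_dna(150))
    q <- rc(substr(tx[["a"]], 40, 60))
    h1 <- find_hits(q, tx, v = 2L, m = Inf)
    tx_rc <- vapply(tx, rc, "")
    h2 <- find_hits(rc(q), tx_rc, v = 2L, m = Inf)
    expect_identical(nrow(h1), nrow(h2))
    expect_identical(sort(table(h1$orientation)),
                     sort(table(h2$orientation)))
  }
})

test_that("suppression is monotone in m and hits monotone in v", {
  set.seed(35)
  tx <- setNames(vapply(1:10, function(i) rand_dna(300), ""),
                 sprintf("t%02d", 1:10))
  q <- rc(substr(tx[[3L]], 100, 121))
  for (v in 0:2) {
    h_inf <- find_hits(q, tx, v = v, m = Inf)
    h_1 <- find_hits(q, tx, v = v, m = 1L)
    expect_lte(nrow(h_1), nrow(h_inf))          # lowering m never adds hits
  }
  h0 <- find_hits(q, tx, v = 0L, m = Inf)
  h2 <- find_hits(q, tx, v = 2L, m = Inf)
  key <- function(h) paste(h$transcript_id, h$start, h$orientation)
  expect_true(all(key(h0) %in% key(h2)))        # raising v never removes
})

test_that("planted target maps are recovered exactly", {
  s <- small_synth()
  sq <- s$sq
  pool <- sq$smallrnas[sq$smallrnas$class != "saRNA", , drop = FALSE]
  tmap <- target_table(pool, sq$transcripts, names(sq$transcripts))
  truth <- sq$truth$smallrna_targets
  want <- lapply(split(truth$smallrna_id, truth$transcript_id),
                 function(x) sort(unique(x)))
  expect_identical(tmap[order(names(tmap))], want[order(names(want))])
  expect_identical(attr(tmap, "n_suppressed"), 0L)

  # empty pool gives an empty map
  empty <- target_table(pool[0L, ], sq$transcripts, names(sq$transcripts))
  expect_length(empty, 0L)
})

test_that("microRNA seed stand-in requires an exact seed site", {
  set.seed(36)
  tx_seq <- rand_dna(300)
  mir <- "TAGCTTATCAGACTGATGTTGA"
  site <- rc(substr(mir, 2, 8))
  tx <- c(hit = paste0(substr(tx_seq, 1, 100), site, substr(tx_seq, 101, 200)),
          miss = rand_dna(300))
  # ensure the decoy lacks the site by construction
  while (grepl(site, tx[["miss"]], fixed = TRUE)) tx[["miss"]] <- rand_dna(300)
  got <- mirna_seed_targets(c(m1 = mir), tx)
  expect_identical(names(got), "hit")
  expect_identical(got[["hit"]], "m1")
  # one mismatch in the site is not a target
  ch <- strsplit(site, "")[[1L]]
  ch[4L] <- setdiff(c("A", "C", "G", "T"), ch[4L])[1L]
  tx2 <- c(near = paste0(rand_dna(100), paste(ch, collapse = ""), rand_dna(100)))
  while (grepl(site, tx2[["near"]], fixed = TRUE))
    tx2[["near"]] <- paste0(rand_dna(100), paste(ch, collapse = ""), rand_dna(100))
  expect_length(mirna_seed_targets(c(m1 = mir), tx2), 0L)
  expect_error(mirna_seed_targets(c(m1 = "ACGTAC"), tx), "seed_span")
})

test_that("planted seed sites are recovered completely", {
  s <- small_synth()
  sq <- s$sq
  got <- mirna_seed_targets(sq$mirnas, sq$transcripts)
  truth <- sq$truth$mirna_targets
  for (i in seq_len(nrow(truth)))
    expect_true(truth$mirna_id[i] %in% got[[truth$transcript_id[i]]])
})

test_that("stage profiles summarise per-stage abundance", {
  df <- data.frame(id = c("a", "b"), sequence = c("ACGTACGTACGTACGTACGT",
                                                  "TTTTACGTACGTACGTACGT"),
                   zygote = c(2, 4), `2C` = c(1, 3), check.names = FALSE)
  pr <- stage_profile(c("a", "b"), df)
  expect_equal(pr$mean[pr$stage == "zygote"], 3)
  expect_equal(pr$mean[pr$stage == "2C"], 2)
  expect_warning(stage_profile(c("a", "zzz"), df), "unknown")
  expect_error(stage_profile(character(0), df), "empty")
})
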