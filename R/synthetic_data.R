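#' Configuration for the synthetic dataset generator
#'
#' One global seed fans out to per-component deterministic substreams
#' (expression, sequences, time courses), so regenerating one component
#' never perturbs the others.  Defaults are sized so the full pipeline
#' runs in minutes on one CPU: 2,000 genes with planted decay-cluster
#' proportions 0.25/0.2/0.15/0.4, 5,000 small RNAs, 200 lncRNAs and
#' 300 ZGA genes.
#'
#' @param seed integer global seed.
#' @param n_genes number of maternal genes in the expression matrices.
#' @param cluster_proportions named proportions for clusters
#'   I/II/III/none (must sum to 1).
#' @param margin_range planted log2 decay-step range; the lower bound
#'   defaults to 1.5x the classification delta so planted effects stay
#'   separable under noise.
#' @param base_log2_range MII baseline `log2(FPKM+1)` range (keeps all
#'   genes above the maternal FPKM threshold).
#' @param noise_sd i.i.d. Gaussian noise sd in log2 space.
#' @param ago2_dep_fraction,zga_dep_fraction fractions of eligible
#'   cluster genes planted as knockdown-/DRB-stabilised.
#' @param n_transcripts,transcript_len transcript sequences emulating
#'   the AGO2-dependent maternal mRNA set.
#' @param n_smallrnas small-RNA pool size; `planted_antisense_fraction`
#'   of it is planted as antisense guides with mismatch counts drawn
#'   from `mismatch_probs` (over 0/1/2).
#' @param guide_len_range planted guide length range (nt).
#' @param n_mirnas,mirna_planted_fraction microRNA pool and the
#'   fraction with planted seed sites.
#' @param n_lncrnas,lncrna_len lncRNA pool; planted complementary-block
#'   coverages cycle through `cmr_coverages` (straddling the 0.9
#'   screen threshold) for `cmr_planted_fraction` of the pool.
#' @param n_scrambled scrambled-decoy lncRNAs.
#' @param n_zga_genes toy-genome gene count; `n_sarnas` small RNAs are
#'   planted into their 1-kb upstream windows, `sarna_band_fraction` of
#'   them at 200-400 bp offsets.
#' @param n_lnc_loci,context_fractions planted lncRNA genomic loci and
#'   their feature-context proportions.
#' @param k_control,k_mimic_factor,k_inhibitor_factor first-order decay
#'   constants (per hour): control default `ln(2)/2` (2 h half-life),
#'   mimic/inhibitor as multiples of control.
#' @param timepoints hours post transcription block.
#' @param kinetics_cv multiplicative log-normal noise CV.
#' @param n_replicates time-course replicates per condition.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 2000L,
                         cluster_proportions = c(I = 0.25, II = 0.2,
                                                 III = 0.15, none = 0.4),
                         margin_range = c(1.5, 3),
                         base_log2_range = c(3, 8),
                         noise_sd = 0.2,
                         ago2_dep_fraction = 0.5,
                         zga_dep_fraction = 0.5,
                         n_transcripts = 400L,
                         transcript_len = 500L,
                         n_smallrnas = 5000L,
                         planted_antisense_fraction = 0.4,
                         mismatch_probs = c(`0` = 0.5, `1` = 0.3, `2` = 0.2),
                         guide_len_range = c(20L, 24L),
                         n_mirnas = 50L,
                         mirna_planted_fraction = 0.5,
                         n_lncrnas = 200L,
                         lncrna_len = 300L,
                         cmr_planted_fraction = 0.5,
                         cmr_coverages = c(0.95, 0.93, 0.85, 0.8),
                         n_scrambled = 100L,
                         n_zga_genes = 300L,
                         promoter_window = 1000L,
                         n_sarnas = 150L,
                         sarna_band_fraction = 0.7,
                         sarna_band = c(200L, 400L),
                         n_lnc_loci = 50L,
                         context_fractions = c(intron = 0.4, coding_exon = 0.2,
                                               UTR_exon = 0.1, intergenic = 0.3),
                         k_control = log(2) / 2,
                         k_mimic_factor = 2,
                         k_inhibitor_factor = 0.5,
                         timepoints = seq(0, 8, length.out = 6),
                         kinetics_cv = 0.05,
                         n_replicates = 200L) {
  if (abs(sum(cluster_proportions) - 1) > 1e-8 || any(cluster_proportions < 0))
    stop("cluster_proportions must be non-negative and sum to 1")
  if (abs(sum(context_fractions) - 1) > 1e-8)
    stop("context_fractions must sum to 1")
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# deterministic per-component substream seeds (kept below 2^31)
component_seed <- function(seed, component)
  as.integer((as.numeric(seed) * 97L + component * 1000003) %% 2147483629)

rand_seq <- function(len)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

mutate_bases <- function(seq, n_mut) {
  if (n_mut == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate stage expression matrices with planted decay clusters
#'
#' Genes are drawn with planted log2-space stage dynamics: cluster I
#' drops by a planted margin before the 2-cell stage then stays flat,
#' cluster II stays flat then drops, cluster III drops twice, "none"
#' stays flat throughout.  A planted subset of cluster genes is
#' AGO2-dependent (the knockdown matrix holds their pre-decay level)
#' and, for the 2C/4C leg, ZGA-dependent (the DRB matrix likewise).
#' I.i.d. Gaussian noise (`noise_sd`, log2 scale) is added on top; the
#' planted truth is emitted alongside.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `control`, `kd`, `drb`
#'   ([stage_matrix()]s) and `truth` (data.frame of planted cluster
#'   labels and dependence flags).
#' @export
gen_expression <- function(cfg) {
  set.seed(component_seed(cfg$seed, 1L))
  n <- cfg$n_genes
  stages <- c("MII", "2C", "4C")
  empty <- function(cond, cols) {
    m <- matrix(numeric(0), 0L, length(cols),
                dimnames = list(character(0), cols))
    stage_matrix(m, cond)
  }
  if (n == 0L)
    return(list(control = empty("control", stages),
                kd = empty("knockdown", c("2C", "4C")),
                drb = empty("DRB", "4C"),
                truth = data.frame(gene_id = character(),
                                   cluster = character(),
                                   ago2_dependent_MII_2C = logical(),
                                   ago2_dependent_2C_4C = logical(),
                                   zga_dependent = logical())))
  ids <- sprintf("G%05d", seq_len(n))
  counts <- floor(cfg$cluster_proportions * n)
  counts["none"] <- n - sum(counts[c("I", "II", "III")])
  cluster <- sample(rep(names(counts), counts))
  d1 <- runif(n, cfg$margin_range[1L], cfg$margin_range[2L])
  d2 <- runif(n, cfg$margin_range[1L], cfg$margin_range[2L])
  # keep the fully-decayed level comfortably above log2(FPKM+1) = 0 so
  # the linear-scale floor never erodes a planted margin
  drop_total <- ifelse(cluster == "I", d1,
                       ifelse(cluster == "II", d2,
                              ifelse(cluster == "III", d1 + d2, 0)))
  lo <- pmax(cfg$base_log2_range[1L], drop_total + 0.5)
  base <- lo + runif(n) * pmax(cfg$base_log2_range[2L] - lo, 0.1)
  e_mii <- base
  e_2c <- base - ifelse(cluster %in% c("I", "III"), d1, 0)
  e_4c <- e_2c - ifelse(cluster %in% c("II", "III"), d2, 0)

  ago2_12 <- cluster %in% c("I", "III") &
    runif(n) < cfg$ago2_dep_fraction
  ago2_24 <- cluster %in% c("II", "III") &
    runif(n) < cfg$ago2_dep_fraction
  zga <- cluster %in% c("II", "III") & runif(n) < cfg$zga_dep_fraction

  # knockdown series: stabilised genes keep the pre-decay level
  kd_2c <- ifelse(ago2_12, e_mii, e_2c)
  kd_4c <- ifelse(ago2_24, e_2c, e_4c)
  drb_4c <- ifelse(zga, e_2c, e_4c)

  noisy <- function(...) {
    e <- cbind(...)
    e <- e + matrix(stats::rnorm(length(e), sd = cfg$noise_sd), nrow(e))
    pmax(2^e - 1, 0)
  }
  ctrl <- noisy(MII = e_mii, `2C` = e_2c, `4C` = e_4c)
  kd <- noisy(`2C` = kd_2c, `4C` = kd_4c)
  drb <- noisy(`4C` = drb_4c)
  rownames(ctrl) <- rownames(kd) <- rownames(drb) <- ids
  list(control = stage_matrix(ctrl, "control"),
       kd = stage_matrix(kd, "knockdown"),
       drb = stage_matrix(drb, "DRB"),
       truth = data.frame(gene_id = ids, cluster = cluster,
                          ago2_dependent_MII_2C = ago2_12,
                          ago2_dependent_2C_4C = ago2_24,
                          zga_dependent = zga,
                          stringsAsFactors = FALSE))
}

#' Generate sequences, small-RNA pools, lncRNAs and a toy genome
#'
#' Emits random transcripts; a small-RNA pool whose planted guides are
#' exact/1-mismatch/2-mismatch reverse complements of transcript
#' windows (plus random decoys); microRNAs with planted exact seed
#' sites; lncRNAs carrying planted complementary blocks whose coverages
#' straddle the screen threshold (plus scrambled decoys); and a toy
#' genome with gene models whose 1-kb upstream windows contain planted
#' saRNA matches at configured offsets, 70% of them in the 200-400 bp
#' band by default.  Every planting is recorded in truth tables, and
#' planted/decoy sequences are rejection-sampled so that the truth
#' tables are exact: decoys have no chance placements and planted
#' guides have exactly their planted placements.
#'
#' @param cfg a [synth_config()].
#' @return list: `transcripts`, `smallrnas` (with a `class` column:
#'   endosiRNA guide / decoy / saRNA), `mirnas`, `lncrnas`,
#'   `lnc_loci`, `genome`, `gene_models`, and `truth` (list of
#'   `smallrna_targets`, `mirna_targets`, `cmr`, `sarna`, `contexts`,
#'   `zga_genes`).
#' @export
gen_sequences <- function(cfg) {
  set.seed(component_seed(cfg$seed, 2L))
  bases <- c("A", "C", "G", "T")

  ## --- transcripts, with planted microRNA seed sites -------------------
  tx_ids <- sprintf("G%05d", seq_len(cfg$n_transcripts))
  tx <- vapply(seq_len(cfg$n_transcripts), function(i)
    rand_seq(cfg$transcript_len), character(1))
  names(tx) <- tx_ids

  n_mir_planted <- round(cfg$n_mirnas * cfg$mirna_planted_fraction)
  mir_ids <- sprintf("MIR%04d", seq_len(cfg$n_mirnas))
  mirnas <- vapply(seq_len(cfg$n_mirnas), function(i) rand_seq(22L),
                   character(1))
  names(mirnas) <- mir_ids
  mir_truth <- NULL
  if (n_mir_planted > 0L) {
    host <- sample(cfg$n_transcripts, n_mir_planted, replace = TRUE)
    for (i in seq_len(n_mir_planted)) {
      site <- revcomp(substr(mirnas[[i]], 2L, 8L))
      pos <- sample(cfg$transcript_len - 7L, 1L)
      substr(tx[host[i]], pos, pos + 6L) <- site
    }
    mir_truth <- data.frame(mirna_id = mir_ids[seq_len(n_mir_planted)],
                            transcript_id = tx_ids[host],
                            stringsAsFactors = FALSE)
  }

  ## --- small-RNA pool: planted antisense guides + clean decoys ---------
  n_guides <- round(cfg$n_smallrnas * cfg$planted_antisense_fraction)
  n_decoys <- cfg$n_smallrnas - n_guides
  placements <- function(s, v = 2L) {
    a <- cpp_scan_hits(unname(tx), revcomp(s), v)
    b <- cpp_scan_hits(unname(tx), s, v)
    data.frame(transcript = c(a$subject, b$subject),
               start = c(a$start, b$start),
               orientation = rep(c("antisense", "sense"),
                                 c(length(a$start), length(b$start))),
               mismatches = c(a$mismatches, b$mismatches))
  }
  guide_seq <- character(n_guides)
  guide_tx <- integer(n_guides); guide_start <- integer(n_guides)
  guide_mm <- integer(n_guides)
  mm_choices <- as.integer(names(cfg$mismatch_probs))
  for (i in seq_len(n_guides)) {
    repeat {
      len <- sample(cfg$guide_len_range[1L]:cfg$guide_len_range[2L], 1L)
      j <- sample(cfg$n_transcripts, 1L)
      s0 <- sample(cfg$transcript_len - len + 1L, 1L) - 1L
      nm <- sample(mm_choices, 1L, prob = cfg$mismatch_probs)
      g <- mutate_bases(revcomp(substr(tx[[j]], s0 + 1L, s0 + len)), nm)
      pl <- placements(g)
      # accept only when the guide's placements are exactly the planted
      # antisense hit, so the recorded truth map is exact
      if (nrow(pl) == 1L && pl$transcript == j && pl$start == s0 &&
          pl$orientation == "antisense" && pl$mismatches == nm) break
    }
    guide_seq[i] <- g; guide_tx[i] <- j; guide_start[i] <- s0
    guide_mm[i] <- nm
  }
  decoy_seq <- character(n_decoys)
  for (i in seq_len(n_decoys)) {
    repeat {
      s <- rand_seq(sample(cfg$guide_len_range[1L]:cfg$guide_len_range[2L], 1L))
      if (nrow(placements(s)) == 0L) break
    }
    decoy_seq[i] <- s
  }

  ## --- lncRNAs with planted complementary blocks -----------------------
  n_cmr <- round(cfg$n_lncrnas * cfg$cmr_planted_fraction)
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lncrnas + cfg$n_scrambled))
  lnc_seq <- character(cfg$n_lncrnas + cfg$n_scrambled)
  cmr_truth <- data.frame(lncrna_id = character(), mrna_id = character(),
                          true_coverage = numeric(), planted = logical(),
                          stringsAsFactors = FALSE)
  anti_diag <- function(rc_block_region, mrna, diag_off) {
    # redraw region bases so nothing matches the mRNA on the planted
    # diagonal: keeps the planted coverage exact
    ch <- strsplit(rc_block_region, "", fixed = TRUE)[[1L]]
    for (q in seq_along(ch)) {
      mpos <- q + diag_off
      if (mpos >= 1L && mpos <= nchar(mrna)) {
        forbid <- substr(mrna, mpos, mpos)
        ch[q] <- sample(setdiff(bases, forbid), 1L)
      }
    }
    paste(ch, collapse = "")
  }
  for (i in seq_len(cfg$n_lncrnas)) {
    L <- cfg$lncrna_len
    if (i <= n_cmr) {
      cov <- cfg$cmr_coverages[(i - 1L) %% length(cfg$cmr_coverages) + 1L]
      blk <- round(cov * L)
      j <- sample(cfg$n_transcripts, 1L)
      ms <- sample(cfg$transcript_len - blk + 1L, 1L) - 1L
      # build in reverse-complement space: planted block + off-diagonal
      # padding that cannot extend the block
      pad_len <- L - blk
      pad_left <- sample(0:pad_len, 1L)
      pad_right <- pad_len - pad_left
      block <- substr(tx[[j]], ms + 1L, ms + blk)
      left <- if (pad_left)
        anti_diag(rand_seq(pad_left), tx[[j]], ms - pad_left) else ""
      right <- if (pad_right)
        anti_diag(rand_seq(pad_right), tx[[j]], ms + blk) else ""
      rc_lnc <- paste0(left, block, right)
      lnc_seq[i] <- revcomp(rc_lnc)
      cmr_truth <- rbind(cmr_truth,
                         data.frame(lncrna_id = lnc_ids[i], mrna_id = tx_ids[j],
                                    true_coverage = blk / L, planted = TRUE,
                                    stringsAsFactors = FALSE))
    } else {
      lnc_seq[i] <- rand_seq(L)
    }
  }
  for (i in seq_len(cfg$n_scrambled)) {
    src <- lnc_seq[(i - 1L) %% max(1L, n_cmr) + 1L]
    lnc_seq[cfg$n_lncrnas + i] <-
      paste(sample(strsplit(src, "", fixed = TRUE)[[1L]]), collapse = "")
  }
  names(lnc_seq) <- lnc_ids
  scrambled_ids <- lnc_ids[cfg$n_lncrnas + seq_len(cfg$n_scrambled)]

  ## --- toy genome, gene models, planted saRNAs and lncRNA loci ---------
  gap <- 500L; gene_len <- 2000L
  unit <- gap + cfg$promoter_window + gene_len
  zga_ids <- sprintf("ZGA%04d", seq_len(cfg$n_zga_genes))
  strand <- sample(c("+", "-"), cfg$n_zga_genes, replace = TRUE)
  gstart <- integer(cfg$n_zga_genes); gend <- integer(cfg$n_zga_genes)
  cursor <- 0L
  for (i in seq_len(cfg$n_zga_genes)) {
    if (strand[i] == "+") gstart[i] <- cursor + gap + cfg$promoter_window
    else gstart[i] <- cursor + gap
    gend[i] <- gstart[i] + gene_len
    cursor <- cursor + unit
  }
  chrom_len <- cursor + gap
  chrom <- rand_seq(chrom_len)
  # gene structure: UTR exon (300) / intron (500) / CDS exon (400) /
  # intron (500) / UTR exon (300); sense-strand layout is sufficient for
  # majority-context labelling
  exon_off <- rbind(c(0L, 300L), c(800L, 1200L), c(1700L, 2000L))
  cds_off <- rbind(c(800L, 1200L))
  gm <- gene_models(data.frame(
    gene_id = zga_ids, chrom = "chr1", strand = strand,
    start = gstart, end = gend, stringsAsFactors = FALSE,
    exons = I(lapply(seq_len(cfg$n_zga_genes),
                     function(i) exon_off + gstart[i])),
    cds = I(lapply(seq_len(cfg$n_zga_genes),
                   function(i) cds_off + gstart[i]))))

  # planted saRNAs written into promoter windows
  sarna_ids <- sprintf("SAR%04d", seq_len(cfg$n_sarnas))
  sarna_seq <- character(cfg$n_sarnas)
  sarna_gene <- sample(cfg$n_zga_genes, cfg$n_sarnas, replace = TRUE)
  in_band <- runif(cfg$n_sarnas) < cfg$sarna_band_fraction
  sarna_off <- integer(cfg$n_sarnas)
  w <- cfg$promoter_window
  occupied <- vector("list", cfg$n_zga_genes)  # claimed window intervals
  for (i in seq_len(cfg$n_sarnas)) {
    gi <- sarna_gene[i]
    repeat {
      len <- sample(20:24, 1L)
      off <- if (in_band[i])
        sample(cfg$sarna_band[1L]:(cfg$sarna_band[2L] - 1L), 1L)
      else sample(setdiff(1:(w - len + 1L),
                          cfg$sarna_band[1L]:(cfg$sarna_band[2L] - 1L)), 1L)
      p2 <- w - off + 1L; p1 <- p2 - len + 1L   # window positions covered
      occ <- occupied[[gi]]
      clash <- !is.null(occ) && any(p1 <= occ[, 2L] & p2 >= occ[, 1L])
      if (!clash) break
    }
    occupied[[gi]] <- rbind(occupied[[gi]], c(p1, p2))
    seqi <- rand_seq(len)
    tss <- gm$tss[gi]
    if (strand[gi] == "+") {
      g1 <- tss - w + p1 - 1L                 # 0-based genomic start
      substr(chrom, g1 + 1L, g1 + len) <- seqi
    } else {
      g1 <- tss + w - p2 + 1L
      substr(chrom, g1 + 1L, g1 + len) <- revcomp(seqi)
    }
    sarna_seq[i] <- seqi; sarna_off[i] <- off
  }
  sarna_truth <- data.frame(smallrna_id = sarna_ids,
                            gene_id = zga_ids[sarna_gene],
                            offset_upstream = sarna_off,
                            in_band = in_band, stringsAsFactors = FALSE)

  # planted lncRNA loci with controlled feature context
  ctx_counts <- round(cfg$context_fractions * cfg$n_lnc_loci)
  ctx_counts[1L] <- cfg$n_lnc_loci - sum(ctx_counts[-1L])
  ctx <- rep(names(ctx_counts), ctx_counts)
  loci_len <- 200L
  host <- sample(cfg$n_zga_genes, cfg$n_lnc_loci, replace = TRUE)
  lstart <- integer(cfg$n_lnc_loci)
  for (i in seq_len(cfg$n_lnc_loci)) {
    g0 <- gstart[host[i]]
    lstart[i] <- switch(ctx[i],
      intron = g0 + 300L + sample(500L - loci_len, 1L) - 1L,
      coding_exon = g0 + 800L + sample(400L - loci_len, 1L) - 1L,
      UTR_exon = g0 + sample(300L - loci_len, 1L) - 1L,
      intergenic = ((host[i] - 1L) * unit) + sample(gap - loci_len, 1L) - 1L)
  }
  lnc_loci <- data.frame(
    lncrna_id = lnc_ids[seq_len(cfg$n_lnc_loci)],
    chrom = "chr1", start = lstart, end = lstart + loci_len,
    stringsAsFactors = FALSE)
  ctx_truth <- data.frame(lncrna_id = lnc_loci$lncrna_id,
                          context = ctx, stringsAsFactors = FALSE)

  ## --- per-stage RPM abundances ----------------------------------------
  rpm_stages <- c("MII", "zygote", "2C", "4C", "8C")
  profile <- function(n, means) {
    m <- matrix(stats::rlnorm(n * length(means), log(means), 0.4),
                n, byrow = TRUE)
    colnames(m) <- rpm_stages
    m
  }
  guide_rpm <- profile(n_guides, c(8, 25, 30, 4, 1))       # early peak
  decoy_rpm <- profile(n_decoys, c(2, 2, 2, 2, 2))
  sarna_rpm <- profile(cfg$n_sarnas, c(1.5, 12, 15, 3, 1)) # zygote/2C high
  # keep planted saRNAs above the RPM screen threshold
  sarna_rpm[, "zygote"] <- pmax(sarna_rpm[, "zygote"], 1.5)
  smallrnas <- data.frame(
    id = c(sprintf("ESI%05d", seq_len(n_guides)),
           sprintf("DEC%05d", seq_len(n_decoys)), sarna_ids),
    sequence = c(guide_seq, decoy_seq, sarna_seq),
    class = rep(c("endosiRNA", "decoy", "saRNA"),
                c(n_guides, n_decoys, cfg$n_sarnas)),
    rbind(guide_rpm, decoy_rpm, sarna_rpm),
    check.names = FALSE, stringsAsFactors = FALSE)

  smallrna_truth <- data.frame(
    smallrna_id = sprintf("ESI%05d", seq_len(n_guides)),
    transcript_id = tx_ids[guide_tx],
    start = guide_start, mismatches = guide_mm,
    stringsAsFactors = FALSE)

  list(transcripts = tx,
       smallrnas = smallrnas,
       mirnas = mirnas,
       lncrnas = lnc_seq,
       lnc_loci = lnc_loci,
       genome = c(chr1 = chrom),
       gene_models = gm,
       truth = list(smallrna_targets = smallrna_truth,
                    mirna_targets = mir_truth,
                    cmr = cmr_truth,
                    scrambled_ids = scrambled_ids,
                    sarna = sarna_truth,
                    contexts = ctx_truth,
                    zga_genes = zga_ids))
}

#' Generate decay time courses with known rate constants
#'
#' First-order decay `N(t) = exp(-k t)` per condition with
#' multiplicative log-normal noise at the configured CV, renormalised
#' to 1 at t = 0; the true k per condition is recorded.
#'
#' @param cfg a [synth_config()].
#' @return list: `courses` (list of [decay_timecourse()]s) and
#'   `truth` (data.frame of condition, replicate, true k).
#' @export
gen_timecourses <- function(cfg) {
  set.seed(component_seed(cfg$seed, 3L))
  ks <- c(control = cfg$k_control,
          mimic = cfg$k_control * cfg$k_mimic_factor,
          inhibitor = cfg$k_control * cfg$k_inhibitor_factor)
  sdlog <- sqrt(log(1 + cfg$kinetics_cv^2))
  courses <- list()
  truth <- list()
  for (cond in names(ks)) {
    for (r in seq_len(cfg$n_replicates)) {
      ab <- exp(-ks[[cond]] * cfg$timepoints) *
        stats::rlnorm(length(cfg$timepoints), 0, sdlog)
      courses[[length(courses) + 1L]] <-
        decay_timecourse(cfg$timepoints, ab,
                         gene_id = sprintf("%s_rep%03d", cond, r),
                         condition = cond)
      truth[[length(truth) + 1L]] <-
        data.frame(condition = cond, replicate = r, k = ks[[cond]])
    }
  }
  list(courses = courses, truth = do.call(rbind, truth))
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits every component as plain-text files (TSV, FASTA, GFF3) that
#' round-trip through the package readers, plus truth tables, so a full
#' pipeline run needs nothing but this directory.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; side effect: files written.
#' @export
write_synthetic_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  ex <- gen_expression(cfg)
  write_expression_table(ex$control, p("expression_control.tsv"))
  write_expression_table(ex$kd, p("expression_kd.tsv"))
  write_expression_table(ex$drb, p("expression_drb.tsv"))
  write_tsv_output(ex$truth, p("truth_expression.tsv"),
                   params = list(seed = cfg$seed))
  sq <- gen_sequences(cfg)
  write_fasta(sq$transcripts, p("transcripts.fa"))
  write_fasta(sq$mirnas, p("mirnas.fa"))
  write_fasta(sq$lncrnas, p("lncrnas.fa"))
  write_fasta(sq$genome, p("genome.fa"))
  write_gene_models(sq$gene_models, p("genes.gff3"))
  write.table(sq$smallrnas, p("smallrnas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sq$lnc_loci, p("lnc_loci.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_tsv_output(sq$truth$smallrna_targets, p("truth_smallrna_targets.tsv"))
  write_tsv_output(sq$truth$cmr, p("truth_cmr.tsv"))
  write_tsv_output(sq$truth$sarna, p("truth_sarna.tsv"))
  write_tsv_output(sq$truth$contexts, p("truth_contexts.tsv"))
  writeLines(sq$truth$zga_genes, p("zga_genes.txt"))
  tc <- gen_timecourses(cfg)
  tc_df <- do.call(rbind, tc$courses)
  write.table(tc_df, p("timecourses.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_tsv_output(tc$truth, p("truth_kinetics.tsv"))
  invisible(dir)
}
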