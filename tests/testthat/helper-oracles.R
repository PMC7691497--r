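# Shared fixtures and independent oracles used across the suite.

rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

rc <- function(s) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(s)))

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# Independent matcher oracle built on Biostrings pattern matching: all
# fully-contained windows at Hamming distance <= v, both orientations,
# with the same multimap-cap semantics as the matcher under test.
oracle_find_hits <- function(query, transcripts, v = 2L, m = 20L,
                             subj = Biostrings::DNAStringSet(transcripts)) {
  one_orientation <- function(pat, orient) {
    mi <- Biostrings::vmatchPattern(pat, subj, max.mismatch = v,
                                    with.indels = FALSE, fixed = TRUE)
    lens <- S4Vectors::elementNROWS(mi)
    if (sum(lens) == 0L)
      return(data.frame(transcript_id = character(), start = integer(),
                        orientation = character(), mismatches = integer(),
                        stringsAsFactors = FALSE))
    idx <- rep(seq_along(subj), lens)
    r <- unlist(mi, use.names = FALSE)
    ok <- IRanges::start(r) >= 1L & IRanges::end(r) <= nchar(transcripts)[idx]
    idx <- idx[ok]; r <- r[ok]
    mm <- mapply(function(i, s) hamming(substr(transcripts[[i]], s,
                                               s + nchar(pat) - 1L), pat),
                 idx, IRanges::start(r))
    data.frame(transcript_id = names(transcripts)[idx],
               start = IRanges::start(r) - 1L,
               orientation = orient,
               mismatches = as.integer(mm),
               stringsAsFactors = FALSE)
  }
  hits <- rbind(one_orientation(rc(query), "antisense"),
                one_orientation(query, "sense"))
  if (is.finite(m) && nrow(hits) > m) {
    out <- hits[0L, ]
    attr(out, "suppressed") <- TRUE
    return(out)
  }
  out <- hits[order(hits$transcript_id, hits$start, hits$orientation), ,
              drop = FALSE]
  rownames(out) <- NULL
  attr(out, "suppressed") <- FALSE
  out
}

# Same oracle against a single N-separated concatenated subject: N is
# never a match under fixed = TRUE, and hits straddling a separator are
# removed by the full-containment filter, so the hit set is identical
# to the per-transcript oracle while avoiding per-transcript overhead.
oracle_concat <- function(transcripts, sep = 35L) {
  widths <- nchar(transcripts)
  concat <- paste(unname(transcripts),
                  collapse = paste(rep("N", sep), collapse = ""))
  offsets <- cumsum(c(0L, utils::head(widths + sep, -1L)))
  list(x = Biostrings::DNAString(concat), offsets = unname(offsets),
       widths = unname(widths), names = names(transcripts),
       seqs = unname(transcripts))
}

oracle_find_hits_concat <- function(query, cc, v = 2L, m = 20L) {
  one <- function(pat, orient) {
    r <- Biostrings::matchPattern(pat, cc$x, max.mismatch = v,
                                  with.indels = FALSE, fixed = TRUE)
    st <- IRanges::start(r); en <- IRanges::end(r)
    idx <- findInterval(st - 1L, cc$offsets)
    ok <- idx >= 1L & st - 1L >= cc$offsets[idx] &
      en <= cc$offsets[idx] + cc$widths[idx]
    idx <- idx[ok]; st <- st[ok]
    if (!length(idx))
      return(data.frame(transcript_id = character(), start = integer(),
                        orientation = character(), mismatches = integer(),
                        stringsAsFactors = FALSE))
    loc <- st - 1L - cc$offsets[idx]
    mm <- mapply(function(i, s) hamming(substr(cc$seqs[i], s + 1L,
                                               s + nchar(pat)), pat),
                 idx, loc)
    data.frame(transcript_id = cc$names[idx], start = loc,
               orientation = orient, mismatches = as.integer(mm),
               stringsAsFactors = FALSE)
  }
  hits <- rbind(one(rc(query), "antisense"), one(query, "sense"))
  if (is.finite(m) && nrow(hits) > m) {
    out <- hits[0L, ]
    attr(out, "suppressed") <- TRUE
    return(out)
  }
  out <- hits[order(hits$transcript_id, hits$start, hits$orientation), ,
              drop = FALSE]
  rownames(out) <- NULL
  attr(out, "suppressed") <- FALSE
  out
}

# Brute-force six-frame ORF oracle: walk codons from every ATG.
oracle_longest_orf <- function(seq) {
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (s in c(seq, rc(seq))) {
    n <- nchar(s)
    for (start in seq_len(max(0L, n - 2L))) {
      if (substr(s, start, start + 2L) != "ATG") next
      pos <- start
      codons <- 0L
      while (pos + 2L <= n) {
        if (substr(s, pos, pos + 2L) %in% stops && pos > start) {
          best <- max(best, codons)
          break
        }
        codons <- codons + 1L
        pos <- pos + 3L
      }
    }
  }
  best
}

# strip matcher attributes so data frames compare cleanly
hit_frame <- function(h) {
  h <- as.data.frame(h)[c("transcript_id", "start", "orientation",
                          "mismatches")]
  rownames(h) <- NULL
  h
}

# small synthetic dataset reused by several test files (generated once)
.small_synth <- new.env()
small_synth <- function() {
  if (is.null(.small_synth$sq)) {
    cfg <- synth_config(seed = 101, n_genes = 200, n_transcripts = 50,
                        n_smallrnas = 300, n_lncrnas = 40, n_scrambled = 20,
                        n_zga_genes = 50, n_sarnas = 30, n_lnc_loci = 20,
                        n_replicates = 10)
    .small_synth$cfg <- cfg
    .small_synth$sq <- gen_sequences(cfg)
    .small_synth$ex <- gen_expression(cfg)
  }
  .small_synth
}
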