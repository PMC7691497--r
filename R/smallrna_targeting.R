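#' Find all mismatch-bounded ungapped alignments of a small RNA
#'
#' Native reimplementation of the short-read screen used to map
#' endosiRNAs onto maternal mRNAs: every ungapped placement of the
#' query on every transcript, in both orientations, with Hamming
#' distance at most `v` is enumerated (report-all semantics), and a
#' query whose total placement count exceeds the multimap cap `m` is
#' suppressed entirely -- no hits are reported and the suppression is
#' flagged.  "Antisense" means the reverse complement of the query
#' equals the transcript window up to `v` mismatches; `N` never matches
#' anything, including `N`.
#'
#' @param query character scalar (the small-RNA sequence, DNA alphabet)
#'   or a one-row small-RNA record with a `sequence` column.
#' @param transcripts named character vector or `DNAStringSet` of
#'   transcript sequences.
#' @param v maximum mismatches per placement (default 2).
#' @param m multimap cap: total placements (both orientations) above
#'   which the query is suppressed (default 20; `Inf` disables).
#' @return data.frame with columns `smallrna_id`, `transcript_id`,
#'   `start` (0-based on the transcript), `orientation`
#'   (`antisense`/`sense`), `mismatches`, sorted by
#'   (transcript_id, start, orientation).  Attribute `suppressed` is
#'   `TRUE` (and the frame empty) when the cap was exceeded;
#'   `n_placements` records the pre-suppression count.
#' @export
find_hits <- function(query, transcripts, v = 2L, m = 20L) {
  id <- NA_character_
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    id <- query$id
    query <- query$sequence
  }
  query <- toupper(chartr("Uu", "Tt", query))
  if (nchar(query) < 1L) stop("query must be non-empty")
  if (grepl("[^ACGTN]", query))
    stop("query contains characters outside {A,C,G,T,N}")
  if (v < 0L) stop("v must be >= 0")
  if (is.finite(m) && m < 1L) stop("m must be >= 1")
  subj <- as_named_chr(transcripts)
  tid <- names(subj)
  if (is.null(tid)) stop("transcripts must be named")

  sense <- cpp_scan_hits(subj, query, as.integer(v))
  anti <- cpp_scan_hits(subj, revcomp(query), as.integer(v))
  n_all <- length(anti$start) + length(sense$start)
  hits <- data.frame(
    smallrna_id = rep(id, n_all),
    transcript_id = c(tid[anti$subject], tid[sense$subject]),
    start = c(anti$start, sense$start),
    orientation = rep(c("antisense", "sense"),
                      c(length(anti$start), length(sense$start))),
    mismatches = c(anti$mismatches, sense$mismatches),
    stringsAsFactors = FALSE)
  n <- nrow(hits)
  if (is.finite(m) && n > m) {
    out <- hits[0L, ]
    attr(out, "suppressed") <- TRUE
    attr(out, "n_placements") <- n
    return(out)
  }
  out <- hits[order(hits$transcript_id, hits$start, hits$orientation), ,
              drop = FALSE]
  rownames(out) <- NULL
  attr(out, "suppressed") <- FALSE
  attr(out, "n_placements") <- n
  out
}

#' Map a small-RNA pool onto maternal transcripts
#'
#' Runs [find_hits()] for every small RNA against the maternal subset of
#' the transcript set and inverts the non-suppressed antisense hits into
#' a transcript -> small-RNA-id index.  Sense placements still count
#' toward each query's multimap cap but are not targeting evidence
#' unless `antisense_only = FALSE`.
#'
#' @param smallrnas data.frame with `id` and `sequence` columns (e.g.
#'   [read_smallrna_table()] output).
#' @param transcripts named sequences.
#' @param maternal_set transcript ids to screen (others are dropped).
#' @param v,m as in [find_hits()].
#' @param antisense_only count only antisense placements as targeting
#'   evidence (default `TRUE`).
#' @return named list mapping transcript_id to a character vector of
#'   targeting small-RNA ids; attributes `n_suppressed` (queries
#'   discarded by the multimap cap), `hits` (the full hit table) and
#'   `targeting_ids` (unique small RNAs with >= 1 reported hit).
#' @export
target_table <- function(smallrnas, transcripts, maternal_set = NULL,
                         v = 2L, m = 20L, antisense_only = TRUE) {
  subj <- as_named_chr(transcripts)
  if (!is.null(maternal_set)) subj <- subj[names(subj) %in% maternal_set]
  hit_list <- vector("list", nrow(smallrnas))
  n_suppressed <- 0L
  for (i in seq_len(nrow(smallrnas))) {
    h <- find_hits(smallrnas[i, , drop = FALSE], subj, v = v, m = m)
    if (isTRUE(attr(h, "suppressed"))) {
      n_suppressed <- n_suppressed + 1L
    } else if (nrow(h)) {
      hit_list[[i]] <- h
    }
  }
  hits <- do.call(rbind, hit_list)
  if (is.null(hits))
    hits <- data.frame(smallrna_id = character(), transcript_id = character(),
                       start = integer(), orientation = character(),
                       mismatches = integer(), stringsAsFactors = FALSE)
  evidence <- if (antisense_only)
    hits[hits$orientation == "antisense", , drop = FALSE] else hits
  map <- lapply(split(evidence$smallrna_id, evidence$transcript_id),
                function(x) sort(unique(x)))
  attr(map, "n_suppressed") <- n_suppressed
  attr(map, "hits") <- hits
  attr(map, "targeting_ids") <- sort(unique(evidence$smallrna_id))
  map
}

#' microRNA seed-match targets (declared stand-in)
#'
#' A deliberately simple seed-complementarity rule standing in for
#' external microRNA target scoring so the microRNA-versus-endosiRNA
#' comparison can run offline: a transcript is a target iff it contains
#' an exact occurrence of the reverse complement of the microRNA seed
#' (positions 2-8, 1-based, on the microRNA).  This does NOT reproduce
#' database target scores.
#'
#' @param mirnas data.frame with `id` and `sequence`, or named character
#'   vector of microRNA sequences.
#' @param transcripts named sequences.
#' @param seed_span 1-based inclusive seed positions on the microRNA
#'   (default `c(2, 8)`).
#' @return named list mapping transcript_id to targeting microRNA ids.
#' @export
mirna_seed_targets <- function(mirnas, transcripts, seed_span = c(2L, 8L)) {
  if (is.data.frame(mirnas)) mirnas <- setNames(mirnas$sequence, mirnas$id)
  mirnas <- toupper(chartr("Uu", "Tt", mirnas))
  if (any(nchar(mirnas) < seed_span[2L]))
    stop("seed_span outside microRNA length")
  subj <- Biostrings::DNAStringSet(as_named_chr(transcripts))
  tid <- names(subj)
  pairs <- lapply(seq_along(mirnas), function(i) {
    seed <- substr(mirnas[[i]], seed_span[1L], seed_span[2L])
    site <- revcomp(seed)
    n <- Biostrings::vcountPattern(site, subj, fixed = TRUE)
    if (any(n > 0))
      data.frame(transcript_id = tid[n > 0], mirna_id = names(mirnas)[i],
                 stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(structure(list(), names = character()))
  lapply(split(pairs$mirna_id, pairs$transcript_id),
         function(x) sort(unique(x)))
}

#' Per-stage abundance profile of a set of ids
#'
#' Mean and standard deviation per stage across the given ids, for
#' comparing e.g. declining maternal targets with peaked endosiRNA
#' pools.  Works on a small-RNA RPM table (columns per stage) or a
#' [stage_matrix()].
#'
#' @param ids character vector (non-empty).
#' @param abundance small-RNA data.frame with an `id` column and stage
#'   columns, or a `stage_matrix`.
#' @param stage_columns stage columns to summarise (default: all stages
#'   present).
#' @return data.frame with `stage`, `mean`, `sd`, `n`.
#' @export
stage_profile <- function(ids, abundance, stage_columns = NULL) {
  if (length(ids) == 0L) stop("empty id set")
  if (inherits(abundance, "stage_matrix")) {
    if (is.null(stage_columns)) stage_columns <- colnames(abundance)
    known <- ids %in% rownames(abundance)
    if (any(!known)) warning(sum(!known), " unknown id(s) skipped")
    vals <- unclass(abundance)[ids[known], stage_columns, drop = FALSE]
  } else {
    if (is.null(stage_columns))
      stage_columns <- setdiff(names(abundance), c("id", "sequence"))
    known <- ids %in% abundance$id
    if (any(!known)) warning(sum(!known), " unknown id(s) skipped")
    rows <- abundance[match(ids[known], abundance$id), , drop = FALSE]
    vals <- as.matrix(rows[stage_columns])
  }
  data.frame(stage = stage_columns,
             mean = colMeans(vals),
             sd = apply(vals, 2L, stats::sd),
             n = nrow(vals),
             row.names = NULL, stringsAsFactors = FALSE)
}
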