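#' @useDynLib mztdecay, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom stats setNames
NULL

# ---------------------------------------------------------------------------
# Stage expression matrices
# ---------------------------------------------------------------------------

#' Construct a stage expression matrix
#'
#' A genes-by-stages matrix of linear-scale FPKM values for one
#' experimental condition (control, knockdown, DRB, ...).  All decay
#' classification downstream operates on `log2(FPKM + pseudocount)`
#' transforms of these matrices; this container stores the linear scale.
#'
#' @param values numeric matrix, rows = genes (rownames are gene ids),
#'   columns = ordered developmental stages (colnames are stage names).
#' @param condition character scalar labelling the series.
#' @return an object of class `stage_matrix`.
#' @export
stage_matrix <- function(values, condition = "control") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("values must carry gene ids as rownames")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values)))
    stop("values must carry stage names as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)) || any(!nzchar(colnames(values))))
    stop("stage names must be unique and non-empty")
  if (anyNA(values) || any(values < 0))
    stop("FPKM values must be non-negative and non-missing")
  structure(values, condition = condition, class = c("stage_matrix", "matrix"))
}

#' @export
print.stage_matrix <- function(x, ...) {
  cat(sprintf("stage_matrix: %d genes x %d stages (%s), condition = %s\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", "),
              attr(x, "condition")))
  invisible(x)
}

#' Stages of a stage matrix
#' @param x a `stage_matrix`
#' @return character vector of stage names
#' @export
stages <- function(x) colnames(x)

#' Read an expression table
#'
#' Reads a TSV with a header row, one row per gene, a gene-id column and
#' one numeric column per stage.  Lines starting with `#` are treated as
#' comments.
#'
#' @param path TSV path.
#' @param stage_columns character vector naming the stage columns, in
#'   developmental order.
#' @param id_column name of the gene-id column (default `"gene_id"`).
#' @param condition condition label stored on the result.
#' @return a [stage_matrix()].
#' @export
read_expression_table <- function(path, stage_columns,
                                  id_column = "gene_id",
                                  condition = "control") {
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
               check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("no records in ", path))
  if (nrow(df) == 0L) stop("no records in ", path)
  missing_cols <- setdiff(c(id_column, stage_columns), names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  ids <- as.character(df[[id_column]])
  if (anyDuplicated(ids))
    stop("duplicate gene id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[stage_columns])
  if (!is.numeric(vals)) {
    bad <- which(apply(df[stage_columns], 1L,
                       function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop("non-numeric stage value(s) at row(s): ",
         paste(bad, collapse = ", "))
  }
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)
    stop("non-numeric stage value(s) at row(s): ", paste(bad, collapse = ", "))
  }
  rownames(vals) <- ids
  stage_matrix(vals, condition = condition)
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]: full-precision TSV round-trip.
#'
#' @param x a `stage_matrix`.
#' @param path output path.
#' @param id_column gene-id column name.
#' @export
write_expression_table <- function(x, path, id_column = "gene_id") {
  df <- data.frame(rownames(x), as.data.frame.matrix(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(x))
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sequence sets
# ---------------------------------------------------------------------------

#' Read a FASTA file into a validated sequence set
#'
#' Sequences are upper-cased and U is normalised to T at parse time, so
#' RNA (small-RNA mimics, lncRNAs) and DNA (genome, transcript models)
#' inputs share one alphabet.  Ids are taken up to the first whitespace.
#'
#' @param path FASTA path.
#' @param kind one of `"transcript"`, `"lncRNA"`, `"smallRNA"`,
#'   `"promoter"`, `"genome"`; stored as metadata.
#' @return a [Biostrings::DNAStringSet] with a `kind` metadata entry.
#' @export
read_fasta <- function(path, kind = c("transcript", "lncRNA", "smallRNA",
                                      "promoter", "genome")) {
  kind <- match.arg(kind)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("u", "t", tolower(as.character(ss)))
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) stop("empty sequence: ", ids[!nzchar(seqs)][1L])
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequence with characters outside {A,C,G,T,U,N}: ",
         ids[grepl("[^ACGTN]", seqs)][1L])
  out <- Biostrings::DNAStringSet(setNames(seqs, ids))
  S4Vectors::metadata(out)$kind <- kind
  out
}

#' Write a sequence set as FASTA
#' @param x a `DNAStringSet` (or named character vector).
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "XStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models
# ---------------------------------------------------------------------------

#' Construct a gene-model table
#'
#' Internal coordinates are 0-based half-open throughout the package;
#' conversion to/from 1-based closed GFF3 happens only at the
#' parse/serialise boundary.  The TSS is the span start on the `+`
#' strand and `end - 1` on the `-` strand.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end` (0-based half-open span) and optional
#'   list-columns `exons` and `cds` (two-column matrices of 0-based
#'   half-open intervals per gene).
#' @return a `gene_models` data.frame with a derived `tss` column.
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(df)))
    stop("gene model table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id in gene models")
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  if (any(df$end <= df$start)) stop("empty or inverted gene span")
  if (is.null(df$exons))
    df$exons <- lapply(seq_len(nrow(df)),
                       function(i) cbind(df$start[i], df$end[i]))
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    if (is.null(ex) || nrow(ex) == 0L) next
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (any(ex[, 1L] < df$start[i] | ex[, 2L] > df$end[i]))
      stop("exon outside gene span for ", df$gene_id[i])
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
      stop("overlapping exons for ", df$gene_id[i])
    df$exons[[i]] <- ex
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 (1-based closed) and BED (0-based half-open) are both unified
#' to the internal 0-based half-open convention.  GFF3 `exon` and `CDS`
#' children are attached to their parent gene; BED carries spans only
#' (one exon per gene).
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @return a [gene_models()] table.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(bed) < 6L) stop("BED file needs >= 6 columns (strand required)")
    df <- data.frame(gene_id = as.character(bed[[4L]]),
                     chrom = as.character(bed[[1L]]),
                     strand = as.character(bed[[6L]]),
                     start = as.integer(bed[[2L]]),
                     end = as.integer(bed[[3L]]),
                     stringsAsFactors = FALSE)
    return(gene_models(df))
  }
  gff <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "source", "type", "start", "end",
                                  "score", "strand", "phase", "attr"))
  get_attr <- function(attr, key) {
    pat <- paste0("(?:^|;)", key, "=([^;]+)")
    hit <- regexpr(pat, attr, perl = TRUE)
    out <- rep(NA_character_, length(attr))
    ok <- hit > 0
    out[ok] <- sub(pat, "\\1", regmatches(attr, hit), perl = TRUE)
    out
  }
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene features in ", path)
  gid <- get_attr(genes$attr, "ID")
  if (anyNA(gid)) stop("gene feature without ID attribute")
  df <- data.frame(gene_id = gid, chrom = genes$chrom, strand = genes$strand,
                   start = as.integer(genes$start) - 1L,
                   end = as.integer(genes$end),
                   stringsAsFactors = FALSE)
  pick_children <- function(type) {
    kids <- gff[gff$type == type, , drop = FALSE]
    if (nrow(kids) == 0L) return(setNames(vector("list", nrow(df)), df$gene_id))
    parent <- get_attr(kids$attr, "Parent")
    lapply(setNames(df$gene_id, df$gene_id), function(g) {
      k <- kids[parent == g, , drop = FALSE]
      if (nrow(k) == 0L) return(NULL)
      cbind(as.integer(k$start) - 1L, as.integer(k$end))
    })
  }
  df$exons <- unname(pick_children("exon"))
  df$exons[vapply(df$exons, is.null, logical(1))] <-
    lapply(which(vapply(df$exons, is.null, logical(1))),
           function(i) cbind(df$start[i], df$end[i]))
  df$cds <- unname(pick_children("CDS"))
  gene_models(df)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()] on the GFF3 route; internal 0-based
#' half-open intervals are serialised back to 1-based closed.
#'
#' @param gm a `gene_models` table.
#' @param path output path.
#' @export
write_gene_models <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(gm))) {
    g <- gm[i, ]
    writeLines(sprintf("%s\tmztdecay\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id), con)
    ex <- gm$exons[[i]]
    if (!is.null(ex))
      for (j in seq_len(nrow(ex)))
        writeLines(sprintf("%s\tmztdecay\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                           g$chrom, ex[j, 1L] + 1L, ex[j, 2L], g$strand,
                           g$gene_id, j, g$gene_id), con)
    cds <- if (!is.null(gm$cds)) gm$cds[[i]] else NULL
    if (!is.null(cds))
      for (j in seq_len(nrow(cds)))
        writeLines(sprintf("%s\tmztdecay\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
                           g$chrom, cds[j, 1L] + 1L, cds[j, 2L], g$strand,
                           g$gene_id, j, g$gene_id), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Small-RNA tables and generic TSV output
# ---------------------------------------------------------------------------

#' Read a small-RNA table
#'
#' TSV with columns `id`, `sequence` and one RPM column per stage.
#' Sequences are U->T normalised and upper-cased like [read_fasta()].
#' Records outside the admissible parse-time length window are rejected.
#'
#' @param path TSV path.
#' @param stage_columns character vector of RPM stage columns.
#' @param min_len,max_len admissible sequence length at parse time
#'   (defaults 15 and 35; the biological 18-30 nt filter is applied
#'   downstream by [filter_sarna_candidates()]).
#' @return data.frame with columns `id`, `sequence` and the stage columns.
#' @export
read_smallrna_table <- function(path, stage_columns, min_len = 15L,
                                max_len = 35L) {
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
               check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("no records in ", path))
  if (nrow(df) == 0L) stop("no records in ", path)
  missing_cols <- setdiff(c("id", "sequence", stage_columns), names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate small-RNA id: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  df$sequence <- toupper(chartr("Uu", "Tt", df$sequence))
  if (any(grepl("[^ACGTN]", df$sequence)))
    stop("sequence with characters outside {A,C,G,T,U,N}")
  len <- nchar(df$sequence)
  if (any(len < min_len | len > max_len))
    stop("small-RNA length outside [", min_len, ", ", max_len, "] for: ",
         paste(df$id[len < min_len | len > max_len][1L]))
  for (s in stage_columns) {
    df[[s]] <- as.numeric(df[[s]])
    if (anyNA(df[[s]]) || any(df[[s]] < 0))
      stop("RPM values must be numeric and non-negative in column ", s)
  }
  df
}

#' Write a TSV with a commented provenance header
#'
#' All pipeline outputs are TSV with `#`-prefixed header lines recording
#' the package version and the parameters of the producing step, so runs
#' are diffable and self-describing.  Floating-point columns are
#' serialised at 6 significant digits.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list of parameters recorded in the header.
#' @export
write_tsv_output <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mztdecay %s", as.character(packageVersion("mztdecay"))),
             con)
  for (nm in names(params))
    writeLines(sprintf("# %s=%s", nm, paste(format(params[[nm]]), collapse = ",")),
               con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6L))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# name-preserving coercion: as.character() drops names on character input
as_named_chr <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  names(x) <- nm
  x
}

# shared helper: reverse complement on plain character vectors
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
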