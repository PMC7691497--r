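#!/usr/bin/env Rscript
# Map the small-RNA pool onto maternal transcripts with the
# mismatch-bounded antisense matcher (report-all, <=2 mismatches,
# multimap cap 20), build the transcript -> endosiRNA target table, the
# microRNA seed stand-in table, and per-stage abundance profiles.

suppressMessages(library(mztdecay))
dir <- "results/synthetic"
out <- "results"
stages <- c("MII", "zygote", "2C", "4C", "8C")

sm <- read_smallrna_table(file.path(dir, "smallrnas.tsv"), stages)
tx <- read_fasta(file.path(dir, "transcripts.fa"), "transcript")
mir <- read_fasta(file.path(dir, "mirnas.fa"), "smallRNA")
pool <- sm[sm$class != "saRNA", , drop = FALSE]

tmap <- target_table(pool, tx, names(tx), v = 2L, m = 20L)
hits <- attr(tmap, "hits")
write_tsv_output(hits, file.path(out, "smallrna_hits.tsv"),
                 params = list(v = 2, m = 20))
counts <- data.frame(transcript_id = names(tmap), n_smallrnas = lengths(tmap))
write_tsv_output(counts, file.path(out, "target_counts.tsv"))

truth <- read.delim(file.path(dir, "truth_smallrna_targets.tsv"),
                    comment.char = "#")
key <- function(d, a, b) paste(d[[a]], d[[b]])
anti <- hits[hits$orientation == "antisense", ]
rec <- mean(key(truth, "smallrna_id", "transcript_id") %in%
              key(anti, "smallrna_id", "transcript_id"))
cat(sprintf("%d antisense hits over %d transcripts; %d queries suppressed\n",
            nrow(anti), length(tmap), attr(tmap, "n_suppressed")))
cat(sprintf("Planted guide recovery: %.1f%% (%d planted)\n",
            100 * rec, nrow(truth)))

mmap <- mirna_seed_targets(as.character(mir), tx)
cat(sprintf("microRNA seed stand-in: %d transcripts with seed sites\n",
            length(mmap)))

prof_tgt <- stage_profile(unique(anti$smallrna_id), sm, stages)
write_tsv_output(prof_tgt, file.path(out, "endosirna_stage_profile.tsv"))
cat("Targeting endosiRNA mean RPM by stage:",
    paste(sprintf("%s=%.1f", prof_tgt$stage, prof_tgt$mean), collapse = ", "),
    "\n")
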