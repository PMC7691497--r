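#!/usr/bin/env Rscript
# Identify candidate saRNAs: filter the expressed 18-30 nt small RNAs
# (RPM > 1 at zygote or 2-cell), scan the 1-kb TSS-upstream windows of
# the ZGA genes, and summarise the positional distribution of hits.

suppressMessages(library(mztdecay))
dir <- "results/synthetic"
out <- "results"

sm <- read_smallrna_table(file.path(dir, "smallrnas.tsv"),
                          c("MII", "zygote", "2C", "4C", "8C"))
gm <- read_gene_models(file.path(dir, "genes.gff3"))
genome <- read_fasta(file.path(dir, "genome.fa"), "genome")
zga <- readLines(file.path(dir, "zga_genes.txt"))

cand <- filter_sarna_candidates(sm)
cat(sprintf("saRNA candidates after length/RPM filter: %d of %d\n",
            nrow(cand), nrow(sm)))

prom <- extract_promoters(gm[gm$gene_id %in% zga, ], genome, window = 1000L)
hits <- scan_promoters(cand, prom, v = 0L, m = 20L)
write_tsv_output(hits, file.path(out, "sarna_hits.tsv"),
                 params = list(window = 1000, v = 0))
write_tsv_output(data.frame(gene_id = names(prom),
                            targeted = names(prom) %in%
                              attr(hits, "targeted_genes")),
                 file.path(out, "sarna_targeted.tsv"))
h <- positional_distribution(hits, bin_bp = 100L, window = 1000L)
write_tsv_output(h, file.path(out, "sarna_histogram.tsv"))

truth <- read.delim(file.path(dir, "truth_sarna.tsv"), comment.char = "#")
key <- function(d) sort(paste(d$smallrna_id, d$gene_id, d$offset_upstream))
cat(sprintf("Promoter hits: %d (planted %d; recovered exactly: %s)\n",
            nrow(hits), nrow(truth),
            identical(key(hits), key(truth))))
cat(sprintf("Targeted ZGA genes: %d/%d (%.1f%%)\n",
            length(attr(hits, "targeted_genes")), length(prom),
            100 * attr(hits, "targeted_fraction")))
cat(sprintf("Histogram mode at %d-%d bp upstream of the TSS\n",
            h$bin_start[which.max(h$count)], h$bin_end[which.max(h$count)]))
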