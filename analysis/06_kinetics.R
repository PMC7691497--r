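#!/usr/bin/env Rscript
# Fit first-order decay to the actinomycin-D time courses, estimate
# half-lives per condition (control / endosiRNA mimic / inhibitor) and
# check the stability ordering; also demonstrates 2^-ddCt relative
# quantification on a worked example.

suppressMessages(library(mztdecay))
dir <- "results/synthetic"
out <- "results"

tc <- read.delim(file.path(dir, "timecourses.tsv"))
fits <- lapply(split(tc, tc$gene_id), function(d) {
  d <- d[order(d$time), ]
  est <- fit_decay(decay_timecourse(d$time, d$abundance,
                                    gene_id = d$gene_id[1L],
                                    condition = d$condition[1L]))
  data.frame(gene_id = d$gene_id[1L], condition = d$condition[1L],
             k = est$k, t_half = est$t_half, r_squared = est$r_squared)
})
fits <- do.call(rbind, fits)
write_tsv_output(fits, file.path(out, "halflife_estimates.tsv"))

med <- tapply(fits$t_half, fits$condition, median)
cat("Median half-life by condition (h):",
    paste(sprintf("%s=%.2f", names(med), med), collapse = ", "), "\n")
truth <- read.delim(file.path(dir, "truth_kinetics.tsv"), comment.char = "#")
true_t <- log(2) / tapply(truth$k, truth$condition, unique)
cat("True half-life by condition (h):",
    paste(sprintf("%s=%.2f", names(true_t), true_t), collapse = ", "), "\n")
ord <- med["mimic"] < med["control"] && med["control"] < med["inhibitor"]
cat(sprintf("Stability ordering mimic < control < inhibitor: %s\n", ord))

rel <- ddct(target_ct = 25, reference_cts = c(20, 22),
            calibrator_delta_ct = 2)
cat(sprintf("Worked 2^-ddCt example (Ct 25 vs refs 20/22, calibrator dCt 2): %.3f\n",
            rel))
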