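#' Classification parameters for maternal decay clustering
#'
#' @param maternal_fpkm_threshold linear-FPKM cutoff defining maternal
#'   mRNAs at the MII stage (strict `>`; default 2).
#' @param log_delta the single log2-unit significance margin (delta)
#'   used by every comparison: decay steps must exceed it, "stable"
#'   means within it, and "increased or stable" under
#'   knockdown/transcription-block means not decreased by more than it.
#' @param pseudocount added to FPKM before the log2 transform.
#' @return a `classification_params` list.
#' @export
classification_params <- function(maternal_fpkm_threshold = 2,
                                  log_delta = 1,
                                  pseudocount = 1) {
  if (maternal_fpkm_threshold <= 0 || log_delta <= 0 || pseudocount <= 0)
    stop("all classification parameters must be strictly positive")
  structure(list(maternal_fpkm_threshold = maternal_fpkm_threshold,
                 log_delta = log_delta,
                 pseudocount = pseudocount),
            class = "classification_params")
}

log2_expr <- function(x, params) log2(unclass(x) + params$pseudocount)

stage_or_stop <- function(x, stage) {
  if (!stage %in% colnames(x))
    stop("stage '", stage, "' absent from matrix")
  stage
}

#' Define maternal mRNAs
#'
#' Maternal mRNAs are the transcripts expressed above the FPKM threshold
#' (strictly) in MII oocytes; boundary values fall outside the set.
#'
#' @param matrix a [stage_matrix()] containing an MII stage.
#' @param params [classification_params()].
#' @param mii_stage name of the MII column (default `"MII"`).
#' @return character vector of maternal gene ids.
#' @export
define_maternal <- function(matrix, params = classification_params(),
                            mii_stage = "MII") {
  stage_or_stop(matrix, mii_stage)
  rownames(matrix)[matrix[, mii_stage] > params$maternal_fpkm_threshold]
}

#' Classify maternal decay dynamics into clusters I-III
#'
#' All comparisons are made in `log2(FPKM + pseudocount)` space with a
#' single margin delta.  With `e = log2 expression`:
#' \itemize{
#'   \item cluster I (MII/2C degradation): `e(MII) > e(2C) + delta` and
#'     `|e(2C) - e(4C)| < delta` (degraded before the 2-cell stage, then
#'     stable);
#'   \item cluster II (2C/4C degradation): `|e(MII) - e(2C)| <= delta`
#'     and `e(2C) > e(4C) + delta` (stable until the 2-cell stage, then
#'     degraded);
#'   \item cluster III (continuous degradation): `e(MII) > e(2C) + delta`
#'     and `e(2C) > e(4C) + delta`;
#'   \item none: everything else.
#' }
#' The three labels are mutually exclusive by construction: clusters I
#' and III differ on the 2C-to-4C leg, and cluster II's stable first leg
#' contradicts the strict first-leg drop of I and III.
#'
#' The printed pair of cluster-II inequalities in the source methods is
#' jointly unsatisfiable (`e(MII) > e(2C) + 1` together with
#' `e(MII) < e(2C) - 1`); this implementation follows the verbal
#' description of cluster II -- no significant MII-to-2C change, then a
#' dramatic 4-cell drop -- which is the repair documented in the methods
#' vignette.
#'
#' @param matrix [stage_matrix()] with MII, 2C and 4C stages.
#' @param maternal_set gene ids to classify (typically
#'   [define_maternal()] output); others get cluster `"none"` implicitly
#'   and are omitted.
#' @param params [classification_params()].
#' @param stage_names length-3 character vector naming the MII, 2-cell
#'   and 4-cell columns.
#' @return data.frame `decay_assignment` with columns `gene_id`,
#'   `cluster` (factor I/II/III/none) and logical dependence flags
#'   `ago2_dependent_MII_2C`, `ago2_dependent_2C_4C`, `zga_dependent`
#'   (all `FALSE` until set by [kd_dependence()]/[zga_dependence()]).
#' @export
classify_decay <- function(matrix, maternal_set = rownames(matrix),
                           params = classification_params(),
                           stage_names = c("MII", "2C", "4C")) {
  for (s in stage_names) stage_or_stop(matrix, s)
  maternal_set <- intersect(maternal_set, rownames(matrix))
  e <- log2_expr(matrix[maternal_set, stage_names, drop = FALSE], params)
  d <- params$log_delta
  mii <- e[, 1L]; c2 <- e[, 2L]; c4 <- e[, 3L]
  drop1 <- mii > c2 + d            # significant MII -> 2C decay
  drop2 <- c2 > c4 + d             # significant 2C -> 4C decay
  stable1 <- abs(mii - c2) <= d
  stable2 <- abs(c2 - c4) < d
  cluster <- rep("none", length(maternal_set))
  cluster[drop1 & stable2] <- "I"
  cluster[stable1 & drop2] <- "II"
  cluster[drop1 & drop2] <- "III"
  data.frame(gene_id = maternal_set,
             cluster = factor(cluster, levels = c("I", "II", "III", "none")),
             ago2_dependent_MII_2C = FALSE,
             ago2_dependent_2C_4C = FALSE,
             zga_dependent = FALSE,
             stringsAsFactors = FALSE)
}

# shared "increased or stable" rule: treated-series expression has not
# dropped more than delta log2 units below the reference stage
increased_or_stable <- function(ref_log2, treated_log2, delta)
  treated_log2 >= ref_log2 - delta

#' Flag AGO2-dependent degradation from a knockdown series
#'
#' A gene's MII-to-2C degradation is called AGO2-dependent when its
#' expression is increased or stable between the control MII oocyte and
#' the AGO2-depleted 2-cell embryo, i.e. the decay it shows in the
#' control series is blocked by the knockdown.  "Increased or stable"
#' means not decreased by more than delta log2 units.  The MII/2C flag
#' applies to clusters I and III; the 2C/4C flag (knockdown 4C vs
#' control 2C) applies to clusters II and III.
#'
#' @param ctrl control [stage_matrix()] (supplies MII and 2C).
#' @param kd knockdown [stage_matrix()] (supplies 2C and 4C).
#' @param assignments [classify_decay()] output.
#' @param params [classification_params()].
#' @param stage_names MII/2C/4C column names, shared by both matrices.
#' @return `assignments` with the two `ago2_dependent_*` flags set;
#'   genes missing from the knockdown matrix keep `NA` flags and are
#'   reported in a warning.
#' @export
kd_dependence <- function(ctrl, kd, assignments,
                          params = classification_params(),
                          stage_names = c("MII", "2C", "4C")) {
  stage_or_stop(ctrl, stage_names[1L]); stage_or_stop(ctrl, stage_names[2L])
  stage_or_stop(kd, stage_names[2L]); stage_or_stop(kd, stage_names[3L])
  d <- params$log_delta
  g <- assignments$gene_id
  in_kd <- g %in% rownames(kd)
  if (any(!in_kd))
    warning(sum(!in_kd), " gene(s) absent from knockdown matrix, unassessable")
  e_ctrl <- log2_expr(ctrl, params)
  e_kd <- log2_expr(kd, params)
  leg1 <- assignments$cluster %in% c("I", "III")
  leg2 <- assignments$cluster %in% c("II", "III")
  f1 <- rep(FALSE, length(g)); f2 <- rep(FALSE, length(g))
  idx <- which(leg1 & in_kd)
  f1[idx] <- increased_or_stable(e_ctrl[g[idx], stage_names[1L]],
                                 e_kd[g[idx], stage_names[2L]], d)
  idx <- which(leg2 & in_kd)
  f2[idx] <- increased_or_stable(e_ctrl[g[idx], stage_names[2L]],
                                 e_kd[g[idx], stage_names[3L]], d)
  f1[leg1 & !in_kd] <- NA
  f2[leg2 & !in_kd] <- NA
  assignments$ago2_dependent_MII_2C <- f1
  assignments$ago2_dependent_2C_4C <- f2
  assignments
}

#' Flag ZGA-dependent degradation from a transcription-blocked series
#'
#' Genes with 2C/4C degradation (cluster II, or the 2C-to-4C leg of
#' cluster III) whose expression is increased or stable in the
#' DRB-treated series -- post-treatment 4C-equivalent expression
#' compared to control 2C, same delta rule as [kd_dependence()] -- are
#' flagged ZGA-dependent: blocking minor zygotic transcription blocked
#' their decay.
#'
#' @param drb DRB-treated [stage_matrix()] supplying the post-treatment
#'   4C-equivalent stage.
#' @param ctrl control [stage_matrix()] supplying 2C.
#' @param assignments [classify_decay()] output (possibly already
#'   through [kd_dependence()]).
#' @param params [classification_params()].
#' @param drb_stage column of `drb` holding post-treatment expression.
#' @param ctrl_stage control reference stage (default `"2C"`).
#' @return `assignments` with `zga_dependent` set.
#' @export
zga_dependence <- function(drb, ctrl, assignments,
                           params = classification_params(),
                           drb_stage = "4C", ctrl_stage = "2C") {
  stage_or_stop(drb, drb_stage); stage_or_stop(ctrl, ctrl_stage)
  d <- params$log_delta
  g <- assignments$gene_id
  eligible <- assignments$cluster %in% c("II", "III")
  in_drb <- g %in% rownames(drb)
  if (any(eligible & !in_drb))
    warning(sum(eligible & !in_drb),
            " gene(s) absent from DRB matrix, unassessable")
  e_drb <- log2_expr(drb, params)
  e_ctrl <- log2_expr(ctrl, params)
  flag <- rep(FALSE, length(g))
  idx <- which(eligible & in_drb)
  flag[idx] <- increased_or_stable(e_ctrl[g[idx], ctrl_stage],
                                   e_drb[g[idx], drb_stage], d)
  flag[eligible & !in_drb] <- NA
  assignments$zga_dependent <- flag
  assignments
}

#' Overlap of ZGA-dependent and AGO2-dependent 2C/4C degradation
#'
#' The derived intersection set: genes whose 2C/4C decay is blocked both
#' by AGO2 knockdown and by DRB transcription inhibition.
#'
#' @param assignments assignments carrying both flags.
#' @return character vector of gene ids.
#' @export
zga_ago2_overlap <- function(assignments) {
  with(assignments,
       gene_id[!is.na(zga_dependent) & zga_dependent &
               !is.na(ago2_dependent_2C_4C) & ago2_dependent_2C_4C])
}

#' Fraction of a target set bound in an RIP experiment
#'
#' Plain set arithmetic: `|targets intersect bound| / |targets|`, e.g.
#' the fraction of maternal-mRNA-targeting endosiRNAs recovered in an
#' AGO2 RIP-seq pull-down.
#'
#' @param target_smallrna_ids character vector (non-empty).
#' @param rip_bound_ids character vector.
#' @return fraction in `[0, 1]`.
#' @export
bound_fraction <- function(target_smallrna_ids, rip_bound_ids) {
  target_smallrna_ids <- unique(target_smallrna_ids)
  if (length(target_smallrna_ids) == 0L) stop("empty target set")
  length(intersect(target_smallrna_ids, rip_bound_ids)) /
    length(target_smallrna_ids)
}

#' Summarise cluster sizes and dependence overlaps
#'
#' @param assignments a decay-assignment table.
#' @return data.frame of counts: the three clusters, the AGO2-dependent
#'   legs per cluster, ZGA-dependent genes and the ZGA/AGO2 overlap.
#' @export
summarize_assignments <- function(assignments) {
  a <- assignments
  cnt <- function(x) sum(x, na.rm = TRUE)
  data.frame(
    quantity = c("cluster_I", "cluster_II", "cluster_III", "none",
                 "ago2_dep_MII_2C_clusterI", "ago2_dep_MII_2C_clusterIII",
                 "ago2_dep_2C_4C_clusterII", "ago2_dep_2C_4C_clusterIII",
                 "zga_dependent", "zga_ago2_overlap"),
    count = c(sum(a$cluster == "I"), sum(a$cluster == "II"),
              sum(a$cluster == "III"), sum(a$cluster == "none"),
              cnt(a$ago2_dependent_MII_2C & a$cluster == "I"),
              cnt(a$ago2_dependent_MII_2C & a$cluster == "III"),
              cnt(a$ago2_dependent_2C_4C & a$cluster == "II"),
              cnt(a$ago2_dependent_2C_4C & a$cluster == "III"),
              cnt(a$zga_dependent),
              length(zga_ago2_overlap(a))),
    stringsAsFactors = FALSE)
}
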