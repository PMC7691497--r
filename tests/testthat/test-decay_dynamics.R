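# FPKM value whose log2(FPKM + 1) equals e
fpkm <- function(e) 2^e - 1

sm <- function(e_mat, condition = "control") {
  stage_matrix(fpkm(e_mat), condition)
}

test_that("maternal definition uses a strict FPKM threshold at MII", {
  m <- matrix(c(2.5, 2.0, 0.5, 1, 1, 1, 1, 1, 1), 3,
              dimnames = list(c("in", "boundary", "low"),
                              c("MII", "2C", "4C")))
  got <- define_maternal(stage_matrix(m))
  expect_identical(got, "in")

  empty <- stage_matrix(matrix(numeric(0), 0, 3,
                               dimnames = list(NULL, c("MII", "2C", "4C"))))
  expect_length(define_maternal(empty), 0L)

  no_mii <- stage_matrix(matrix(1, 1, 2, dimnames = list("g", c("2C", "4C"))))
  expect_error(define_maternal(no_mii), "MII")
})

test_that("decay clusters follow the printed log2-margin rules", {
  e <- rbind(cI = c(5, 3, 3), cII = c(5, 5, 2), cIII = c(7, 5, 3),
             none = c(5, 4.5, 4.2))
  colnames(e) <- c("MII", "2C", "4C")
  asg <- classify_decay(sm(e))
  expect_identical(as.character(asg$cluster),
                   c("I", "II", "III", "none"))
})

test_that("cluster labels are mutually exclusive on random profiles", {
  set.seed(20)
  e <- matrix(runif(500 * 3, 0, 9), 500,
              dimnames = list(sprintf("g%03d", 1:500), c("MII", "2C", "4C")))
  asg <- classify_decay(sm(e))
  # factor assignment guarantees one label; re-derive conditions and check
  # at most one cluster's full condition set holds per gene
  d <- 1
  drop1 <- e[, 1] > e[, 2] + d
  drop2 <- e[, 2] > e[, 3] + d
  stable1 <- abs(e[, 1] - e[, 2]) <= d
  stable2 <- abs(e[, 2] - e[, 3]) < d
  n_sat <- (drop1 & stable2) + (stable1 & drop2) + (drop1 & drop2)
  expect_true(all(n_sat <= 1))
  lab <- ifelse(drop1 & stable2, "I",
                ifelse(stable1 & drop2, "II",
                       ifelse(drop1 & drop2, "III", "none")))
  expect_identical(as.character(asg$cluster), unname(lab))
})

test_that("cluster III membership is non-increasing in delta", {
  set.seed(21)
  e <- matrix(runif(300 * 3, 0, 9), 300,
              dimnames = list(sprintf("g%03d", 1:300), c("MII", "2C", "4C")))
  x <- sm(e)
  in_iii <- function(delta) {
    asg <- classify_decay(x, params = classification_params(log_delta = delta))
    asg$gene_id[asg$cluster == "III"]
  }
  prev <- in_iii(0.5)
  for (delta in c(1, 1.5, 2)) {
    cur <- in_iii(delta)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("classification is invariant to log-space shifts", {
  set.seed(22)
  e <- matrix(runif(100 * 3, 1, 8), 100,
              dimnames = list(sprintf("g%03d", 1:100), c("MII", "2C", "4C")))
  a1 <- classify_decay(sm(e))
  a2 <- classify_decay(sm(e + 0.7))
  expect_identical(a1$cluster, a2$cluster)
})

test_that("knockdown dependence follows the increased-or-stable rule", {
  e_ctrl <- rbind(g1 = c(5, 3, 3), g2 = c(5, 3, 3), g3 = c(5, 4.5, 4.4))
  colnames(e_ctrl) <- c("MII", "2C", "4C")
  e_kd <- rbind(g1 = c(4.8, 3), g2 = c(3.0, 3), g3 = c(4.4, 4.4))
  colnames(e_kd) <- c("2C", "4C")
  asg <- classify_decay(sm(e_ctrl))
  asg <- kd_dependence(sm(e_ctrl), sm(e_kd, "knockdown"), asg)
  expect_true(asg$ago2_dependent_MII_2C[asg$gene_id == "g1"])   # 4.8 >= 5 - 1
  expect_false(asg$ago2_dependent_MII_2C[asg$gene_id == "g2"])  # 3.0 <  5 - 1
  expect_false(asg$ago2_dependent_MII_2C[asg$gene_id == "g3"])  # cluster none
  expect_false(asg$ago2_dependent_2C_4C[asg$gene_id == "g3"])

  # gene absent from the knockdown matrix is unassessable, with warning
  e_kd2 <- e_kd[1:2, , drop = FALSE]
  expect_warning(
    asg2 <- kd_dependence(sm(e_ctrl), sm(e_kd2, "knockdown"),
                          classify_decay(sm(e_ctrl))),
    "unassessable")
  expect_false(anyNA(asg2$ago2_dependent_MII_2C[asg2$cluster == "none"]))
})

test_that("ZGA dependence applies only to 2C/4C-degrading clusters", {
  e_ctrl <- rbind(g1 = c(5, 5, 2), g2 = c(5, 3, 3), g3 = c(7, 5, 3))
  colnames(e_ctrl) <- c("MII", "2C", "4C")
  e_drb <- cbind(`4C` = c(g1 = 4.8, g2 = 4.9, g3 = 2.0))
  asg <- classify_decay(sm(e_ctrl))
  asg <- zga_dependence(sm(e_drb, "DRB"), sm(e_ctrl), asg)
  expect_true(asg$zga_dependent[asg$gene_id == "g1"])    # cluster II, stable
  expect_false(asg$zga_dependent[asg$gene_id == "g2"])   # cluster I: never
  expect_false(asg$zga_dependent[asg$gene_id == "g3"])   # III but degraded
})

test_that("planted dependence flags and overlap are recovered at zero noise", {
  cfg <- synth_config(seed = 33, n_genes = 400, noise_sd = 0)
  ex <- gen_expression(cfg)
  asg <- classify_decay(ex$control, define_maternal(ex$control))
  asg <- kd_dependence(ex$control, ex$kd, asg)
  asg <- zga_dependence(ex$drb, ex$control, asg)
  tr <- ex$truth[match(asg$gene_id, ex$truth$gene_id), ]
  expect_identical(as.character(asg$cluster), tr$cluster)
  eligible1 <- tr$cluster %in% c("I", "III")
  expect_identical(asg$ago2_dependent_MII_2C[eligible1],
                   tr$ago2_dependent_MII_2C[eligible1])
  eligible2 <- tr$cluster %in% c("II", "III")
  expect_identical(asg$ago2_dependent_2C_4C[eligible2],
                   tr$ago2_dependent_2C_4C[eligible2])
  expect_identical(asg$zga_dependent[eligible2], tr$zga_dependent[eligible2])
  expect_setequal(zga_ago2_overlap(asg),
                  tr$gene_id[tr$zga_dependent & tr$ago2_dependent_2C_4C])
})

test_that("bound fraction is plain set arithmetic", {
  expect_equal(bound_fraction(c("a", "b", "c", "d"), c("a", "b", "c", "x")),
               0.75)
  expect_equal(bound_fraction(c("a", "b"), c("x", "y")), 0)
  expect_equal(bound_fraction(c("a", "b"), c("a", "b", "c")), 1)
  expect_error(bound_fraction(character(0), "a"), "empty")
})
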