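mat2 <- function(...) {
  m <- cbind(...)
  rownames(m) <- paste0("p", seq_len(nrow(m)))
  m
}

test_that("quantile normalization follows the two-point closed form", {
  m <- mat2(s1 = c(1, 3), s2 = c(2, 4))
  q <- quantileNormalize(m)
  expect_equal(unname(q[, "s1"]), c(1.5, 3.5))
  expect_equal(unname(q[, "s2"]), c(1.5, 3.5))
  ## order preserved within column
  m2 <- mat2(s1 = c(3, 1), s2 = c(2, 4))
  q2 <- quantileNormalize(m2)
  expect_equal(unname(q2[, "s1"]), c(3.5, 1.5))
})

test_that("quantile normalization fixes identical columns and equalizes sorted columns", {
  m <- mat2(s1 = c(5, 1, 9), s2 = c(5, 1, 9))
  expect_equal(quantileNormalize(m), m)
  withr::local_seed(71)
  r <- matrix(rexp(300) + 0.1, 50, 6,
              dimnames = list(paste0("p", 1:50), paste0("s", 1:6)))
  q <- quantileNormalize(r)
  sorted <- apply(q, 2L, sort)
  for (j in 2:6)
    expect_equal(sorted[, j], sorted[, 1L])
  ## rank order preserved per column
  for (j in 1:6)
    expect_equal(order(q[, j]), order(r[, j]))
  expect_warning(quantileNormalize(r[, 1, drop = FALSE]), "single-sample")
  expect_error(quantileNormalize(-r), "positive")
})

test_that("median polish recovers exactly additive data in one sweep", {
  a <- c(0.5, -1, 2, 0)           # probe affinities
  b <- c(7, 8, 9)                 # sample effects
  l2 <- outer(a, b, "+")
  dimnames(l2) <- list(paste0("p", 1:4), paste0("s", 1:3))
  lin <- 2^l2
  out <- summarizeByFeature(lin, setNames(rep("F1", 4), rownames(lin)))
  ## summary = b + mean-centred constant; differences across samples exact
  expect_equal(unname(diff(out["F1", ])), diff(b), tolerance = 1e-9)
  ## residuals zero: overall+row+col reproduces the matrix
  mp <- stats::medpolish(l2, eps = 1e-6, maxiter = 10L,
                         trace.iter = FALSE)
  expect_lt(max(abs(mp$residuals)), 1e-9)
})

test_that("single-probe features summarize to the probe itself", {
  lin <- mat2(s1 = c(4, 16), s2 = c(8, 32))
  out <- summarizeByFeature(lin, c(p1 = "A", p2 = "B"))
  expect_equal(unname(out["A", ]), c(2, 3))
  expect_equal(unname(out["B", ]), c(4, 5))
})

test_that("median-polish summaries equal the independent oracle", {
  withr::local_seed(73)
  for (rep in 1:10) {
    x <- matrix(sample(1:64, 12, TRUE), 4, 3,
                dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
    out <- summarizeByFeature(2^x, setNames(rep("F", 4), rownames(x)))
    o <- oracleMedpolish(x)
    expect_equal(unname(out["F", ]), unname(o$overall + o$col),
                 tolerance = 1e-9)
  }
})

test_that("GNI is the per-sample probe-set minus cluster log2 signal", {
  ps <- matrix(8, 1, 2, dimnames = list("PS1", c("s1", "s2")))
  cl <- matrix(6, 1, 2, dimnames = list("C1", c("s1", "s2")))
  gni <- computeGNI(ps, cl, c(PS1 = "C1"))
  expect_equal(unname(gni["PS1", ]), c(2, 2))
  ## probe set tracking its cluster exactly -> GNI identically zero
  trk <- matrix(c(5, 7, 6, 9), 1, 4,
                dimnames = list("PS1", paste0("s", 1:4)))
  rownames(trk) <- "PS1"
  cl2 <- trk; rownames(cl2) <- "C1"
  expect_true(all(computeGNI(trk, cl2, c(PS1 = "C1")) == 0))
  expect_error(computeGNI(ps, cl[, 1, drop = FALSE], c(PS1 = "C1")),
               "same samples")
})

test_that("GNI is zero when a cluster has a single probe set", {
  ## the cluster summary pools exactly the probe set's probes, so both
  ## median polishes see the same sub-matrix
  withr::local_seed(79)
  lin <- matrix(2^rnorm(24, 8), 6, 4,
                dimnames = list(paste0("p", 1:6), paste0("s", 1:4)))
  ps <- summarizeByFeature(lin, setNames(rep("PS1", 6), rownames(lin)))
  cl <- summarizeByFeature(lin, setNames(rep("C1", 6), rownames(lin)))
  gni <- computeGNI(ps, cl, c(PS1 = "C1"))
  expect_true(all(abs(gni) < 1e-12))
})

test_that("splice index is the group difference of mean GNI", {
  design <- groupDesign(paste0("s", 1:4), c("g1", "g1", "g2", "g2"))
  gni <- matrix(c(2, 2, 0.5, 0.5), 1, 4,
                dimnames = list("PS1", paste0("s", 1:4)))
  res <- spliceIndex(gni, design, c(PS1 = "C1"))
  expect_equal(res$si, 1.5)
  ## identical GNI in both groups -> SI 0, p 1
  flat <- matrix(1, 1, 4, dimnames = dimnames(gni))
  res0 <- spliceIndex(flat, design, c(PS1 = "C1"))
  expect_equal(res0$si, 0)
  expect_equal(res0$p_value, 1)
})

test_that("swapping group labels negates SI and fold change bitwise", {
  withr::local_seed(83)
  gni <- matrix(rnorm(40), 5, 8,
                dimnames = list(paste0("PS", 1:5), paste0("s", 1:8)))
  grp <- rep(c("A", "B"), each = 4)
  d1 <- groupDesign(paste0("s", 1:8), grp)
  d2 <- groupDesign(paste0("s", 1:8), grp, ref = "B")
  map <- setNames(rep("C1", 5), paste0("PS", 1:5))
  r1 <- spliceIndex(gni, d1, map)
  r2 <- spliceIndex(gni, d2, map)
  expect_identical(r1$si, -r2$si)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  e1 <- differentialExpression(gni, d1)
  e2 <- differentialExpression(gni, d2)
  expect_identical(e1$log2_fold_change, -e2$log2_fold_change)
})

test_that("differential expression handles exact shifts and flat data", {
  design <- groupDesign(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  base <- matrix(rep(c(5, 6, 7), each = 6), 3, 6, byrow = TRUE,
                 dimnames = list(paste0("C", 1:3), paste0("s", 1:6)))
  ## identical groups: fc 0, flat zero-variance rows give p = 1
  r0 <- differentialExpression(base, design)
  expect_true(all(r0$log2_fold_change == 0))
  expect_true(all(r0$p_value == 1))
  ## +1 log2 shift of group A with zero noise: fc exactly 1
  shifted <- base
  shifted[, 1:3] <- shifted[, 1:3] + 1
  r1 <- differentialExpression(shifted, design)
  expect_true(all(r1$log2_fold_change == 1))
})

test_that("Welch p-values match the textbook formula", {
  withr::local_seed(89)
  design <- groupDesign(paste0("s", 1:9),
                        c(rep("A", 4), rep("B", 5)))
  m <- matrix(rnorm(180), 20, 9,
              dimnames = list(paste0("C", 1:20), paste0("s", 1:9)))
  res <- differentialExpression(m, design)
  for (i in 1:20)
    expect_equal(res$p_value[i],
                 oracleWelchP(m[i, 1:4], m[i, 5:9]), tolerance = 1e-9)
  expect_equal(res$fdr, p.adjust(res$p_value, "BH"))
})

test_that("top-variance selection keeps the n most variable rows in order", {
  m <- mat2(s1 = c(0, 0, 0), s2 = c(0, 1, 2), s3 = c(0, -1, -2))
  ## row variances 0, 1, 4
  expect_equal(rownames(selectTopVariance(m, 1)), "p3")
  expect_identical(selectTopVariance(m, 10), m)
  withr::local_seed(97)
  r <- matrix(rnorm(1500), 300, 5,
              dimnames = list(paste0("p", 1:300), paste0("s", 1:5)))
  sel <- selectTopVariance(r, 150)
  v <- apply(r, 1, var)
  want <- sort(order(v, decreasing = TRUE)[1:150])
  expect_identical(rownames(sel), rownames(r)[want])
  ## original order preserved among the selected
  expect_false(is.unsorted(match(rownames(sel), rownames(r))))
})
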