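# Core statistical primitives checked against closed forms and independent
# reference implementations.

test_that("Welch t matches the closed form on the toy triples", {
  res <- welch_t_pvalue(c(1, 2, 3), c(4, 5, 6))
  # closed form: means 2 and 5, variances 1, se = sqrt(2/3), df = 4
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  expect_equal(round(res$p, 4), 0.0213)
})

test_that("Welch t agrees with t.test and is translation invariant", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    ref <- t.test(x, y)
    res <- welch_t_pvalue(x, y)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(res$p, ref$p.value, tolerance = 1e-9)
    shifted <- welch_t_pvalue(x + 5, y + 5)
    expect_equal(shifted$t, res$t, tolerance = 1e-9)
  }
  # identical degenerate groups carry no evidence
  expect_equal(welch_t_pvalue(c(1, 1, 1), c(1, 1))$p, 1)
})

test_that("row-wise Welch equals per-row t.test on a matrix", {
  set.seed(2)
  m <- matrix(rnorm(50 * 14), 50)
  res <- row_welch(m, 1:6, 7:14)
  ref_p <- apply(m, 1, function(v) t.test(v[1:6], v[7:14])$p.value)
  expect_equal(res$p, ref_p, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("BH adjustment reproduces the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(100)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("rank AUC agrees with pROC and is monotone invariant", {
  skip_if_not_installed("pROC")
  set.seed(4)
  for (i in 1:10) {
    y <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    s <- rnorm(40) + y
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-9)
    expect_equal(roc_auc(exp(s), y), roc_auc(s, y), tolerance = 1e-12)
  }
  # ties counted as 1/2
  expect_equal(roc_auc(c(1, 1), c(TRUE, FALSE)), 0.5)
})

test_that("Spearman test matches cor.test's t approximation", {
  set.seed(5)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  res <- spearman_test(x, y)
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-9)
  # perfectly monotone association
  expect_equal(spearman_test(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_test(1:10, (1:10)^3)$p, 0)
  # missing pairs dropped
  x[1] <- NA
  expect_equal(spearman_test(x, y)$n, 29)
})

test_that("exact hypergeometric enrichment reproduces the enumeration oracle", {
  # universe of 10 genes, one 4-gene pathway, 5 foreground genes, overlap 4:
  # P(X >= 4) = C(4,4) C(6,1) / C(10,5) = 6/252
  cg <- data.frame(compound_id = paste0("c", 1:10), gene = paste0("g", 1:10))
  gp <- data.frame(gene = paste0("g", 1:4), pathway = "pw1")
  res <- hypergeom_enrichment(paste0("c", 1:5), paste0("c", 1:10),
                              rbind(cg[1:4, ], cg[5:10, ]), gp)
  expect_equal(res$p[res$pathway == "pw1"], 6 / 252, tolerance = 1e-9)
})

test_that("retention-time alignment interpolates and extrapolates linearly", {
  anchors <- cbind(c(1, 3), c(2, 6))
  expect_equal(align_rt(2, anchors), 4)           # interpolation arithmetic
  expect_equal(align_rt(c(1, 3), anchors), c(2, 6))  # nodes map exactly
  expect_equal(align_rt(0, anchors), 0)           # terminal slope extended
  expect_equal(align_rt(4, anchors), 8)
  id <- cbind(c(1, 5, 10), c(1, 5, 10))
  rt <- c(0.5, 2, 7, 12)
  expect_equal(align_rt(rt, id), rt)
  expect_error(align_rt(1, cbind(c(1, 1), c(2, 3))), "strictly increasing")
  # monotone anchors give a monotone map
  set.seed(6)
  a <- cbind(sort(runif(4, 0, 10)), sort(runif(4, 0, 12)))
  x <- sort(runif(50, -2, 14))
  expect_true(all(diff(align_rt(x, a)) >= 0))
})

test_that("ppm matching arithmetic respects the 5 ppm boundary", {
  src <- data.frame(compound_id = "a", mz = 500.0000, rt = 5, ion_mode = "positive")
  near <- data.frame(compound_id = "b", mz = 500.0024, rt = 5 + 5 / 60,
                     ion_mode = "positive")
  far <- data.frame(compound_id = "b", mz = 500.0026, rt = 5, ion_mode = "positive")
  expect_equal(nrow(match_lipids(src, near)), 1)   # 4.8 ppm, 5 s
  expect_equal(nrow(match_lipids(src, far)), 0)    # 5.2 ppm
  late <- near; late$rt <- 5 + 7 / 60               # 7 s away
  expect_equal(nrow(match_lipids(src, late)), 0)
})
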