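test_that("basic lipid filters reproduce the hand-enumerated keep/drop set", {
  res <- basic_lipid_filters(toy_lipid_table())
  kept <- res$matrix$features$compound_id
  expect_setequal(kept, c("P02", "P03", "P05", "P07", "P09", "P14", "P15",
                          sprintf("P%02d", 16:20)))
  # rt 1.4 dropped at the window edge, 1.5 kept (closed interval)
  rep_rt <- subset(res$report, rule == "rt_window")
  expect_equal(rep_rt$decision[rep_rt$compound_id == "P01"], "drop")
  expect_equal(rep_rt$decision[rep_rt$compound_id == "P02"], "keep")
  # detection fraction boundary: exactly 75% kept, below dropped
  rep_det <- subset(res$report, rule == "detection")
  expect_equal(rep_det$decision[rep_det$compound_id == "P07"], "keep")
  expect_equal(rep_det$decision[rep_det$compound_id == "P08"], "drop")
  expect_equal(rep_det$statistic[rep_det$compound_id == "P07"], 0.75)
  # sub-floor values on kept peaks are replaced by the floor
  expect_equal(res$matrix$values["P09", "s1"], 200)
  expect_equal(res$matrix$values["P07", "s7"], 200)
  # one m/z at four well-separated retention times is a contaminant
  rep_dup <- subset(res$report, rule == "contaminant")
  expect_true(all(rep_dup$decision[rep_dup$compound_id %in%
                                     sprintf("P%02d", 10:13)] == "drop"))
  expect_true(all(rep_dup$decision[rep_dup$compound_id %in% c("P14", "P15")] == "keep"))
  # every compound appears exactly once per rule
  expect_true(all(table(res$report$rule) == 20))
})

test_that("an empty post-filter matrix is an explicit error", {
  m <- toy_lipid_table()
  m$features$rt <- rep(0.5, 20)
  expect_error(basic_lipid_filters(m), "no lipid peaks remain")
})

test_that("drift scores flag run-order-dependent peaks only", {
  st <- sample_table(data.frame(sample_id = paste0("s", 1:60),
                                population = "HC", age = 30,
                                run_order = sample(60)))
  set.seed(8)
  flat <- rep(5000, 60)
  drifting <- 3000 + 50 * st$run_order + rnorm(60, 0, 10)
  noisy <- 5000 + rnorm(60, 0, 300)
  vals <- rbind(flat = flat, drifting = drifting, noisy = noisy)
  colnames(vals) <- st$sample_id
  feat <- data.frame(compound_id = rownames(vals), kind = "lipid",
                     mz = c(400, 500, 600), rt = 5, ion_mode = "positive",
                     name = NA)
  m <- intensity_matrix(vals, feat, st, scale = "raw")
  sc <- runorder_drift_scores(m)
  expect_lt(abs(sc["flat"]), 0.05)
  expect_gt(sc["drifting"], 0.9)
  expect_lt(sc["noisy"], 0.5)

  no_ro <- st; no_ro$run_order[1] <- NA
  m2 <- m; m2$samples <- no_ro
  expect_error(runorder_drift_scores(m2), "run order missing")
})

test_that("top-drift exclusion removes exactly the k strongest per mode", {
  fx <- small_study()
  m <- fx$dat$lipids_pos
  scores <- setNames(seq_len(nrow(m$values)) / nrow(m$values),
                     m$features$compound_id)
  res <- exclude_top_drift(m, scores,
                           lipid_filter_config(drift_exclude_pos = 3,
                                               drift_exclude_neg = 0))
  dropped <- setdiff(m$features$compound_id, res$matrix$features$compound_id)
  expect_setequal(dropped, names(sort(scores, decreasing = TRUE))[1:3])
  # k = 0 is the identity
  res0 <- exclude_top_drift(m, scores,
                            lipid_filter_config(drift_exclude_pos = 0,
                                                drift_exclude_neg = 0))
  expect_equal(res0$matrix$features$compound_id, m$features$compound_id)
})

test_that("planted drift compounds are recovered by the exclusion step", {
  fx <- small_study()
  # reports from the fixture's preprocessing: which compounds did the
  # drift rule drop, and were they the planted ones?
  planted <- fx$dat$truth$drift_ids
  generated <- c(fx$dat$lipids_pos$features$compound_id,
                 fx$dat$lipids_neg$features$compound_id)
  excluded <- setdiff(generated, fx$lipids$features$compound_id)
  expect_gt(mean(planted %in% excluded), 0.75)
})

test_that("upper-quartile normalization equalizes scale and preserves ranks", {
  fx <- small_study()
  raw <- basic_lipid_filters(fx$dat$lipids_pos)$matrix
  # a doubled sample collapses onto the original after normalization
  m2 <- raw
  m2$values[, 2] <- 2 * m2$values[, 1]
  normed <- normalize_lipids(m2)
  expect_equal(normed$values[, 1], normed$values[, 2], ignore_attr = TRUE)
  # upper quartiles equal across samples afterwards
  uq <- apply(2^normalize_lipids(raw)$values, 2, quantile, 0.75)
  expect_lt(diff(range(uq)) / mean(uq), 1e-12)
  # within-sample rank order unchanged
  expect_equal(order(normalize_lipids(raw)$values[, 5]), order(raw$values[, 5]))
  # zero upper quartile is an error
  bad <- raw; bad$values[] <- 0
  expect_error(normalize_lipids(bad), "upper quartile")
})

test_that("metabolite preprocessing applies the 50% rule, fill, batch removal and quantile normalization", {
  st <- sample_table(data.frame(sample_id = paste0("s", 1:6),
                                population = "HC", age = 30,
                                batch = rep(c("b1", "b2"), each = 3)))
  vals <- rbind(
    M1 = c(500, 600, 700, NA, NA, NA),      # detected in exactly 50%: kept
    M2 = c(800, 900, NA, NA, NA, NA),       # detected in 33%: dropped
    M3 = c(1000, 1100, 1200, 2000, 2200, 2400),  # strong batch offset
    M4 = c(400, 500, 600, 450, 520, 610))
  colnames(vals) <- st$sample_id
  feat <- data.frame(compound_id = rownames(vals), kind = "metabolite",
                     mz = NA, rt = NA, ion_mode = "none", name = rownames(vals))
  res <- preprocess_metabolites(intensity_matrix(vals, feat, st, "raw"))
  expect_setequal(res$matrix$features$compound_id, c("M1", "M3", "M4"))
  expect_equal(subset(res$report, compound_id == "M2")$decision, "drop")
  expect_false(anyNA(res$matrix$values))
  expect_equal(res$matrix$scale, "log2")
  # batch means agree after correction
  v3 <- res$matrix$values["M3", ]
  expect_lt(abs(mean(v3[1:3]) - mean(v3[4:6])), 0.35)
})

test_that("quantile normalization maps identical samples to identical columns", {
  st <- sample_table(data.frame(sample_id = c("a", "b"), population = "HC",
                                age = 30, batch = "b1"))
  vals <- cbind(a = c(100, 400, 900, 1600), b = c(100, 400, 900, 1600))
  rownames(vals) <- paste0("M", 1:4)
  feat <- data.frame(compound_id = rownames(vals), kind = "metabolite",
                     mz = NA, rt = NA, ion_mode = "none", name = rownames(vals))
  res <- preprocess_metabolites(intensity_matrix(vals, feat, st, "raw"))
  expect_equal(res$matrix$values[, "a"], res$matrix$values[, "b"],
               ignore_attr = TRUE)
})

test_that("PMI filter drops confounded compounds and reports rho/p/n", {
  fx <- small_study()
  m <- normalize_lipids(basic_lipid_filters(fx$dat$lipids_pos)$matrix)
  st <- assign_dataset(m$samples)
  # plant a compound that is a monotone function of PMI
  adult_pmi <- ifelse(is.na(st$pmi), 20, st$pmi)
  m$values[1, ] <- log2(adult_pmi + 1)
  res <- pmi_filter(m, p_threshold = 0.01)
  first <- m$features$compound_id[1]
  expect_false(first %in% res$matrix$features$compound_id)
  rep1 <- subset(res$report, compound_id == first)
  expect_gt(abs(rep1$statistic), 0.99)
  expect_equal(rep1$decision, "drop")
  expect_true(all(res$report$n == sum(st$dataset == "DS:5-71" & !is.na(st$pmi))))
  # relaxed threshold drops at least as many as the strict one
  strict <- sum(pmi_filter(m, 0.01)$report$decision == "drop")
  relaxed <- sum(pmi_filter(m, 0.1)$report$decision == "drop")
  expect_gte(relaxed, strict)
})

test_that("RIN subsetting uses an inclusive boundary", {
  fx <- small_study()
  m <- fx$lipids
  m$samples$rin <- seq(6, 8, length.out = nrow(m$samples))
  sub <- rin_subset(m, rin_min = 7)
  expect_true(all(sub$samples$rin >= 7))
  expect_equal(nrow(sub$samples), sum(m$samples$rin >= 7))
  m$samples$rin <- NA_real_
  expect_error(rin_subset(m), "no samples")
})
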