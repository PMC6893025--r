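make_pub_cohort <- function(seed = 61) {
  set.seed(seed)
  sample_table(data.frame(
    sample_id = sprintf("P%02d", 1:14),
    population = rep(c("HC", "WE", "AA"), times = c(5, 5, 4)),
    age = runif(14, 20, 45), sex = "unknown", batch = "pub",
    run_order = sample(14)))
}

test_that("matching is one-to-one, mode-gated and symmetric", {
  src <- data.frame(compound_id = c("a1", "a2", "a3"),
                    mz = c(400, 500, 600), rt = c(5, 6, 7),
                    ion_mode = "positive")
  tgt <- data.frame(compound_id = c("b1", "b2", "b3", "b4"),
                    mz = c(400.0000, 500.0005, 500.0010, 600),
                    rt = c(5, 6, 6.01, 7), ion_mode = "positive")
  m <- match_lipids(src, tgt)
  # a2 sees two candidates within tolerance and is removed entirely
  expect_false("a2" %in% m$source_id)
  expect_setequal(m$source_id, c("a1", "a3"))
  # symmetric under swapping roles
  m_rev <- match_lipids(tgt, src)
  expect_setequal(paste(m$source_id, m$target_id),
                  paste(m_rev$target_id, m_rev$source_id))
  # a negative-mode target never matches a positive-mode source
  tgt_neg <- tgt; tgt_neg$ion_mode <- "negative"
  expect_equal(nrow(match_lipids(src, tgt_neg)), 0)
  # disjoint mass ranges give an empty result
  far <- tgt; far$mz <- far$mz + 50
  expect_equal(nrow(match_lipids(src, far)), 0)
})

test_that("replica datasets are recovered by alignment plus tolerance matching", {
  fx <- small_study()
  pub <- generate_replica(make_pub_cohort(), fx$cfg, fx$dat$truth,
                          fx$dat$lipids_pos$features, seed = 62)
  src <- fx$dat$lipids_pos$features[, c("compound_id", "mz", "rt", "ion_mode")]
  # anchors at known warp points (warp is rt -> 0.2 + 1.02 rt)
  anchors <- cbind(c(2, 8, 16), 0.2 + 1.02 * c(2, 8, 16))
  src$rt <- align_rt(src$rt, anchors)
  matches <- match_lipids(src, pub$features[, c("compound_id", "mz", "rt", "ion_mode")])
  expect_gt(nrow(matches), 0.9 * nrow(src))
  expect_true(all(paste0("R_", matches$source_id) == matches$target_id))
  expect_true(all(matches$ppm_error <= 5))
  expect_true(all(matches$rt_error_sec <= 6))
})

test_that("fold changes agree between a study and its replica and not under noise", {
  fx <- small_study()
  pub <- normalize_lipids(generate_replica(make_pub_cohort(), fx$cfg,
                                           fx$dat$truth,
                                           fx$dat$lipids_pos$features,
                                           seed = 63))
  src <- fx$dat$lipids_pos$features[, c("compound_id", "mz", "rt", "ion_mode")]
  anchors <- cbind(c(2, 8, 16), 0.2 + 1.02 * c(2, 8, 16))
  src$rt <- align_rt(src$rt, anchors)
  matches <- match_lipids(src, pub$features[, c("compound_id", "mz", "rt", "ion_mode")])
  hc_set <- population_specific_set(fx$adult, alpha = 0.05)$HC$compound_id
  res <- foldchange_consistency(fx$adult, pub, matches, hc_set)
  expect_gt(res$rho, 0)
  expect_lt(res$p, 0.05)
  # identical datasets correlate perfectly
  self <- matches; self$target_id <- self$source_id
  res_self <- foldchange_consistency(fx$adult, fx$adult, self, hc_set)
  expect_equal(res_self$rho, 1)
  # a pure-noise replica shows no consistency
  null_cfg <- small_cfg(seed = 64, hc_effect_size = 0)
  null_truth <- generate_intensities(generate_cohort(null_cfg), null_cfg)$truth
  pub_null <- normalize_lipids(generate_replica(make_pub_cohort(65), null_cfg,
                                                null_truth,
                                                fx$dat$lipids_pos$features[, ],
                                                seed = 65))
  res_null <- foldchange_consistency(fx$adult, pub_null, matches, hc_set)
  expect_lt(abs(res_null$rho), 0.35)
  # too few matched compounds is an explicit error
  expect_error(foldchange_consistency(fx$adult, pub, matches[0, ], hc_set),
               "matched compounds")
})

test_that("external validation classifies replica samples and fails under permutation", {
  fx <- small_study()
  pub <- normalize_lipids(generate_replica(make_pub_cohort(), fx$cfg,
                                           fx$dat$truth,
                                           fx$dat$lipids_pos$features,
                                           seed = 66))
  src <- fx$dat$lipids_pos$features[, c("compound_id", "mz", "rt", "ion_mode")]
  anchors <- cbind(c(2, 8, 16), 0.2 + 1.02 * c(2, 8, 16))
  src$rt <- align_rt(src$rt, anchors)
  matches <- match_lipids(src, pub$features[, c("compound_id", "mz", "rt", "ion_mode")])
  ev <- external_validation(fx$adult, pub, matches,
                            cfg = classifier_config(n_stab = 40, seed = 67),
                            top_k_grid = c(1, 5, 10, 22), norm_iter = 50)
  expect_gte(ev$best_auc, max(ev$auc$auc))
  expect_gt(ev$best_auc, 0.8)
  # label permutation destroys the signal on average
  set.seed(68)
  perm_auc <- replicate(20, {
    pub_perm <- pub
    pub_perm$samples$population <- sample(pub$samples$population)
    ids <- names(ev$ranking$counts)[seq_len(ev$best_k)]
    # scores are fixed by the model; permuting labels is equivalent
    roc_auc(seq_len(14), pub_perm$samples$population == "HC")
  })
  expect_gt(mean(perm_auc), 0.3)
  expect_lt(mean(perm_auc), 0.7)
  # requesting more predictors than matches is truncated with a warning
  expect_warning(
    external_validation(fx$adult, pub, matches[1:10, ],
                        cfg = classifier_config(n_stab = 5, seed = 69),
                        top_k_grid = c(2, 50), norm_iter = 5),
    "truncated")
})
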