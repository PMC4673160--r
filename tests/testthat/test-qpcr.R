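make_ct <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(sample = r[[1]], assay = r[[2]], role = r[[3]],
               replicate = as.integer(r[[4]]), ct = as.numeric(r[[5]]))))
  ct_table(df)
}

REFS <- c("GAPDH", "ACTB", "RPLP0")

## samples with reference genes at fixed Ct 20/21/22 and a chosen target Ct
ref_block <- function(sample, target_ct) {
  list(list(sample, "SPP1", "target", 1, target_ct),
       list(sample, "GAPDH", "reference", 1, 20),
       list(sample, "ACTB", "reference", 1, 21),
       list(sample, "RPLP0", "reference", 1, 22))
}

test_that("the worked reference-index case gives ddCt -3 and fold 8", {
  ## calibrator sample has dCt = 7; test sample Ct 25 against index 21
  ct <- make_ct(c(ref_block("cal", 28), ref_block("tum", 25)))
  f <- ddct_fold_change(ct, "SPP1", REFS, calibrator = "cal")
  expect_equal(f$reference_index_ct, c(21, 21))
  tum <- f[f$sample == "tum", ]
  expect_equal(tum$delta_delta_ct, -3)
  expect_equal(tum$fold, 8)
})

test_that("self-calibration gives fold exactly 1 and a one-cycle drop doubles it", {
  ct <- make_ct(ref_block("s1", 25))
  f <- ddct_fold_change(ct, "SPP1", REFS, calibrator = "s1")
  expect_equal(f$fold, 1)

  ct2 <- make_ct(c(ref_block("cal", 25), ref_block("s2", 24)))
  f2 <- ddct_fold_change(ct2, "SPP1", REFS, calibrator = "cal")
  expect_equal(f2$fold[f2$sample == "s2"], 2)
})

test_that("calibrator geometric-mean fold is exactly 1 and reference shifts cancel", {
  ct <- make_ct(c(ref_block("c1", 24), ref_block("c2", 27),
                  ref_block("t1", 22)))
  f <- ddct_fold_change(ct, "SPP1", REFS, calibrator = c("c1", "c2"))
  expect_equal(exp(mean(log(f$fold[f$sample %in% c("c1", "c2")]))), 1)
  ## adding a constant to every assay Ct of one sample leaves folds intact
  shifted <- as.data.frame(ct)
  shifted$ct[shifted$sample == "t1"] <- shifted$ct[shifted$sample == "t1"] + 3
  f2 <- ddct_fold_change(ct_table(shifted), "SPP1", REFS,
                         calibrator = c("c1", "c2"))
  expect_equal(f2$fold, f$fold)
})

test_that("replicates are averaged and discordant pairs flagged", {
  df <- do.call(rbind, lapply(ref_block("s1", 25), function(r)
    data.frame(sample = r[[1]], assay = r[[2]], role = r[[3]],
               replicate = 1L, ct = as.numeric(r[[5]]))))
  df2 <- df; df2$replicate <- 2L
  df2$ct[df2$assay == "SPP1"] <- 26.5  # 1.5 cycles apart
  expect_warning(ct <- ct_table(rbind(df, df2)), "concordance")
  expect_equal(nrow(attr(ct, "discordant")), 1L)
  f <- ddct_fold_change(ct, "SPP1", REFS, calibrator = "s1")
  expect_equal(f$ct_target, 25.75)
})

test_that("missing assays and empty calibrators raise located errors", {
  ct <- make_ct(ref_block("s1", 25))
  expect_error(ddct_fold_change(ct, "SPP1", REFS, calibrator = character(0)),
               "calibrator")
  expect_error(ddct_fold_change(ct, "MYC", REFS, calibrator = "s1"),
               "MYC.*s1")
  expect_error(ct_table(data.frame(sample = "s", assay = "a", role = "target",
                                   replicate = 1, ct = -1)), "positive")
})

test_that("the 2m+s caller reproduces hand-computable thresholds and the boundary rule", {
  labels <- data.frame(sample = c("n1", "n2", "n3", "t1"),
                       class = c("Normal", "Normal", "BE", "EAC_II"))
  mk_folds <- function(folds) {
    structure(data.frame(sample = labels$sample, fold = folds),
              class = c("fold_change", "data.frame"))
  }
  ## reference folds {1,1,1} -> m=1, s=0, T=2; tumor 2.5 called
  calls <- call_overexpression(mk_folds(c(1, 1, 1, 2.5)), labels)
  expect_equal(unique(calls$threshold), 2)
  expect_true(calls$called[calls$sample == "t1"])
  expect_false(any(calls$called[calls$class != "EAC_II"]))
  ## m=1, s=0.5 -> T=2.5; tumor 2.4 not called
  f2 <- mk_folds(c(0.5, 1, 1.5, 2.4))
  calls2 <- call_overexpression(f2, labels)
  expect_equal(unique(calls2$threshold), 2 * 1 + 0.5)
  expect_false(calls2$called[calls2$sample == "t1"])
  ## fold exactly at the threshold is not called (strict inequality)
  calls3 <- call_overexpression(mk_folds(c(1, 1, 1, 2)), labels)
  expect_false(calls3$called[calls3$sample == "t1"])
  ## monotone in fold with a fixed reference group
  folds_grid <- seq(1.5, 3, by = 0.25)
  called_seq <- sapply(folds_grid, function(x)
    call_overexpression(mk_folds(c(1, 1, 1, x)), labels)$called[4])
  expect_true(all(diff(called_seq) >= 0))
  expect_error(call_overexpression(mk_folds(c(1, 1, 1, 3))[c(4, 4, 4, 4), ],
                                   labels[4, ]), "reference")
})

test_that("copy-number ratios follow the paired ddCt arithmetic", {
  ct <- make_ct(list(
    list("t1", "SPP1", "target", 1, 24), list("t1", "GAPDH", "internal_control", 1, 20),
    list("n1", "SPP1", "target", 1, 25), list("n1", "GAPDH", "internal_control", 1, 21),
    list("t2", "SPP1", "target", 1, 23), list("t2", "GAPDH", "internal_control", 1, 20),
    list("n2", "SPP1", "target", 1, 24), list("n2", "GAPDH", "internal_control", 1, 20)))
  pairs <- data.frame(tumor = c("t1", "t2"), normal = c("n1", "n2"))
  cn <- copy_number_ratio(ct, "SPP1", "GAPDH", pairs)
  expect_equal(cn$ratio, c(1, 2))
  expect_equal(cn$status, c("unchanged", "gain"))
  ## swapping tumor and normal inverts the ratio
  cn_sw <- copy_number_ratio(ct, "SPP1", "GAPDH",
                             data.frame(tumor = c("n1", "n2"),
                                        normal = c("t1", "t2")))
  expect_equal(cn_sw$ratio, 1 / cn$ratio)
  expect_error(copy_number_ratio(ct, "SPP1", "GAPDH",
                                 data.frame(tumor = "t1", normal = "nX")),
               "nX")
})

test_that("a simulated diploid cohort is called unchanged in >= 90% of pairs", {
  cfg <- sim_config(seed = 9, ct_noise_sd = 0.2, n_replicates = 2L)
  n_pairs <- 40
  q <- rep(500, 2 * n_pairs)
  names(q) <- c(sprintf("t%02d", 1:n_pairs), sprintf("n%02d", 1:n_pairs))
  Q <- cbind(SPP1 = q, GAPDH = rep(1000, length(q)))
  rownames(Q) <- names(q)
  ct <- simulate_ct(Q, cfg, references = character(0),
                    roles = c(SPP1 = "target", GAPDH = "internal_control"))
  cn <- copy_number_ratio(ct, "SPP1", "GAPDH",
                          data.frame(tumor = sprintf("t%02d", 1:n_pairs),
                                     normal = sprintf("n%02d", 1:n_pairs)))
  expect_gte(mean(cn$status == "unchanged"), 0.9)
})

test_that("class comparison separates a configured tumor shift and honors degenerate classes", {
  cfg <- sim_config(n_per_class = 50, classes = c("Normal", "BE", "EAC_II"),
                    seed = 1, sample_factor_sd = 1)
  sim <- simulate_cohort(cfg)
  ct <- simulate_ct(setNames(attr(sim$truth, "total"),
                             rownames(sim$truth)), cfg)
  f <- ddct_fold_change(ct, "SPP1", REFS,
                        calibrator = sim$labels$sample[sim$labels$class ==
                                                         "Normal"])
  cc <- compare_classes(f, sim$labels)
  eac_ref <- cc$tests[cc$tests$class_a == "EAC_II" &
                        cc$tests$class_b == "<reference>", ]
  expect_lt(eac_ref$p_value, 0.01)
  ## recovered class effect close to the configured +3 log2 shift
  s <- cc$summary
  expect_equal(s$mean[s$class == "EAC_II"] -
                 mean(c(s$mean[s$class == "Normal"], s$mean[s$class == "BE"])),
               3, tolerance = 0.3)
  ## identical classes compare to p ~= 1
  labels_same <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                            class = c("Normal", "Normal", "BE", "BE"))
  folds_same <- structure(data.frame(sample = labels_same$sample,
                                     fold = c(1, 2, 1, 2)),
                          class = c("fold_change", "data.frame"))
  cc2 <- compare_classes(folds_same, labels_same)
  expect_equal(cc2$tests$p_value[cc2$tests$class_a == "Normal" &
                                   cc2$tests$class_b == "BE"], 1,
               tolerance = 1e-9)
  ## zero-variance equal-mean classes -> p = 1 by convention
  folds_const <- structure(data.frame(sample = labels_same$sample,
                                      fold = c(2, 2, 2, 2)),
                           class = c("fold_change", "data.frame"))
  cc3 <- compare_classes(folds_const, labels_same)
  expect_equal(cc3$tests$p_value, rep(1, nrow(cc3$tests)))
  ## degenerate (n=1) classes are flagged and skipped in tests
  labels_deg <- data.frame(sample = c("a1", "a2", "b1", "b2", "c1"),
                           class = c("Normal", "Normal", "BE", "BE",
                                     "EAC_IV"))
  folds_deg <- structure(data.frame(sample = labels_deg$sample,
                                    fold = c(1, 2, 1, 2, 9)),
                         class = c("fold_change", "data.frame"))
  cc4 <- compare_classes(folds_deg, labels_deg)
  expect_true(cc4$summary$degenerate[cc4$summary$class == "EAC_IV"])
  expect_false("EAC_IV" %in% c(cc4$tests$class_a, cc4$tests$class_b))
})

test_that("caller sensitivity is high under the configured 8-fold tumor shift", {
  cfg <- sim_config(n_per_class = 40,
                    classes = c("Normal", "BE", "EAC_II"),
                    sample_factor_sd = 0.25, seed = 2)
  sim <- simulate_cohort(cfg)
  ct <- simulate_ct(setNames(attr(sim$truth, "total"),
                             rownames(sim$truth)), cfg)
  f <- ddct_fold_change(ct, "SPP1", REFS,
                        calibrator = sim$labels$sample[sim$labels$class ==
                                                         "Normal"])
  calls <- call_overexpression(f, sim$labels)
  sens <- mean(calls$called[calls$class == "EAC_II"])
  expect_gte(sens, 0.9)
})
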