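test_that("large cohorts reproduce the class marginals", {
  params <- cohortParams()
  tab <- sampleFeatures(params, 5000, 2000, seed = 1)
  ctrl <- tab[tab$class == "control", ]
  ## repeated rows of one subject are correlated, so the effective standard
  ## error carries the design effect 1 + (m - 1) * icc
  deff <- sqrt(1 + (541 / 162 - 1) * 0.85)
  expect_lt(abs(mean(ctrl$hi_interval_ms) - 65),
            3 * deff * 12 / sqrt(5000) + 0.3)
  expect_lt(abs(sd(ctrl$hi_interval_ms) - 12), 1)
  chf <- tab[tab$class == "CHF", ]
  expect_lt(abs(mean(chf$im_interval_ms) - 260),
            3 * deff * 37 / sqrt(2000) + 1.5)
  b <- cohortParams()@bounds
  for (k in seq_len(ncol(b))) {
    v <- tab[[colnames(b)[k]]]
    expect_true(all(v >= b["lower", k] & v <= b["upper", k]))
  }
})

test_that("the latent loading sets the inter-feature correlation", {
  t0 <- sampleFeatures(cohortParams(latentLoading = 0), 3000, 10, seed = 2)
  c0 <- t0[t0$class == "control", ]
  expect_lt(abs(cor(c0$hi_interval_ms, c0$mn_amp_v)), 0.05)
  t5 <- sampleFeatures(cohortParams(latentLoading = 0.5), 3000, 10, seed = 3)
  c5 <- t5[t5$class == "control", ]
  for (pair in list(c("hi_interval_ms", "mn_amp_v"),
                    c("im_interval_ms", "ij_slope_vps"),
                    c("hi_amp_v", "mn_slope_vps")))
    expect_lt(abs(cor(c5[[pair[1]]], c5[[pair[2]]]) - 0.5), 0.07)
})

test_that("cohort sampling is deterministic and repeated-measures structured", {
  a <- sampleFeatures(cohortParams(), 100, 60, seed = 11)
  b <- sampleFeatures(cohortParams(), 100, 60, seed = 11)
  expect_identical(a, b)
  expect_lt(length(unique(a$subject_id)), nrow(a))
  ## within-subject correlation close to the configured ICC
  big <- sampleFeatures(cohortParams(), 4000, 10, seed = 12)
  ctrl <- big[big$class == "control", ]
  v_tot <- var(ctrl$hi_interval_ms)
  v_btw <- var(tapply(ctrl$hi_interval_ms, ctrl$subject_id, mean))
  expect_lt(abs(v_btw / v_tot - 0.85), 0.1)
})

test_that("group comparison flags the published CHF directions", {
  tab <- sampleFeatures(cohortParams(), 101, 61, seed = 5)
  cmp <- groupCompare(tab)
  ivct <- cmp[cmp$feature == "hi_interval_ms", ]
  expect_lt(ivct$p_value, 0.001)
  expect_identical(ivct$direction, "up")
  lvet <- cmp[cmp$feature == "im_interval_ms", ]
  expect_lt(lvet$p_value, 0.001)
  expect_identical(lvet$direction, "down")
  ivrt <- cmp[cmp$feature == "mn_interval_ms", ]
  expect_lt(ivrt$p_value, 0.001)
  expect_identical(ivrt$direction, "up")
  expect_error(groupCompare(tab[tab$class == "CHF", ]), "two classes")
})

test_that("identical class distributions rarely reach p < 0.001", {
  par_null <- cohortParams()
  par_null@means["control", ] <- par_null@means["chf", ]
  par_null@sds["control", ] <- par_null@sds["chf", ]
  any_sig <- vapply(1:100, function(s) {
    tab <- sampleFeatures(par_null, 101, 61, seed = 1000 + s)
    any(groupCompare(tab)$p_value < 0.001)
  }, logical(1))
  expect_gte(mean(!any_sig), 0.95)
})

test_that("Welch t matches the hand formula on a toy table", {
  x <- c(1, 2, 4)
  y <- c(3, 5, 6, 9)
  tab <- data.frame(class = factor(rep(c("control", "CHF"), c(3, 4)),
                                   levels = c("control", "CHF")),
                    hi_interval_ms = c(x, y))
  cmp <- groupCompare(tab)
  se <- sqrt(var(x) / 3 + var(y) / 4)
  expect_equal(cmp$t_statistic, (mean(y) - mean(x)) / se)
})

test_that("a separable toy cohort is classified perfectly by all models", {
  set.seed(1)
  n <- 30
  ## discrete within-class levels: every test value also occurs in training,
  ## so split-point tie-breaking cannot push a boundary inside a class
  mk <- function(center) as.data.frame(
    matrix(center + sample(c(-0.1, 0, 0.1), n * 9, replace = TRUE), n, 9,
           dimnames = list(NULL, bcgcycle:::FEATURE_NAMES)))
  tab <- rbind(cbind(class = "control", mk(0)), cbind(class = "CHF", mk(10)))
  tab$class <- factor(tab$class, levels = c("control", "CHF"))
  for (m in c("LR", "SVM", "KNN", "DTC", "RF", "XGBoost")) {
    cv <- crossvalClassify(tab, m, k = 5, seed = 1)
    expect_equal(cv@summary$mean[cv@summary$metric == "accuracy"], 1,
                 label = m)
  }
  expect_error(crossvalClassify(tab, "MLP"), "unknown model")
})

test_that("permuted labels score near the majority-class rate", {
  tab <- sampleFeatures(cohortParams(), 60, 40, seed = 6)
  accs <- vapply(1:20, function(s) {
    set.seed(5000 + s)
    tab$class <- sample(tab$class)
    cv <- crossvalClassify(tab, "LR", k = 5, seed = s)
    cv@summary$mean[cv@summary$metric == "accuracy"]
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.6), 0.1)
})

test_that("reported metrics equal brute-force computation from counts", {
  tab <- sampleFeatures(cohortParams(), 40, 30, seed = 7)
  cv <- crossvalClassify(tab, "KNN", k = 5, seed = 2)
  f <- cv@folds
  expect_equal(f$accuracy, (f$tp + f$tn) / (f$tp + f$tn + f$fp + f$fn))
  expect_equal(f$sensitivity, f$tp / (f$tp + f$fn))
  expect_equal(f$specificity, f$tn / (f$tn + f$fp))
  expect_equal(f$f1, 2 * f$tp / (2 * f$tp + f$fp + f$fn))
  expect_true(all(f[, c("accuracy", "auc", "sensitivity", "specificity",
                        "f1")] >= 0 &
                    f[, c("accuracy", "auc", "sensitivity", "specificity",
                          "f1")] <= 1))
})

test_that("standardization is fitted on training rows only", {
  set.seed(3)
  xtr <- matrix(rnorm(50 * 9), 50, 9)
  fit <- bcgcycle:::.std_fit(xtr)
  expect_equal(fit$center, colMeans(xtr))
  xte <- matrix(rnorm(10 * 9), 10, 9)
  xte[1, ] <- 1e6  # test-only outlier
  fit2 <- bcgcycle:::.std_fit(xtr)
  expect_identical(fit, fit2)
  scaled <- bcgcycle:::.std_apply(xte, fit)
  expect_equal(scaled[2, ], (xte[2, ] - fit$center) / fit$scale,
               ignore_attr = TRUE)
})

test_that("grouped cross-validation keeps subjects in one fold", {
  tab <- sampleFeatures(cohortParams(), 80, 50, seed = 8)
  cls <- factor(tab$class, levels = c("control", "CHF"))
  sid <- as.character(tab$subject_id)
  subj <- !duplicated(sid)
  sf <- bcgcycle:::.stratified_folds(droplevels(cls[subj]), 5, 1)
  fold <- sf[match(sid, sid[subj])]
  expect_true(all(tapply(fold, sid, function(v) length(unique(v))) == 1))
  cv <- crossvalClassify(tab, "LR", k = 5, seed = 1, grouped = TRUE)
  expect_s4_class(cv, "CVMetrics")
})

test_that("larger class separation never lowers LR accuracy", {
  base <- cohortParams()
  wide <- cohortParams()
  wide@means["chf", ] <- base@means["control", ] +
    1.5 * (base@means["chf", ] - base@means["control", ])
  acc <- function(p) {
    tab <- sampleFeatures(p, 120, 80, seed = 9)
    cv <- crossvalClassify(tab, "LR", k = 5, seed = 9)
    cv@summary$mean[cv@summary$metric == "accuracy"]
  }
  expect_gte(acc(wide), acc(base))
})
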