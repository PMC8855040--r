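# small synthetic feature table builder (feature level, no signal pipeline)
make_feature_df <- function(n_young = 32, n_old = 18, informative = 0,
                            seed = 1) {
  set.seed(seed)
  n <- n_young + n_old
  group <- rep(c("younger", "older"), c(n_young, n_old))
  chans <- montage_16()
  df <- data.frame(subject_id = sprintf("S%03d", 1:n), group = group,
                   stringsAsFactors = FALSE)
  for (p in c("c1", "absc2", "entropy", "ns_alpha")) {
    block <- matrix(rnorm(n * 16), n)
    if (informative > 0 && p %in% c("c1", "entropy")) {
      block <- block + informative * (group == "older")
    }
    colnames(block) <- paste0(p, "_", chans)
    df <- cbind(df, block)
  }
  df
}

test_that("feature assembly selects blocks and standardizes columns", {
  df <- make_feature_df()
  af <- assemble_features(df, feature_set_spec("c1", "c1"))
  expect_identical(dim(af$x), c(50L, 16L))
  expect_identical(sum(af$y), 18L)
  expect_true(all(abs(colMeans(af$x)) < 1e-12))
  expect_equal(unname(apply(af$x, 2, sd)), rep(1, 16))

  af2 <- assemble_features(df, feature_set_spec("two", c("c1", "NS_alpha")))
  expect_identical(ncol(af2$x), 32L)

  dfc <- df; dfc$c1_Fp1 <- 1
  expect_error(assemble_features(dfc, feature_set_spec("c1", "c1")),
               "constant")
  expect_error(feature_set_spec("bad", "nope"), "subset")
})

test_that("rank AUC agrees with the trapezoidal ROC (pROC) exactly", {
  set.seed(91)
  for (i in 1:10) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(40) + y
    expect_equal(auc_score(y, s),
                 as.numeric(pROC::auc(y, s, quiet = TRUE, direction = "<")))
  }
  expect_identical(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_identical(auc_score(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0)
})

test_that("repeated-CV AUC hits the endpoint cases", {
  # near-duplicate labels: perfect discrimination
  df <- make_feature_df(informative = 100, seed = 2)
  af <- assemble_features(df, feature_set_spec("c1", "c1"))
  r <- cv_auc(af$x, af$y, repeats = 5, seed = 1)
  expect_gt(r$auc_mean, 0.99)

  # uninformative features: chance-level
  df0 <- make_feature_df(informative = 0, seed = 3)
  af0 <- assemble_features(df0, feature_set_spec("c1", "c1"))
  r0 <- cv_auc(af0$x, af0$y, repeats = 10, seed = 1)
  expect_lt(abs(r0$auc_mean - 0.5), 0.12)

  # seeded determinism
  r1 <- cv_auc(af0$x, af0$y, repeats = 5, seed = 7)
  r2 <- cv_auc(af0$x, af0$y, repeats = 5, seed = 7)
  expect_identical(r1$per_repeat_auc, r2$per_repeat_auc)
  expect_length(r1$per_repeat_auc, 5)
  expect_error(cv_auc(af0$x[1:6, ], af0$y[1:6], folds = 5), "per class")
})

test_that("PCA is fitted without any test-fold row (no leakage)", {
  df <- make_feature_df(seed = 4)
  af <- assemble_features(df, feature_set_spec("c1", "c1"))
  r <- cv_auc(af$x, af$y, repeats = 3, seed = 2)
  for (rep_log in r$fit_log) {
    tested <- sort(unlist(lapply(rep_log, `[[`, "test")))
    expect_identical(tested, seq_along(af$y)) # every row tested exactly once
    for (fold in rep_log) {
      expect_length(intersect(fold$train, fold$test), 0)
      expect_identical(sort(c(fold$train, fold$test)), seq_along(af$y))
    }
  }
})

test_that("stratified folds keep both classes in every fold", {
  set.seed(92)
  y <- rep(c(0, 1), c(32, 18))
  for (i in 1:20) {
    fold <- eegcomplexity:::stratified_folds(y, 5)
    tab <- table(fold, y)
    expect_true(all(tab > 0))
  }
})

test_that("paired AUC comparison behaves at the boundaries", {
  df <- make_feature_df(informative = 1, seed = 5)
  af <- assemble_features(df, feature_set_spec("c1", "c1"))
  r <- cv_auc(af$x, af$y, repeats = 5, seed = 3)
  same <- compare_auc(r, r)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)

  af2 <- assemble_features(df, feature_set_spec("ns", "NS_alpha"))
  r2 <- cv_auc(af2$x, af2$y, repeats = 5, seed = 3)
  ab <- compare_auc(r, r2)
  ba <- compare_auc(r2, r)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  r3 <- cv_auc(af2$x, af2$y, repeats = 4, seed = 3)
  expect_error(compare_auc(r, r3), "repeat counts")
})

test_that("combining an informative with an uninformative block helps", {
  set.seed(93)
  wins <- replicate(30, {
    df <- make_feature_df(informative = 1.2, seed = sample.int(1e6, 1))
    a <- assemble_features(df, feature_set_spec("c", c("c1", "NS_alpha")))
    b <- assemble_features(df, feature_set_spec("n", "NS_alpha"))
    ra <- cv_auc(a$x, a$y, repeats = 3, seed = 11)
    rb <- cv_auc(b$x, b$y, repeats = 3, seed = 11)
    ra$auc_mean >= rb$auc_mean
  })
  expect_gte(mean(wins), 0.9)
})

test_that("decision regions are monotone in the threshold and well formed", {
  df <- make_feature_df(informative = 2, seed = 6)
  af <- assemble_features(df, feature_set_spec("c1", "c1"))
  dr9 <- decision_region(af$x, af$y, axis_x = 1, axis_y = 2,
                         grid_resolution = 41, threshold = 0.9)
  dr5 <- decision_region(af$x, af$y, axis_x = 1, axis_y = 2,
                         grid_resolution = 41, threshold = 0.5)
  expect_identical(dim(dr9$mask), c(41L, 41L))
  # 0.9 region nested inside 0.5 region
  expect_true(all(dr5$mask[dr9$mask]))
  expect_true(any(dr9$mask)) # strongly separable toy has a region
  # logistic linearity: the 0.5 boundary is a straight line in PC space ->
  # each grid column's region is contiguous
  runs <- apply(dr9$mask, 2, function(col) sum(abs(diff(col))))
  expect_true(all(runs <= 2))

  # single-class labels: empty region
  dr0 <- decision_region(af$x, rep(0L, nrow(af$x)), axis_x = 1, axis_y = 2,
                         grid_resolution = 21)
  expect_false(any(dr0$mask))
  expect_error(decision_region(af$x, af$y, axis_x = 1, axis_y = 9), "axes")
})
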