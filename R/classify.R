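#' Feature-set specification for classification
#'
#' Named selection of feature blocks entering the PCA + logistic-regression
#' classifier, mirroring the single-index and combined models compared in
#' the analysis: `c1`, `abs_c2`, `fast_entropy`, and node strength per band
#' (`NS_delta` ... `NS_gamma`).
#'
#' @param name label for reporting.
#' @param blocks character subset of
#'   `c("c1", "abs_c2", "fast_entropy", "NS_delta", "NS_theta", "NS_alpha",
#'   "NS_beta", "NS_gamma")`.
#' @param n_components principal components kept (default 3: components 1-3).
#' @return list of class `feature_set_spec`.
#' @export
feature_set_spec <- function(name, blocks, n_components = 3L) {
  valid <- c("c1", "abs_c2", "fast_entropy",
             paste0("NS_", c("delta", "theta", "alpha", "beta", "gamma")))
  if (length(blocks) == 0 || !all(blocks %in% valid)) {
    stop("blocks must be a non-empty subset of: ", paste(valid, collapse = ", "))
  }
  structure(list(name = name, blocks = blocks,
                 n_components = as.integer(n_components)),
            class = "feature_set_spec")
}

block_prefix <- function(block) {
  switch(block,
    c1 = "c1_", abs_c2 = "absc2_", fast_entropy = "entropy_",
    paste0("ns_", tolower(sub("NS_", "", block)), "_")
  )
}

#' Assemble the classifier design matrix from a feature table
#'
#' Selects the requested blocks' columns, column-standardizes them, and
#' encodes labels older = 1, younger = 0.
#'
#' @param features data.frame from [feature_table()].
#' @param spec a [feature_set_spec()].
#' @return list with `x` (standardized subject x feature matrix), `y`
#'   (0/1 integer labels), `feature_names`.
#' @export
assemble_features <- function(features, spec) {
  stopifnot(inherits(spec, "feature_set_spec"))
  if (anyNA(features$group)) {
    stop("missing group labels for subjects: ",
         paste(features$subject_id[is.na(features$group)], collapse = ", "))
  }
  cols <- unlist(lapply(spec$blocks, function(b) {
    sel <- grep(paste0("^", block_prefix(b)), names(features), value = TRUE)
    if (length(sel) == 0) stop("no columns found for block '", b, "'")
    sel
  }))
  x <- as.matrix(features[, cols, drop = FALSE])
  if (anyNA(x)) {
    bad <- features$subject_id[apply(x, 1, anyNA)]
    stop("missing feature values for subjects: ", paste(bad, collapse = ", "))
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature columns: ",
         paste(cols[sds == 0], collapse = ", "))
  }
  x <- scale(x)
  list(x = x, y = as.integer(features$group == "older"),
       feature_names = cols)
}

#' Rank-based AUC of predicted probabilities
#'
#' Mann-Whitney formulation (ties by average ranks), identical to the area
#' under the empirical ROC curve with trapezoidal tie handling.
#'
#' @param labels 0/1 vector.
#' @param scores predicted probabilities (or any monotone scores).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified k-fold assignment; every fold gets members of each class
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_pca_logistic <- function(x_train, y_train, n_components, lambda) {
  ncomp <- min(n_components, ncol(x_train), nrow(x_train) - 1L)
  pca <- stats::prcomp(x_train, center = TRUE, scale. = TRUE)
  z_train <- pca$x[, seq_len(ncomp), drop = FALSE]
  fit <- glmnet::glmnet(z_train, y_train, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  list(pca = pca, fit = fit, ncomp = ncomp, lambda = lambda)
}

predict_pca_logistic <- function(model, x_new) {
  z <- stats::predict(model$pca, x_new)[, seq_len(model$ncomp), drop = FALSE]
  as.numeric(stats::predict(model$fit, z, type = "response"))
}

#' Repeated cross-validated AUC of the PCA + logistic classifier
#'
#' For each of `repeats` trials: a fresh stratified `folds`-fold split; in
#' each fold, PCA is fitted on the training folds only (no test rows touch
#' the fit — the returned `fit_log` records the rows used) and a
#' ridge-regularized logistic regression (fixed `lambda = 1/n`) is fitted on
#' the leading `n_components` scores; held-out predicted probabilities are
#' pooled across the 5 folds into a single ROC, giving one AUC per repeat.
#' Mean and SD are taken over the repeat AUCs.
#'
#' @param x standardized feature matrix (from [assemble_features()]).
#' @param y 0/1 labels (older = 1).
#' @param n_components principal components kept (default 3).
#' @param repeats number of CV repetitions (default 20).
#' @param folds folds per repetition (default 5).
#' @param seed integer; repeat `i` uses stream `seed + i` so results are
#'   reproducible and pairable across feature sets.
#' @param name label stored in the result.
#' @return object of class `roc_result`: `auc_mean`, `auc_sd`,
#'   `per_repeat_auc`, `folds`, `repeats`, `seed`, `name`, `fit_log`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(50 * 4), 50)
#' y <- rep(c(0, 1), c(30, 20))
#' cv_auc(x, y, repeats = 3, seed = 1)$auc_mean
cv_auc <- function(x, y, n_components = 3L, repeats = 20L, folds = 5L,
                   seed = 1L, name = "features") {
  x <- as.matrix(x)
  y <- as.integer(y)
  counts <- table(factor(y, levels = c(0, 1)))
  if (min(counts) < folds) stop("need at least `folds` subjects per class")
  old_rng <- get_rng_state()
  on.exit(restore_rng_state(old_rng))
  lambda <- 1 / nrow(x)
  per_repeat <- numeric(repeats)
  fit_log <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    set.seed(seed + rep_i)
    fold <- stratified_folds(y, folds)
    prob <- numeric(length(y))
    logs <- vector("list", folds)
    for (f in seq_len(folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      model <- fit_pca_logistic(x[train, , drop = FALSE], y[train],
                                n_components, lambda)
      prob[test] <- predict_pca_logistic(model, x[test, , drop = FALSE])
      logs[[f]] <- list(fold = f, train = train, test = test)
    }
    per_repeat[rep_i] <- auc_score(y, prob)
    fit_log[[rep_i]] <- logs
  }
  structure(
    list(auc_mean = mean(per_repeat), auc_sd = stats::sd(per_repeat),
         per_repeat_auc = per_repeat, folds = folds, repeats = repeats,
         seed = seed, name = name, n_components = n_components,
         fit_log = fit_log),
    class = "roc_result"
  )
}

#' @exportS3Method base::print
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s: AUC %.3f (SD %.3f) over %d x %d-fold CV\n",
              x$name, x$auc_mean, x$auc_sd, x$repeats, x$folds))
  invisible(x)
}

#' Paired comparison of two repeated-CV AUC results
#'
#' Paired t-test across the per-repeat AUCs (pairing by repeat index; both
#' results must come from the same cohort, repeats and seed so the CV splits
#' pair up). Degenerate zero-variance differences return `t = 0, p = 1`
#' when the means agree.
#'
#' @param a,b `roc_result` objects.
#' @return list with `t`, `p`, `mean_diff` (a minus b), `df`.
#' @export
compare_auc <- function(a, b) {
  stopifnot(inherits(a, "roc_result"), inherits(b, "roc_result"))
  if (a$repeats != b$repeats) {
    stop("repeat counts differ (", a$repeats, " vs ", b$repeats, ")")
  }
  d <- a$per_repeat_auc - b$per_repeat_auc
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t_val <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    t_val <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(abs(t_val), df = n - 1, lower.tail = FALSE)
  }
  list(t = t_val, p = p, mean_diff = mean(d), df = n - 1)
}

#' Decision region of the classifier over a principal-component plane
#'
#' Fits PCA and the ridge-logistic model on the full standardized feature
#' matrix, then evaluates the predicted probability of "older" over a grid
#' on two chosen components, all remaining components held at their grand
#' means (zero, by PCA centering). The region is where the probability
#' exceeds `threshold` (0.9).
#'
#' @param x standardized feature matrix.
#' @param y 0/1 labels.
#' @param n_components components in the model (default 3).
#' @param axis_x,axis_y component indices spanning the plane (must be kept
#'   components).
#' @param grid_resolution points per axis.
#' @param threshold probability cut (default 0.9).
#' @param expand fractional range expansion beyond the observed scores.
#' @return object of class `decision_region`: `grid_x`, `grid_y`, `prob`
#'   (matrix), `mask` (`prob > threshold`), `axis_x`, `axis_y`, `threshold`.
#' @export
decision_region <- function(x, y, n_components = 3L, axis_x = 1L, axis_y = 2L,
                            grid_resolution = 101L, threshold = 0.9,
                            expand = 0.25) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    # degenerate single-class fit: constant predicted probability
    pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
    ncomp <- min(n_components, ncol(x), nrow(x) - 1L)
    scores <- pca$x[, seq_len(ncomp), drop = FALSE]
    gx <- seq(min(scores[, axis_x]), max(scores[, axis_x]),
              length.out = grid_resolution)
    gy <- seq(min(scores[, axis_y]), max(scores[, axis_y]),
              length.out = grid_resolution)
    p0 <- unique(y)[1]
    prob <- matrix(p0, grid_resolution, grid_resolution)
    return(structure(
      list(grid_x = gx, grid_y = gy, prob = prob, mask = prob > threshold,
           axis_x = axis_x, axis_y = axis_y, threshold = threshold),
      class = "decision_region"
    ))
  }
  model <- fit_pca_logistic(x, y, n_components, 1 / nrow(x))
  if (max(axis_x, axis_y) > model$ncomp) {
    stop("axes must be among the ", model$ncomp, " retained components")
  }
  scores <- model$pca$x[, seq_len(model$ncomp), drop = FALSE]
  rng <- function(v) {
    r <- range(v); span <- diff(r)
    c(r[1] - expand * span, r[2] + expand * span)
  }
  gx <- seq(rng(scores[, axis_x])[1], rng(scores[, axis_x])[2],
            length.out = grid_resolution)
  gy <- seq(rng(scores[, axis_y])[1], rng(scores[, axis_y])[2],
            length.out = grid_resolution)
  base <- colMeans(scores) # grand means (zero up to numerical precision)
  grid <- as.matrix(expand.grid(gx = gx, gy = gy))
  z <- matrix(rep(base, each = nrow(grid)), nrow(grid), model$ncomp)
  z[, axis_x] <- grid[, "gx"]
  z[, axis_y] <- grid[, "gy"]
  prob <- matrix(
    as.numeric(stats::predict(model$fit, z, type = "response")),
    nrow = grid_resolution, ncol = grid_resolution
  )
  structure(
    list(grid_x = gx, grid_y = gy, prob = prob, mask = prob > threshold,
         axis_x = axis_x, axis_y = axis_y, threshold = threshold),
    class = "decision_region"
  )
}
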