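#' Benjamini-Hochberg significance mask
#'
#' Step-up FDR control at level `q` over one comparison family: a p-value is
#' significant iff its BH-adjusted value is at most `q`.
#'
#' @param p vector of raw p-values (one family).
#' @param q FDR level (default 0.05).
#' @return logical mask, same length as `p`.
#' @export
bh_significant <- function(p, q = 0.05) {
  stats::p.adjust(p, method = "BH") <= q
}

# orthonormal basis of the contrast space of a factor with `a` levels
contrast_basis <- function(a) {
  qr.Q(qr(cbind(1, stats::contr.helmert(a))))[, -1, drop = FALSE]
}

# Greenhouse-Geisser epsilon for the effect whose (orthonormal) contrast
# matrix over the within-cells is M, from the group-pooled covariance of the
# subject x cells response matrix.
gg_epsilon <- function(Y, group, M) {
  group <- as.factor(group)
  S <- matrix(0, ncol(Y), ncol(Y))
  df <- 0
  for (g in levels(group)) {
    Yg <- Y[group == g, , drop = FALSE]
    if (nrow(Yg) > 1) {
      S <- S + stats::cov(Yg) * (nrow(Yg) - 1)
      df <- df + nrow(Yg) - 1
    }
  }
  S <- S / df
  E <- t(M) %*% S %*% M
  d <- ncol(M)
  eps <- sum(diag(E))^2 / (d * sum(E^2))
  min(max(eps, 1 / d), 1)
}

extract_stratum <- function(aov_summary, stratum, effect) {
  tab <- aov_summary[[stratum]][[1]]
  rn <- trimws(rownames(tab))
  i <- match(effect, rn)
  resid <- match("Residuals", rn)
  if (is.na(i) || is.na(resid)) {
    stop("effect '", effect, "' not found in stratum ", stratum)
  }
  list(
    ss = tab[i, "Sum Sq"], df1 = tab[i, "Df"],
    ss_err = tab[resid, "Sum Sq"], df2 = tab[resid, "Df"],
    F = tab[i, "F value"]
  )
}

anova_row <- function(effect, st, epsilon) {
  df1 <- st$df1 * epsilon
  df2 <- st$df2 * epsilon
  data.frame(
    effect = effect,
    F = st$F,
    p = stats::pf(st$F, df1, df2, lower.tail = FALSE),
    partial_eta2 = st$ss / (st$ss + st$ss_err),
    df1 = df1, df2 = df2, epsilon = epsilon,
    stringsAsFactors = FALSE
  )
}

#' Mixed-design repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Split-plot ANOVA with one between-subjects factor (group) and one or two
#' within-subject factors (electrode, and optionally temporal scale). All
#' within cells must be present for every subject (balanced within design;
#' unequal group sizes are fine). Within-effect degrees of freedom and
#' p-values are Greenhouse-Geisser corrected, with epsilon computed per
#' effect from the pooled within-group covariance of the contrast-transformed
#' responses; the between-group effect needs no sphericity correction.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)` using the
#' error stratum of each effect.
#'
#' @param values subject x cells numeric matrix. For two within factors the
#'   columns must be nested with the first factor slowest (all levels of the
#'   second factor for level 1 of the first, and so on).
#' @param group factor/character of group labels, one per subject.
#' @param within named list of within-factor level counts, e.g.
#'   `list(node = 16)` or `list(node = 16, scale = 30)`.
#' @param covariate optional subject-level numeric covariate; when given, the
#'   between-subjects (group) effect is adjusted for it (sequential sums of
#'   squares, covariate entered first).
#' @return data.frame with one row per effect: `effect`, `F`, `p`,
#'   `partial_eta2`, `df1`, `df2` (corrected), `epsilon`.
#' @export
mixed_anova <- function(values, group, within, covariate = NULL) {
  Y <- as.matrix(values)
  group <- as.factor(group)
  if (nrow(Y) != length(group)) stop("one group label per subject required")
  if (anyNA(Y)) {
    bad <- which(apply(Y, 1, anyNA))
    stop("missing cells for subject rows: ", paste(bad, collapse = ", "))
  }
  sizes <- vapply(within, as.integer, 1L)
  if (prod(sizes) != ncol(Y)) {
    stop("within-level product (", prod(sizes),
         ") does not match column count (", ncol(Y), ")")
  }
  if (!is.null(covariate)) {
    if (length(covariate) != nrow(Y)) stop("one covariate value per subject")
    if (stats::sd(covariate) == 0) stop("covariate has zero variance")
  }
  n <- nrow(Y)
  nf <- length(sizes)
  f1 <- names(sizes)[1]
  subject <- factor(rep(seq_len(n), times = ncol(Y)))
  gvec <- rep(group, times = ncol(Y))
  if (nf == 1) {
    w1 <- factor(rep(seq_len(sizes[1]), each = n))
    dat <- data.frame(y = as.vector(Y), subject, group = gvec, w1 = w1)
    if (is.null(covariate)) {
      fit <- stats::aov(y ~ group * w1 + Error(subject / w1), data = dat)
    } else {
      dat$cov <- rep(covariate, times = ncol(Y))
      fit <- stats::aov(y ~ cov + group * w1 + Error(subject / w1), data = dat)
    }
    sm <- summary(fit)
    eps1 <- gg_epsilon(Y, group, contrast_basis(sizes[1]))
    rbind(
      anova_row("group", extract_stratum(sm, "Error: subject", "group"), 1),
      anova_row(paste0("group:", f1),
                extract_stratum(sm, "Error: subject:w1", "group:w1"), eps1)
    )
  } else if (nf == 2) {
    f2 <- names(sizes)[2]
    a <- sizes[1]; b <- sizes[2]
    # columns nested: first factor slowest
    w1 <- factor(rep(rep(seq_len(a), each = b), each = n))
    w2 <- factor(rep(rep(seq_len(b), times = a), each = n))
    dat <- data.frame(y = as.vector(Y), subject, group = gvec,
                      w1 = w1, w2 = w2)
    if (is.null(covariate)) {
      fit <- stats::aov(y ~ group * w1 * w2 + Error(subject / (w1 * w2)),
                        data = dat)
    } else {
      dat$cov <- rep(covariate, times = ncol(Y))
      fit <- stats::aov(y ~ cov + group * w1 * w2 + Error(subject / (w1 * w2)),
                        data = dat)
    }
    sm <- summary(fit)
    M1 <- contrast_basis(a); M2 <- contrast_basis(b)
    j1 <- matrix(1 / sqrt(a), a, 1); j2 <- matrix(1 / sqrt(b), b, 1)
    eps1 <- gg_epsilon(Y, group, kronecker(M1, j2))
    eps2 <- gg_epsilon(Y, group, kronecker(j1, M2))
    eps12 <- gg_epsilon(Y, group, kronecker(M1, M2))
    rbind(
      anova_row("group", extract_stratum(sm, "Error: subject", "group"), 1),
      anova_row(paste0("group:", f1),
                extract_stratum(sm, "Error: subject:w1", "group:w1"), eps1),
      anova_row(paste0("group:", f2),
                extract_stratum(sm, "Error: subject:w2", "group:w2"), eps2),
      anova_row(paste0("group:", f1, ":", f2),
                extract_stratum(sm, "Error: subject:w1:w2", "group:w1:w2"),
                eps12)
    )
  } else {
    stop("at most two within factors are supported")
  }
}

#' @rdname mixed_anova
#' @param values,group,within as in [mixed_anova()].
#' @export
ancova_covariate <- function(values, group, within, covariate) {
  if (is.null(covariate)) stop("`covariate` is required")
  mixed_anova(values, group, within, covariate = covariate)
}

#' Post-hoc per-cell Welch t-tests with BH-FDR correction
#'
#' One Welch two-sample t-test per column of `values` (the comparison family:
#' e.g. 16 electrodes; 480 electrode x scale cells; 600 electrode-pair x band
#' cells; 80 electrode x band cells), with a single Benjamini-Hochberg mask
#' over the whole family at `q`.
#'
#' @param values subject x comparisons matrix.
#' @param group two-level group labels, one per subject.
#' @param q FDR level (default 0.05).
#' @param expected_family optional integer; error if the family size differs
#'   (guards the family-size bookkeeping).
#' @return list of class `corrected_comparisons`: `t_values`, `raw_p`,
#'   `significant`, `q_threshold`, `family_size`.
#' @export
posthoc_ttests <- function(values, group, q = 0.05, expected_family = NULL) {
  Y <- as.matrix(values)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (!is.null(expected_family) && ncol(Y) != expected_family) {
    stop("comparison family has ", ncol(Y), " members; expected ",
         expected_family)
  }
  # sign convention: t > 0 means higher in the non-reference group
  # (older - younger when those labels are used)
  ref <- if ("younger" %in% levels(group)) "younger" else levels(group)[1]
  g_ref <- group == ref
  tt <- apply(Y, 2, function(col) {
    ht <- stats::t.test(col[!g_ref], col[g_ref]) # Welch by default
    c(t = unname(ht$statistic), p = ht$p.value)
  })
  structure(
    list(t_values = tt["t", ], raw_p = tt["p", ],
         significant = bh_significant(tt["p", ], q),
         q_threshold = q, family_size = ncol(Y)),
    class = "corrected_comparisons"
  )
}

#' Per-channel Spearman correlation between node strength and a complexity index
#'
#' Within one group: Spearman's R (average ranks for ties) between each
#' channel's node strength and its complexity index (c1 or |c2|), with a BH
#' mask over the 16 channels.
#'
#' @param ns subject x channels node-strength matrix (one band).
#' @param index subject x channels complexity-index matrix.
#' @param q FDR level.
#' @return list of class `corrected_comparisons` with `R` (per channel),
#'   `raw_p`, `significant`.
#' @export
spearman_ns_complexity <- function(ns, index, q = 0.05) {
  ns <- as.matrix(ns); index <- as.matrix(index)
  if (!all(dim(ns) == dim(index))) stop("dimension mismatch")
  if (nrow(ns) < 4) stop("need at least 4 subjects")
  res <- vapply(seq_len(ncol(ns)), function(ch) {
    ct <- suppressWarnings(
      stats::cor.test(ns[, ch], index[, ch], method = "spearman")
    )
    c(R = unname(ct$estimate), p = ct$p.value)
  }, numeric(2))
  structure(
    list(R = stats::setNames(res["R", ], colnames(ns)),
         raw_p = res["p", ],
         significant = bh_significant(res["p", ], q),
         q_threshold = q, family_size = ncol(ns)),
    class = "corrected_comparisons"
  )
}
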