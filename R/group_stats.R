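#' Preprocess a cell-by-feature matrix for cross-modal statistics
#'
#' Applies the standard imputation-and-robust-scaling pipeline: cells with
#' more than `max_missing` missing features are dropped; the remaining
#' missing entries are imputed as the mean of the `k` nearest neighbours
#' (distances computed on the robust-scaled complete features, i.e. features
#' observed for every retained cell); features are then centred about the
#' median and scaled by the interquartile range. A zero IQR scales by 1
#' (constant features carry no information either way).
#'
#' @param x Cells x features numeric matrix (NA = missing).
#' @param max_missing Maximum missing features per retained cell.
#' @param k Number of neighbours for imputation.
#' @return List: `x` (imputed, scaled matrix), `kept` (row indices of
#'   retained cells), `center`, `scale`.
#' @export
preprocess_features <- function(x, max_missing = 3, k = 5) {
  x <- as.matrix(x)
  if (nrow(x) < k + 1) stop("need at least k + 1 cells")
  keep <- rowSums(is.na(x)) <= max_missing
  if (!any(keep)) stop("all cells dropped")
  x <- x[keep, , drop = FALSE]
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  iqr <- apply(x, 2, stats::IQR, na.rm = TRUE)
  iqr[iqr == 0 | is.na(iqr)] <- 1
  xs <- sweep(sweep(x, 2, med), 2, iqr, "/")
  complete <- which(colSums(is.na(xs)) == 0)
  if (anyNA(xs)) {
    if (!length(complete))
      stop("no complete features available for neighbour distances")
    d <- as.matrix(stats::dist(xs[, complete, drop = FALSE]))
    diag(d) <- Inf
    for (j in which(colSums(is.na(xs)) > 0)) {
      obs <- which(!is.na(xs[, j]))
      for (i in which(is.na(xs[, j]))) {
        nb <- obs[order(d[i, obs])][seq_len(min(k, length(obs)))]
        xs[i, j] <- mean(xs[nb, j])
      }
    }
  }
  list(x = xs, kept = which(keep), center = med, scale = iqr)
}

#' Depth-gradient regression with robust inference
#'
#' Ordinary least-squares regression of each feature against scaled L2-3
#' depth; significance from the heteroscedasticity-robust (HC3) F test, with
#' Benjamini-Hochberg FDR correction across the feature batch.
#'
#' @param features Cells x features numeric matrix (or a single numeric
#'   vector).
#' @param depth Scaled depth per cell; must vary.
#' @param min_n Minimum paired observations per feature.
#' @return data.frame: `feature`, `n`, `slope`, `r2`, `r`, `p`, `q`.
#' @export
depth_regression <- function(features, depth, min_n = 10) {
  if (is.null(dim(features)))
    features <- matrix(features, ncol = 1,
                       dimnames = list(NULL, "feature"))
  features <- as.matrix(features)
  if (stats::sd(depth, na.rm = TRUE) == 0) stop("zero-variance depth")
  nm <- colnames(features)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(features)))
  res <- lapply(seq_len(ncol(features)), function(j) {
    y <- features[, j]
    ok <- stats::complete.cases(y, depth)
    n <- sum(ok)
    if (n < min_n || stats::sd(y[ok]) == 0)
      return(data.frame(feature = nm[j], n = n, slope = NA_real_,
                        r2 = NA_real_, r = NA_real_, p = NA_real_))
    X <- cbind(1, depth[ok])
    ht <- hc3_f_test(X, y[ok])
    r <- stats::cor(depth[ok], y[ok])
    data.frame(feature = nm[j], n = n, slope = unname(ht$coef[2]),
               r2 = r^2, r = r, p = ht$p)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}

#' One-way ANOVA by cell type with robust inference
#'
#' Effect size as eta-squared (between-group over total sum of squares);
#' p-value from the HC3 robust F test on the group-indicator regression.
#'
#' @param y Feature values.
#' @param labels Group labels (>= 2 groups with >= 3 cells each).
#' @return List: `eta2`, `p`, `n`, `groups`.
#' @export
anova_by_type <- function(y, labels) {
  ok <- stats::complete.cases(y, labels)
  y <- y[ok]; g <- factor(labels[ok])
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 3))
    stop("need >= 2 groups with >= 3 cells each")
  gm <- tapply(y, g, mean)
  ssb <- sum(tab * (gm - mean(y))^2)
  sst <- sum((y - mean(y))^2)
  X <- stats::model.matrix(~g)
  ht <- hc3_f_test(X, y)
  list(eta2 = if (sst > 0) ssb / sst else 0, p = ht$p, n = length(y),
       groups = levels(g))
}

#' Pairwise Mann-Whitney post hocs
#'
#' All pairwise two-sided Mann-Whitney tests between groups for one feature,
#' BH-corrected within the feature. Pairs containing a group with fewer than
#' 2 distinct values are skipped.
#'
#' @inheritParams anova_by_type
#' @return data.frame: `group1`, `group2`, `U`, `p`, `q` (skipped pairs have
#'   `NA` statistics).
#' @export
posthoc_pairs <- function(y, labels) {
  ok <- stats::complete.cases(y, labels)
  y <- y[ok]; g <- factor(labels[ok])
  lv <- levels(g)
  pr <- utils::combn(lv, 2)
  res <- lapply(seq_len(ncol(pr)), function(i) {
    a <- y[g == pr[1, i]]; b <- y[g == pr[2, i]]
    if (length(unique(a)) < 2 || length(unique(b)) < 2)
      return(data.frame(group1 = pr[1, i], group2 = pr[2, i],
                        U = NA_real_, p = NA_real_))
    mw <- mann_whitney(a, b)
    data.frame(group1 = pr[1, i], group2 = pr[2, i], U = mw$U, p = mw$p)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}

#' Pathology comparison with and without a depth covariate
#'
#' Tests a feature against a binary pathology-score bin (low 0-1 versus
#' high 2-3) twice: model 1 regresses the feature on the bin alone, model 2
#' adds scaled depth as a covariate. Both report the HC3 robust p-value of
#' the bin coefficient, exposing effects explained away by imbalanced
#' sampling across depth.
#'
#' @param y Feature values.
#' @param bin Factor or character with two levels (e.g. "low"/"high"); both
#'   bins must be non-empty.
#' @param depth Scaled depth per cell.
#' @return List: `p_unadjusted` (model 1), `p_depth_adjusted` (model 2),
#'   `coef_unadjusted`, `coef_depth_adjusted`, `unstable` (TRUE when the
#'   bins are perfectly confounded with depth).
#' @export
pathology_comparison <- function(y, bin, depth) {
  ok <- stats::complete.cases(y, bin, depth)
  y <- y[ok]; b <- factor(bin[ok]); depth <- depth[ok]
  if (nlevels(b) != 2 || any(table(b) == 0)) stop("both bins must be non-empty")
  z <- as.numeric(b) - 1
  m1 <- hc3_f_test(cbind(1, z), y, which = 2)
  unstable <- FALSE
  if (stats::sd(depth) == 0) {
    # degenerate covariate: model 2 reduces to model 1
    m2 <- m1
  } else if (abs(stats::cor(z, depth)) > 0.999) {
    unstable <- TRUE
    m2 <- list(coef = c(NA, NA, NA), coef_p = c(NA, NA, NA), p = NA_real_)
  } else {
    m2 <- hc3_f_test(cbind(1, z, depth), y, which = 2)
  }
  list(p_unadjusted = unname(m1$coef_p[2]),
       p_depth_adjusted = unname(m2$coef_p[2]),
       coef_unadjusted = unname(m1$coef[2]),
       coef_depth_adjusted = unname(m2$coef[2]),
       unstable = unstable)
}

#' Batch pathology comparison with FDR correction
#'
#' Runs [pathology_comparison()] across feature columns and BH-corrects the
#' two p-value series separately.
#'
#' @param features Cells x features matrix.
#' @param bin,depth As in [pathology_comparison()].
#' @return data.frame: `feature`, `p_unadjusted`, `q_unadjusted`,
#'   `p_depth_adjusted`, `q_depth_adjusted`, `unstable`.
#' @export
pathology_comparison_batch <- function(features, bin, depth) {
  features <- as.matrix(features)
  nm <- colnames(features)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(features)))
  rows <- lapply(seq_len(ncol(features)), function(j) {
    pc <- pathology_comparison(features[, j], bin, depth)
    data.frame(feature = nm[j], p_unadjusted = pc$p_unadjusted,
               p_depth_adjusted = pc$p_depth_adjusted,
               unstable = pc$unstable)
  })
  out <- do.call(rbind, rows)
  out$q_unadjusted <- bh_adjust(out$p_unadjusted)
  out$q_depth_adjusted <- bh_adjust(out$p_depth_adjusted)
  out[, c("feature", "p_unadjusted", "q_unadjusted", "p_depth_adjusted",
          "q_depth_adjusted", "unstable")]
}
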