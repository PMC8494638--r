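#' Variance-stabilized variable-gene ranking
#'
#' Ranks genes by the variance of their log2(CPM+1) values standardized
#' within 20 mean-expression bins (so highly expressed genes do not dominate
#' purely through their mean-variance relationship).
#'
#' @param logcpm Genes x cells log2(CPM+1) matrix.
#' @param n Number of genes to return.
#' @param n_bins Mean-expression bins used for standardization.
#' @return Character vector (or row indices when unnamed) of the top `n`
#'   variable genes, most variable first.
#' @export
variable_genes <- function(logcpm, n = 80, n_bins = 20) {
  if (n > nrow(logcpm)) stop("n exceeds the number of available genes")
  mu <- rowMeans(logcpm)
  v <- apply(logcpm, 1, stats::var)
  bin <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  z <- v
  for (b in unique(bin)) {
    ix <- bin == b
    mv <- mean(v[ix]); sv <- stats::sd(v[ix])
    z[ix] <- if (is.na(sv) || sv == 0) 0 else (v[ix] - mv) / sv
  }
  ids <- if (is.null(rownames(logcpm))) seq_len(nrow(logcpm)) else
    rownames(logcpm)
  ids[order(-z, ids)][seq_len(n)]
}

#' Permutation-calibrated cluster heterogeneity statistic
#'
#' Measures within-cluster structure as the percentage of variance explained
#' by the first principal component of a cells x variable-genes submatrix,
#' against a permutation null in which each gene's values are shuffled
#' independently across cells (breaking gene-gene correlations while
#' preserving every gene's marginal distribution exactly). The procedure:
#' sample `n_cells` cells (with replacement, with a warning, when the cluster
#' is smaller), take the `n_genes` most variable genes ([variable_genes()]),
#' drop outlier cells whose radius in the first two PCs exceeds
#' `outlier_mult` times the median radius (once), and compute PC1 percent
#' variance; repeat on `n_perm` shuffled data sets.
#'
#' @param logcpm Genes x cells log2(CPM+1) matrix for one cluster.
#' @param n_cells,n_genes Subsample sizes (80 each by convention).
#' @param n_perm Number of permutations (0 gives the observed value only).
#' @param seed Integer seed.
#' @param outlier_mult Outlier radius multiplier.
#' @param keep_first_perm Also return the first shuffled cells x genes
#'   matrix (for auditing that permutations preserve gene marginals).
#' @return List: `observed` (percent variance, PC1), `perm_mean`, `perm_sd`,
#'   `perms` (length `n_perm`), `z` (observed minus null mean over null sd);
#'   with `subset` (the observed cells x genes matrix) and, if requested,
#'   `first_perm`.
#' @export
cluster_heterogeneity <- function(logcpm, n_cells = 80, n_genes = 80,
                                  n_perm = 100, seed = 1L,
                                  outlier_mult = 4,
                                  keep_first_perm = FALSE) {
  set.seed(seed)
  nc <- ncol(logcpm)
  if (nc < n_cells) {
    warning("cluster smaller than n_cells; sampling with replacement")
    cells <- sample(nc, n_cells, replace = TRUE)
  } else cells <- sample(nc, n_cells)
  sub <- logcpm[, cells, drop = FALSE]
  if (n_genes > nrow(sub))
    stop("n_genes exceeds the number of available genes")
  vg <- variable_genes(sub, n = n_genes)
  x <- t(sub[vg, , drop = FALSE])          # cells x genes
  observed <- .pc1_pct(x, outlier_mult)
  if (n_perm <= 0)
    return(list(observed = observed, perm_mean = NA_real_,
                perm_sd = NA_real_, perms = numeric(0), z = NA_real_,
                subset = x))
  first_perm <- NULL
  perms <- vapply(seq_len(n_perm), function(p) {
    xp <- apply(x, 2, sample)
    if (p == 1 && keep_first_perm) first_perm <<- xp
    .pc1_pct(xp, outlier_mult)
  }, 0)
  pm <- mean(perms); ps <- stats::sd(perms)
  list(observed = observed, perm_mean = pm, perm_sd = ps, perms = perms,
       z = (observed - pm) / ps, subset = x, first_perm = first_perm)
}

# percent variance explained by PC1 after one round of outlier removal
.pc1_pct <- function(x, outlier_mult) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  r <- sqrt(rowSums(pc$x[, 1:min(2, ncol(pc$x)), drop = FALSE]^2))
  keep <- r <= outlier_mult * stats::median(r)
  if (any(!keep) && sum(keep) > 2)
    pc <- stats::prcomp(x[keep, , drop = FALSE], center = TRUE)
  100 * pc$sdev[1]^2 / sum(pc$sdev^2)
}

#' Cluster discreteness: mean differentially-expressed gene count
#'
#' For a target cluster, counts genes up-regulated against each other cluster
#' after subsampling both to `n_sub` cells, and returns the mean count over
#' pairs. A gene counts for a pair when (1) the log2 fold change of mean CPM
#' (pseudocount 1) is at least `lfc_min`, (2) the expressed proportion in the
#' target is at least `prop_min`, and (3) the relative proportion difference
#' `(p_target - p_other) / max(p_target, p_other)` is at least `rel_min`.
#' Only target-upregulated genes are considered.
#'
#' @param es Labelled `expression_set`.
#' @param target Target cluster label.
#' @param others Other cluster labels (default: all remaining clusters).
#' @param n_sub Subsample size per cluster (sampling with replacement when a
#'   cluster is smaller).
#' @param lfc_min,prop_min,rel_min DE criterion thresholds.
#' @param cpm_threshold Expression threshold for proportions.
#' @param seed Integer seed for the subsampling.
#' @return List: `mean_de` (mean count over pairs), `per_pair` (named
#'   counts), `genes` (list of DE gene vectors per pair).
#' @export
cluster_discreteness <- function(es, target, others = NULL, n_sub = 80,
                                 lfc_min = 1, prop_min = 0.5, rel_min = 0.7,
                                 cpm_threshold = 1, seed = 1L) {
  cl <- es$cell_meta$cluster
  if (is.null(others)) others <- setdiff(sort(unique(cl)), target)
  if (!length(others)) stop("need >= 2 clusters")
  if (sum(cl == target) < 2) stop("singleton target cluster")
  set.seed(seed)
  lc <- cpm_log(es$counts)
  cpm <- 2^lc - 1
  expressed <- lc > log2(cpm_threshold + 1)
  sub_idx <- function(label) {
    ix <- which(cl == label)
    if (length(ix) < n_sub) sample(ix, n_sub, replace = TRUE)
    else sample(ix, n_sub)
  }
  ti <- sub_idx(target)
  mt <- rowMeans(cpm[, ti, drop = FALSE])
  pt <- rowMeans(expressed[, ti, drop = FALSE])
  genes <- lapply(others, function(o) {
    oi <- sub_idx(o)
    mo <- rowMeans(cpm[, oi, drop = FALSE])
    po <- rowMeans(expressed[, oi, drop = FALSE])
    lfc <- log2((mt + 1) / (mo + 1))
    rel <- (pt - po) / pmax(pt, po)
    rel[!is.finite(rel)] <- 0
    rownames(es$counts)[lfc >= lfc_min & pt >= prop_min & rel >= rel_min]
  })
  names(genes) <- others
  per_pair <- lengths(genes)
  list(mean_de = mean(per_pair), per_pair = per_pair, genes = genes)
}

#' Marker selection among three deep clusters
#'
#' A specificity-score selection in the spirit of quantile-threshold marker
#' finders: each gene is binarized at its own `quant` expression quantile
#' across all cells, per-cluster expressed fractions `x_c` give a posterior
#' `pi_c = x_c / sum(x_c)`, and a gene is retained when it is selective for
#' one cluster (top posterior >= `post1_min` with expressed fraction >=
#' `frac_min`) or for two of the three (top-two posterior sum >=
#' `post2_min`, both expressed fractions >= `frac_min`, remaining posterior
#' <= `post_other_max`). Binarizing at the global 0.7 quantile caps a
#' two-of-three marker's per-cluster expressed fraction near 0.45, so
#' `frac_min` sits below that; the posterior thresholds keep uniform genes
#' out.
#'
#' @param es Labelled `expression_set` restricted to exactly 3 clusters.
#' @param quant Per-gene binarization quantile (0.7, slightly relaxed).
#' @param post1_min,post2_min,post_other_max,frac_min Selection thresholds.
#' @return data.frame: `gene`, `selective_for` (comma-joined cluster
#'   labels), `n_clusters` (1 or 2).
#' @export
deep_marker_selection <- function(es, quant = 0.7, post1_min = 0.75,
                                  post2_min = 0.9, post_other_max = 0.2,
                                  frac_min = 0.3) {
  cl <- es$cell_meta$cluster
  cls <- sort(unique(cl))
  if (length(cls) != 3) stop("exactly 3 clusters required")
  lc <- cpm_log(es$counts)
  thr <- apply(lc, 1, stats::quantile, probs = quant)
  expressed <- lc > thr
  x <- vapply(cls, function(c_)
    rowMeans(expressed[, cl == c_, drop = FALSE]), numeric(nrow(lc)))
  tot <- rowSums(x)
  out <- vector("list", nrow(lc))
  for (g in which(tot > 0)) {
    pi_ <- x[g, ] / tot[g]
    ord <- order(-pi_, cls)
    if (pi_[ord[1]] >= post1_min && x[g, ord[1]] >= frac_min) {
      out[[g]] <- data.frame(gene = rownames(lc)[g],
                             selective_for = cls[ord[1]], n_clusters = 1L)
    } else if (pi_[ord[1]] + pi_[ord[2]] >= post2_min &&
               x[g, ord[1]] >= frac_min && x[g, ord[2]] >= frac_min &&
               pi_[ord[3]] <= post_other_max) {
      out[[g]] <- data.frame(
        gene = rownames(lc)[g],
        selective_for = paste(sort(cls[ord[1:2]]), collapse = ","),
        n_clusters = 2L)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(gene = character(0), selective_for = character(0),
                      n_clusters = integer(0)))
  do.call(rbind, out)
}
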