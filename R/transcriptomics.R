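#' Log2 CPM normalization
#'
#' `log2(1e6 * count / cell_total + 1)` per entry, the standard library-size
#' normalization for count matrices.
#'
#' @param counts Genes x cells non-negative matrix; every cell (column) must
#'   have a positive total.
#' @return Matrix of log2(CPM + 1) values, same dimensions.
#' @export
cpm_log <- function(counts) {
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("zero-total cell")
  log2(sweep(counts, 2, 1e6 / tot, "*") + 1)
}

#' Beta marker score
#'
#' Binariness statistic for marker genes: for each gene with expressed-cell
#' proportions `p_1..p_k` across clusters,
#' `beta = sum_{i<j} (p_i - p_j)^2 / (sum_{i<j} |p_i - p_j| + eps)`.
#' Scores lie in `[0, 1]`; a perfectly binary marker (proportion 1 in one
#' cluster and 0 elsewhere) scores 1 up to `eps`.
#'
#' @param proportions Genes x clusters matrix of expressed-cell proportions
#'   in `[0, 1]` (a single gene may be given as a vector), >= 2 clusters.
#' @param eps Small constant avoiding division by zero.
#' @return Numeric score per gene.
#' @export
beta_score <- function(proportions, eps = 1e-6) {
  if (is.null(dim(proportions))) proportions <- matrix(proportions, nrow = 1)
  if (ncol(proportions) < 2) stop("need >= 2 clusters")
  if (any(proportions < 0 | proportions > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  pairs <- utils::combn(ncol(proportions), 2)
  d <- proportions[, pairs[1, ], drop = FALSE] -
    proportions[, pairs[2, ], drop = FALSE]
  num <- rowSums(d^2)
  den <- rowSums(abs(d)) + eps
  unname(num / den)
}

# proportion of cells expressing each gene (CPM > threshold) per cluster
.expr_proportions <- function(counts, cluster, cpm_threshold = 1) {
  lc <- cpm_log(counts)
  expressed <- lc > log2(cpm_threshold + 1)
  vapply(split(seq_along(cluster), cluster),
         function(ix) rowMeans(expressed[, ix, drop = FALSE]),
         numeric(nrow(counts)))
}

#' Select the most binary genes by beta score
#'
#' Ranks genes by [beta_score()] of their per-cluster expressed proportions
#' (CPM above `cpm_threshold`) and returns the top `n`; ties broken by gene
#' symbol, so selection is deterministic.
#'
#' @param es An `expression_set` (see [simulate_expression()]) with cluster
#'   labels in `cell_meta$cluster`.
#' @param n Number of genes to return (full gene list with a warning when
#'   fewer genes exist).
#' @param cpm_threshold CPM above which a gene counts as expressed.
#' @return Character vector of gene symbols.
#' @export
select_binary_genes <- function(es, n = 2000, cpm_threshold = 1) {
  cl <- es$cell_meta$cluster
  if (is.null(cl) || anyNA(cl)) stop("cluster labels required")
  props <- .expr_proportions(es$counts, cl, cpm_threshold)
  b <- beta_score(props)
  sym <- rownames(es$counts)
  if (n >= length(sym)) {
    if (n > length(sym)) warning("fewer genes than requested; returning all")
    return(sym[order(-b, sym)])
  }
  sym[order(-b, sym)][seq_len(n)]
}

#' Filter genes prone to platform and quality artefacts
#'
#' Removes, with an audit count per rule: (1) sex-chromosome (chrX/chrY)
#' genes; (2) mitochondrial genes; (3) genes whose class of maximal
#' expression is non-neuronal; (4) genes with at least `log2_fc_max`-fold
#' (default four-fold) expression difference between the reference and
#' Patch-seq platforms, measured as
#' `|log2(mean_ref + 0.01) - log2(mean_query + 0.01)|` on CPM means over
#' shared cell types. The rules are independent predicates, so their order
#' does not change the retained set. Missing chromosome annotation skips
#' rules 1-2 with a warning.
#'
#' @param ref,query `expression_set`s sharing gene symbols.
#' @param log2_fc_max Platform-difference threshold in log2 units.
#' @return List: `retained` (gene symbols), `removed` (named counts per
#'   rule: `sex_chromosome`, `mitochondrial`, `non_neuronal`,
#'   `platform_fold`).
#' @export
filter_genes <- function(ref, query, log2_fc_max = 2) {
  genes <- intersect(rownames(ref$counts), rownames(query$counts))
  if (!length(genes)) stop("no shared gene symbols")
  gm <- ref$gene_meta[match(genes, ref$gene_meta$symbol), ]
  drop_sex <- drop_mito <- rep(FALSE, length(genes))
  if (all(is.na(gm$chromosome))) {
    warning("missing chromosome annotations: sex/mito rules skipped")
  } else {
    drop_sex <- gm$chromosome %in% c("chrX", "chrY", "X", "Y")
    drop_mito <- gm$chromosome %in% c("chrM", "MT") |
      (!is.na(gm$is_mito) & gm$is_mito)
  }
  drop_nn <- !is.na(gm$class_of_max_expression) &
    gm$class_of_max_expression != "neuronal"
  mr <- rowMeans(2^cpm_log(ref$counts)[genes, , drop = FALSE] - 1)
  mq <- rowMeans(2^cpm_log(query$counts)[genes, , drop = FALSE] - 1)
  drop_fc <- abs(log2(mr + 1e-2) - log2(mq + 1e-2)) >= log2_fc_max
  keep <- !(drop_sex | drop_mito | drop_nn | drop_fc)
  list(retained = genes[keep],
       removed = c(sex_chromosome = sum(drop_sex),
                   mitochondrial = sum(drop_mito),
                   non_neuronal = sum(drop_nn),
                   platform_fold = sum(drop_fc)))
}

#' Normalized marker sum (NMS) transcriptome quality score
#'
#' For each query cell, the summed log2(CPM+1) expression of each class's
#' "on"-type markers is divided by the median of the same sum over reference
#' cells of that class; the score is the maximum over classes (the
#' best-matching class). Cells pass at a score strictly greater than
#' `threshold` (default 0.4).
#'
#' @param query_logcpm Genes x cells log2(CPM+1) matrix for the query cells.
#' @param marker_sets Named list of marker gene vectors, one per class; all
#'   non-empty.
#' @param ref_logcpm Genes x cells log2(CPM+1) reference matrix.
#' @param ref_class Class label per reference cell.
#' @param threshold Pass threshold (strict inequality).
#' @return data.frame: `cell`, `score`, `best_class`, `pass`.
#' @export
nms_score <- function(query_logcpm, marker_sets, ref_logcpm, ref_class,
                      threshold = 0.4) {
  if (!length(marker_sets) || any(!lengths(marker_sets)))
    stop("marker sets must be non-empty")
  classes <- names(marker_sets)
  ref_med <- vapply(classes, function(cl) {
    ix <- which(ref_class == cl)
    if (!length(ix)) stop("empty reference class: ", cl)
    g <- intersect(marker_sets[[cl]], rownames(ref_logcpm))
    stats::median(colSums(ref_logcpm[g, ix, drop = FALSE]))
  }, 0)
  s <- vapply(classes, function(cl) {
    g <- intersect(marker_sets[[cl]], rownames(query_logcpm))
    colSums(query_logcpm[g, , drop = FALSE]) / ref_med[[cl]]
  }, numeric(ncol(query_logcpm)))
  s <- matrix(s, ncol = length(classes), dimnames = list(NULL, classes))
  best <- max.col(s, ties.method = "first")
  score <- s[cbind(seq_len(nrow(s)), best)]
  data.frame(cell = colnames(query_logcpm), score = score,
             best_class = classes[best], pass = score > threshold)
}

#' Build a cluster reference from labelled expression data
#'
#' Per-cluster centroids (median log2(CPM+1) per gene) and expressed-cell
#' proportions over a marker panel.
#'
#' @param es Labelled `expression_set`.
#' @param markers Marker panel; default the top 2000 genes by beta score.
#' @param cpm_threshold Expression threshold for proportions.
#' @return Object of class `cluster_reference`: list with `clusters`,
#'   `centroids` (genes x clusters), `proportions`, `markers`.
#' @export
cluster_reference <- function(es, markers = NULL, cpm_threshold = 1) {
  cl <- es$cell_meta$cluster
  if (is.null(markers))
    markers <- select_binary_genes(es, min(2000, nrow(es$counts)))
  lc <- cpm_log(es$counts)
  cls <- sort(unique(cl))
  cen <- vapply(cls, function(c_)
    apply(lc[, cl == c_, drop = FALSE], 1, stats::median),
    numeric(nrow(lc)))
  props <- .expr_proportions(es$counts, cl, cpm_threshold)[, cls, drop = FALSE]
  structure(list(clusters = cls, centroids = cen, proportions = props,
                 markers = markers),
            class = "cluster_reference")
}

#' Map query cells onto reference clusters by marker-gene correlation
#'
#' Assigns each query cell the cluster whose centroid has the highest Pearson
#' correlation with the cell's log2(CPM+1) marker-gene vector; the confidence
#' is the gap between the best and runner-up correlations. Ties break by
#' cluster label order; zero-variance cells are returned unmapped with a
#' reason.
#'
#' @param query_counts Genes x cells count matrix (or an `expression_set`).
#' @param reference A [cluster_reference()]; its marker panel must be present
#'   in the query gene set.
#' @return data.frame: `cell`, `label`, `confidence`, `reason` (`NA` when
#'   mapped).
#' @export
map_cells <- function(query_counts, reference) {
  if (inherits(query_counts, "expression_set"))
    query_counts <- query_counts$counts
  mk <- reference$markers
  if (!all(mk %in% rownames(query_counts)))
    stop("marker panel not fully present in query gene set")
  lc <- cpm_log(query_counts)[mk, , drop = FALSE]
  cen <- reference$centroids[mk, , drop = FALSE]
  n <- ncol(lc)
  label <- character(n); conf <- numeric(n); reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    x <- lc[, i]
    if (stats::sd(x) == 0) {
      label[i] <- NA_character_; conf[i] <- NA_real_
      reason[i] <- "zero_variance"
      next
    }
    r <- apply(cen, 2, function(cc)
      if (stats::sd(cc) == 0) -Inf else stats::cor(x, cc))
    ord <- order(-r, reference$clusters)
    label[i] <- reference$clusters[ord[1]]
    conf[i] <- r[ord[1]] - r[ord[2]]
  }
  data.frame(cell = colnames(query_counts), label = label,
             confidence = conf, reason = reason)
}
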