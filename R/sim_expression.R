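#' Design for a synthetic gene-by-cell count matrix
#'
#' Describes a discrete-cluster-plus-gradient expression structure: `k`
#' negative-binomial clusters with planted cluster-specific marker genes, and
#' optionally one cluster whose designated gradient genes have log-mean
#' expression linear in the cell's scaled cortical depth.
#'
#' @param n_clusters,cells_per_cluster,n_genes,n_markers_per_cluster Counts,
#'   all >= 1.
#' @param marker_fold_change Linear fold change of a marker gene in its own
#'   cluster (stored also as `marker_log2_fc`).
#' @param gradient_cluster Cluster index carrying the depth gradient, or
#'   `NA` for none.
#' @param gradient_genes Number of gradient genes (distinct from markers).
#' @param gradient_slope Log2-expression change per unit scaled depth.
#' @param nb_dispersion Negative-binomial dispersion (1/size), > 0.
#' @param marker_off_cpm Off-state mean expression (CPM) of a marker gene
#'   outside its own cluster; markers are lowly expressed off-type so that
#'   expressed-cell proportions carry the cluster signal, as real marker
#'   genes do.
#' @param seed Integer seed.
#' @return Object of class `expression_design`.
#' @export
expression_design <- function(n_clusters = 5, cells_per_cluster = 80,
                              n_genes = 1000, n_markers_per_cluster = 50,
                              marker_fold_change = 4, gradient_cluster = NA,
                              gradient_genes = 50, gradient_slope = 0,
                              nb_dispersion = 0.5, marker_off_cpm = 0.5,
                              seed = 1L) {
  cnt <- c(n_clusters, cells_per_cluster, n_genes, n_markers_per_cluster)
  if (any(cnt < 1)) stop("all counts must be >= 1")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (n_clusters * n_markers_per_cluster + gradient_genes > n_genes)
    stop("not enough genes for the requested markers and gradient genes")
  structure(list(n_clusters = n_clusters, cells_per_cluster = cells_per_cluster,
                 n_genes = n_genes,
                 n_markers_per_cluster = n_markers_per_cluster,
                 marker_fold_change = marker_fold_change,
                 marker_log2_fc = log2(marker_fold_change),
                 gradient_cluster = gradient_cluster,
                 gradient_genes = gradient_genes,
                 gradient_slope = gradient_slope,
                 nb_dispersion = nb_dispersion,
                 marker_off_cpm = marker_off_cpm, seed = as.integer(seed)),
            class = "expression_design")
}

#' Simulate a gene-by-cell count matrix with known cluster structure
#'
#' Counts are negative binomial with gene-wise means: every gene has a
#' baseline relative abundance (log-normal), marker genes are multiplied by
#' the design fold change in their own cluster, and gradient genes in the
#' gradient cluster have log2 mean linear in the cell's scaled depth.
#' Relative abundances are normalized per cell and scaled by log-normal
#' library sizes (mu = log 5e5, sigma = 0.3, typical single-nucleus scale).
#' Cell metadata records donor, platform, the true cluster and scaled depth;
#' gene metadata includes chromosome (a few genes on chrX/chrY/chrM) and the
#' class of maximal expression (a few non-neuronal genes) to exercise the
#' gene filters.
#'
#' @param design An [expression_design()].
#' @param platform Value recorded in `cell_meta$platform`.
#' @param cell_seed Optional separate seed for the cell-level draws (depths,
#'   library sizes, counts). Gene-level parameters (baseline abundances,
#'   marker assignments, annotations) always derive from `design$seed`, so
#'   two simulations differing only in `cell_seed` share the same genes —
#'   use this to generate a query cohort for a reference built from the same
#'   design.
#' @return Object of class `expression_set`: list with `counts` (genes x
#'   cells integer matrix), `gene_meta` (`symbol`, `chromosome`, `is_mito`,
#'   `class_of_max_expression`), `cell_meta` (`cell`, `donor`, `platform`,
#'   `cluster`, `scaled_depth`) and `truth` (marker gene lists per cluster,
#'   gradient gene list, the design).
#' @export
simulate_expression <- function(design, platform = "reference",
                                cell_seed = NULL) {
  stopifnot(inherits(design, "expression_design"))
  set.seed(design$seed)
  k <- design$n_clusters
  nc <- design$cells_per_cluster
  ng <- design$n_genes
  n_cells <- k * nc
  genes <- sprintf("G%04d", seq_len(ng))
  cluster <- rep(paste0("C", seq_len(k)), each = nc)
  markers <- split(genes[seq_len(k * design$n_markers_per_cluster)],
                   rep(seq_len(k), each = design$n_markers_per_cluster))
  names(markers) <- paste0("C", seq_len(k))
  grad_genes <- if (design$gradient_genes > 0)
    genes[k * design$n_markers_per_cluster + seq_len(design$gradient_genes)]
  else character(0)
  # baseline relative abundance per gene; markers sit at a low off-state
  # abundance so their expressed-cell proportions are cluster-informative
  base <- stats::rlnorm(ng, meanlog = 0, sdlog = 1.2)
  mk_idx <- match(unlist(markers), genes)
  base[mk_idx] <- design$marker_off_cpm * sum(base[-mk_idx]) / 1e6
  # gene annotations (chromosome, mito, class of maximal expression)
  chrom <- sample(paste0("chr", 1:22), ng, replace = TRUE)
  n_special <- max(2L, round(ng * 0.01))
  non_marker <- setdiff(seq_len(ng), c(mk_idx, match(grad_genes, genes)))
  sp <- sample(non_marker, 3 * n_special)
  chrom[sp[seq_len(n_special)]] <- "chrX"
  chrom[sp[n_special + seq_len(n_special)]] <- "chrY"
  chrom[sp[2 * n_special + seq_len(n_special)]] <- "chrM"
  cls <- rep("neuronal", ng)
  cls[sample(non_marker, max(2L, round(ng * 0.02)))] <- "non-neuronal"
  # cell-level draws may use their own seed (query cohorts)
  if (!is.null(cell_seed)) set.seed(cell_seed)
  # laminar structure: clusters occupy overlapping depth bands; the gradient
  # cluster spans the full L2-3 depth
  centers <- seq(-0.15, -0.85, length.out = k)
  depth <- numeric(n_cells)
  for (c_i in seq_len(k)) {
    idx <- which(cluster == paste0("C", c_i))
    if (!is.na(design$gradient_cluster) && c_i == design$gradient_cluster) {
      depth[idx] <- stats::runif(length(idx), -1, 0)
    } else {
      depth[idx] <- pmin(0, pmax(-1, stats::rnorm(length(idx), centers[c_i],
                                                  0.12)))
    }
  }
  logmu <- matrix(log2(base), nrow = ng, ncol = n_cells,
                  dimnames = list(genes, NULL))
  for (c_i in seq_len(k)) {
    gi <- match(markers[[c_i]], genes)
    ci <- which(cluster == paste0("C", c_i))
    logmu[gi, ci] <- logmu[gi, ci] + design$marker_log2_fc
  }
  if (!is.na(design$gradient_cluster) && length(grad_genes)) {
    gi <- match(grad_genes, genes)
    ci <- which(cluster == paste0("C", design$gradient_cluster))
    logmu[gi, ci] <- logmu[gi, ci] +
      design$gradient_slope * rep(depth[ci], each = length(gi))
  }
  rel <- 2^logmu
  rel <- sweep(rel, 2, colSums(rel), "/")
  lib <- stats::rlnorm(n_cells, meanlog = log(5e5), sdlog = 0.3)
  mu <- sweep(rel, 2, lib, "*")
  counts <- matrix(stats::rnbinom(ng * n_cells, mu = mu,
                                  size = 1 / design$nb_dispersion),
                   nrow = ng, dimnames = list(genes, NULL))
  cells <- sprintf("cell_%04d", seq_len(n_cells))
  colnames(counts) <- cells
  structure(list(
    counts = counts,
    gene_meta = data.frame(symbol = genes, chromosome = chrom,
                           is_mito = chrom == "chrM",
                           class_of_max_expression = cls),
    cell_meta = data.frame(cell = cells,
                           donor = sample(paste0("donor", 1:4), n_cells,
                                          replace = TRUE),
                           platform = platform, cluster = cluster,
                           scaled_depth = depth),
    truth = list(markers = markers, gradient_genes = grad_genes,
                 design = design)),
    class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d genes x %d cells, %d clusters\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$cluster))))
  invisible(x)
}
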