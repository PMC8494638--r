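# small labelled expression set shared across tests
es_small <- simulate_expression(
  expression_design(n_clusters = 3, cells_per_cluster = 40, n_genes = 300,
                    n_markers_per_cluster = 20, marker_fold_change = 8,
                    gradient_genes = 0, seed = 21))

test_that("cpm_log matches its closed form and is scale invariant", {
  cm <- matrix(c(0, 5, 95, 10, 10, 80), nrow = 3,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  lc <- cpm_log(cm)
  expect_identical(lc["g1", "a"], 0)
  expect_equal(lc["g3", "b"], log2(1e6 * 80 / 100 + 1))
  single <- matrix(c(7), dimnames = list("g", "c"))
  expect_equal(cpm_log(single)[1], log2(1e6 + 1))  # count = cell total
  expect_equal(cpm_log(cm * 2)[, "a"], lc[, "a"])  # doubling a cell: no-op
  cm0 <- cm; cm0[, 1] <- 0
  expect_error(cpm_log(cm0), "zero-total")
})

test_that("beta score: closed-form examples and oracle equivalence", {
  eps <- 1e-6
  expect_equal(beta_score(matrix(c(1, 0, 0, 0, 0), 1)), 4 / (4 + eps))
  expect_identical(beta_score(matrix(0.3, 1, 4)), 0)
  expect_equal(beta_score(matrix(c(1, 0.5), 1)), 0.25 / (0.5 + eps))
  expect_error(beta_score(matrix(1.2, 1, 3)), "\\[0, 1\\]")
  expect_error(beta_score(matrix(0.5, 2, 1)), ">= 2")
  set.seed(4)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    p <- matrix(runif(7 * k), 7, k)
    got <- beta_score(p)
    want <- apply(p, 1, oracle_beta)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("select_binary_genes ranks planted markers on top,
          deterministically", {
  truth_markers <- unlist(es_small$truth$markers)
  top <- select_binary_genes(es_small, length(truth_markers))
  expect_gte(mean(top %in% truth_markers), 0.95)
  expect_identical(top, select_binary_genes(es_small,
                                            length(truth_markers)))
  expect_warning(all_g <- select_binary_genes(es_small, 10000), "fewer")
  expect_identical(sort(all_g), sort(rownames(es_small$counts)))
})

test_that("filter_genes applies each rule and reports audit counts", {
  mk <- function(counts, chrom, cls) {
    structure(list(
      counts = counts,
      gene_meta = data.frame(symbol = rownames(counts), chromosome = chrom,
                             is_mito = chrom == "chrM",
                             class_of_max_expression = cls),
      cell_meta = data.frame(cell = colnames(counts),
                             cluster = "C1", platform = "x")),
      class = "expression_set")
  }
  g <- paste0("g", 1:5)
  ref_counts <- matrix(100, 5, 4, dimnames = list(g, paste0("r", 1:4)))
  q_counts <- ref_counts
  colnames(q_counts) <- paste0("q", 1:4)
  q_counts["g5", ] <- 20                    # 5-fold lower in query
  chrom <- c("chrX", "chrM", "chr1", "chr2", "chr3")
  cls <- c("neuronal", "neuronal", "non-neuronal", "neuronal", "neuronal")
  fg <- filter_genes(mk(ref_counts, chrom, cls), mk(q_counts, chrom, cls))
  expect_identical(fg$removed[["sex_chromosome"]], 1L)
  expect_identical(fg$removed[["mitochondrial"]], 1L)
  expect_identical(fg$removed[["non_neuronal"]], 1L)
  expect_identical(fg$removed[["platform_fold"]], 1L)
  expect_identical(fg$retained, "g4")       # identical platform means kept
  # rules are independent predicates: the union drives the retained set
  expect_identical(setdiff(g, fg$retained),
                   g[chrom %in% c("chrX", "chrM") | cls != "neuronal" |
                       g == "g5"])
  expect_warning(
    filter_genes(mk(ref_counts, rep(NA, 5), cls),
                 mk(q_counts, rep(NA, 5), cls)),
    "chromosome")
})

test_that("nms_score self-normalizes and applies a strict 0.4 cutoff", {
  set.seed(5)
  ref <- matrix(rlnorm(50 * 30, 2, 0.2), 50, 30,
                dimnames = list(paste0("g", 1:50), paste0("r", 1:30)))
  cls <- rep(c("A", "B"), each = 15)
  ref[1:10, cls == "A"] <- ref[1:10, cls == "A"] + 5
  mk_sets <- list(A = paste0("g", 1:10), B = paste0("g", 11:20))
  # a reference cell fed back as a query scores near 1
  ns <- nms_score(ref[, 1, drop = FALSE], mk_sets, ref, cls)
  expect_gt(ns$score, 0.9)
  expect_true(ns$pass)
  zero <- matrix(0, 50, 1, dimnames = list(rownames(ref), "z"))
  nz <- nms_score(zero, mk_sets, ref, cls)
  expect_identical(nz$score, 0)
  expect_false(nz$pass)
  # exactly at threshold: strict inequality fails
  med_A <- median(colSums(ref[mk_sets$A, cls == "A"]))
  q <- zero
  q[mk_sets$A, 1] <- 0.4 * med_A / 10
  nq <- nms_score(q, mk_sets, ref, cls)
  expect_equal(nq$score, 0.4, tolerance = 1e-12)
  expect_false(nq$pass)
  expect_error(nms_score(zero, list(A = character(0)), ref, cls),
               "non-empty")
})

test_that("map_cells recovers labels, self-maps centroids, flags degenerate
          cells", {
  ref <- cluster_reference(es_small, markers = select_binary_genes(es_small,
                                                                   60))
  # a centroid fed as a query maps to its own label
  cen_counts <- round(2^ref$centroids[, "C2", drop = FALSE] - 1) * 100 + 1
  colnames(cen_counts) <- "centroid"
  self <- map_cells(cen_counts, ref)
  expect_identical(self$label, "C2")
  expect_gt(self$confidence, 0)
  # held-out cohort from the same design
  q <- simulate_expression(
    expression_design(n_clusters = 3, cells_per_cluster = 40, n_genes = 300,
                      n_markers_per_cluster = 20, marker_fold_change = 8,
                      gradient_genes = 0, seed = 21),
    platform = "patchseq", cell_seed = 77)
  mp <- map_cells(q, ref)
  expect_gte(mean(mp$label == q$cell_meta$cluster), 0.95)
  # CPM invariance: per-cell library rescaling leaves labels unchanged
  scaled <- q$counts
  scaled[, 1:10] <- scaled[, 1:10] * 7L
  expect_identical(map_cells(scaled, ref)$label, mp$label)
  # constant query vector is unmapped with a reason
  flat <- matrix(5, nrow(q$counts), 1,
                 dimnames = list(rownames(q$counts), "flat"))
  fm <- map_cells(flat, ref)
  expect_true(is.na(fm$label))
  expect_identical(fm$reason, "zero_variance")
})

test_that("cluster_heterogeneity: null calibration, permutation marginals,
          degenerate n_perm", {
  # i.i.d. Gaussian-noise cluster: gene-independent by construction
  set.seed(77)
  lc <- matrix(rnorm(300 * 120, 5, 1), 300, 120,
               dimnames = list(sprintf("g%03d", 1:300), NULL))
  h0 <- cluster_heterogeneity(lc, n_perm = 0, seed = 1)
  expect_identical(h0$perms, numeric(0))
  expect_true(is.na(h0$z))
  h <- cluster_heterogeneity(lc, n_perm = 30, seed = 1,
                             keep_first_perm = TRUE)
  expect_lt(abs(h$z), 3)                   # i.i.d. cluster: consistent null
  # each gene's marginal distribution is preserved exactly by the shuffle
  expect_identical(apply(h$first_perm, 2, sort), apply(h$subset, 2, sort))
  expect_error(cluster_heterogeneity(lc, n_genes = 1e6), "exceed")
  expect_warning(cluster_heterogeneity(lc[, 1:10], n_cells = 20,
                                       n_perm = 2), "replacement")
})

test_that("a planted gradient drives the heterogeneity statistic far above
          its null", {
  des <- expression_design(n_clusters = 1, cells_per_cluster = 100,
                           n_genes = 300, n_markers_per_cluster = 1,
                           marker_fold_change = 1, gradient_cluster = 1,
                           gradient_genes = 50, gradient_slope = 2,
                           seed = 31)
  es <- simulate_expression(des)
  h <- cluster_heterogeneity(cpm_log(es$counts), n_perm = 30, seed = 2)
  expect_gt(h$z, 5)
})

test_that("cluster_discreteness counts planted up-regulated markers only", {
  # two identical clusters: zero DE genes
  set.seed(8)
  same <- matrix(rnbinom(200 * 80, mu = 40, size = 2), 200, 80,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 sprintf("c%03d", 1:80)))
  es2 <- structure(list(
    counts = same,
    gene_meta = data.frame(symbol = rownames(same)),
    cell_meta = data.frame(cell = colnames(same),
                           cluster = rep(c("A", "B"), each = 40))),
    class = "expression_set")
  expect_identical(cluster_discreteness(es2, "A", n_sub = 40)$mean_de, 0)
  # planted on/off markers: expressed in ~90% of target, ~5% of other
  es3 <- es2
  on <- sprintf("g%03d", 1:50)
  a_cells <- es3$cell_meta$cluster == "A"
  es3$counts[on, ] <- 0
  es3$counts[on, a_cells] <-
    rnbinom(50 * 40, mu = 8, size = 5) * rbinom(50 * 40, 1, 0.92)
  es3$counts[on, !a_cells] <-
    rnbinom(50 * 40, mu = 8, size = 5) * rbinom(50 * 40, 1, 0.05)
  counts <- vapply(1:5, function(s)
    cluster_discreteness(es3, "A", n_sub = 40, seed = s)$mean_de, 0)
  expect_true(all(abs(counts - 50) / 50 <= 0.1))
  # the same markers are never counted for the down-regulated side
  rev_counts <- cluster_discreteness(es3, "B", n_sub = 40, seed = 1)
  expect_false(any(on %in% rev_counts$genes[["A"]]))
  expect_error(cluster_discreteness(es2, "A", others = character(0)),
               "clusters")
})

test_that("deep_marker_selection keeps one- and two-type markers, drops
          uniform genes", {
  set.seed(9)
  ng <- 150; npc <- 40
  cl <- rep(c("X", "Y", "Z"), each = npc)
  counts <- matrix(rnbinom(ng * 3 * npc, mu = 30, size = 2), ng, 3 * npc,
                   dimnames = list(sprintf("g%03d", 1:ng),
                                   sprintf("c%03d", seq_len(3 * npc))))
  counts["g001", ] <- 0
  counts["g001", cl == "X"] <- rnbinom(npc, mu = 60, size = 5)  # one-type
  counts["g002", ] <- 0
  counts["g002", cl != "Z"] <- rnbinom(2 * npc, mu = 60, size = 5)  # two-type
  es3 <- structure(list(counts = counts,
                        gene_meta = data.frame(symbol = rownames(counts)),
                        cell_meta = data.frame(cell = colnames(counts),
                                               cluster = cl)),
                   class = "expression_set")
  sel <- deep_marker_selection(es3)
  expect_true("g001" %in% sel$gene)
  expect_identical(sel$selective_for[sel$gene == "g001"], "X")
  expect_true("g002" %in% sel$gene)
  expect_identical(sel$selective_for[sel$gene == "g002"], "X,Y")
  expect_false("g100" %in% sel$gene)       # uniform background gene
  es2cl <- es3
  es2cl$cell_meta$cluster <- rep(c("X", "Y"), length.out = 3 * npc)
  expect_error(deep_marker_selection(es2cl), "3 clusters")
})
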