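#' @title Morphometric corrections and laminar quantification
#' @description Shrinkage and slice-tilt corrections, depth-binned branch
#'   length histograms with layer totals, cohort apical-histogram principal
#'   component, and scalar morphometrics.
#' @name morph_features
NULL

.soma_xyz <- function(m) {
  s <- m[m$type == "soma" & m$parent == -1, ]
  c(s$x[1], s$y[1], s$z[1])
}

#' Correct z-shrinkage of a reconstruction
#'
#' Tissue processing compresses the slice along z (perpendicular to the cut
#' surface). Coordinates are re-expanded about the soma by the ratio of the
#' soma-to-surface distance during recording to the distance after fixation;
#' x and y are unchanged and the soma is a fixed point.
#'
#' @param m A [morphology()].
#' @param depth_recorded,depth_fixed Soma depth below the cut surface during
#'   recording and after fixation (um), both > 0.
#' @return Corrected [morphology()].
#' @export
correct_shrinkage <- function(m, depth_recorded, depth_fixed) {
  if (depth_recorded <= 0 || depth_fixed <= 0)
    stop("depths must be positive")
  s <- .soma_xyz(m)
  m$z <- s[3] + (m$z - s[3]) * depth_recorded / depth_fixed
  m
}

#' Correct slicing-angle tilt
#'
#' Rigid rotation about the soma in the plane containing the slice normal (z)
#' and the pia axis (y), compensating the difference between the slicing
#' angle and the direct pia-white-matter direction.
#'
#' @param m A [morphology()].
#' @param tilt_angle Degrees, |angle| < 90.
#' @return Rotated [morphology()].
#' @export
correct_tilt <- function(m, tilt_angle) {
  if (abs(tilt_angle) >= 90) stop("tilt angle out of range (|angle| < 90)")
  th <- tilt_angle * pi / 180
  s <- .soma_xyz(m)
  y <- m$y - s[2]; z <- m$z - s[3]
  m$y <- s[2] + y * cos(th) - z * sin(th)
  m$z <- s[3] + y * sin(th) + z * cos(th)
  m
}

# segment table for a compartment: one row per (parent, child) pair where the
# child is of the requested type; returns endpoint depths and 3D lengths
.segments <- function(m, compartment) {
  ch <- m[m$type == compartment & m$parent != -1, ]
  if (!nrow(ch)) return(NULL)
  pi_ <- match(ch$parent, m$id)
  data.frame(
    d1 = -m$y[pi_], d2 = -ch$y,
    len = sqrt((ch$x - m$x[pi_])^2 + (ch$y - m$y[pi_])^2 +
                 (ch$z - m$z[pi_])^2))
}

#' Laminar branch-length histogram
#'
#' Apportions each inter-node segment's length across depth bins (and across
#' cortical layers) proportionally to the fraction of its vertical extent
#' falling in each bin, by linear interpolation of the endpoints; purely
#' horizontal segments are assigned to the bin containing their depth. The
#' sum over bins equals the total compartment length (length conservation).
#'
#' @param m An aligned [morphology()] (pia at y = 0, y decreasing with
#'   depth).
#' @param compartment `"basal"`, `"apical"` or `"axon"`.
#' @param ctx A [layer_context()].
#' @param bin_um Depth bin width (um).
#' @return List: `bins` (data.frame `depth_lo`, `depth_hi`, `length_um`),
#'   `layers` (named vector of per-layer totals, um), `total_um`.
#' @export
laminar_histogram <- function(m, compartment = c("apical", "basal", "axon"),
                              ctx, bin_um = 50) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(ctx, "layer_context"))
  if (any(-m$y < -1e-6))
    stop("morphology not aligned: nodes found above the pia (y > 0)")
  segs <- .segments(m, compartment)
  max_d <- max(ctx$boundaries[["wm"]], if (!is.null(segs))
    max(segs$d1, segs$d2) else 0)
  edges <- seq(0, bin_um * ceiling(max_d / bin_um), by = bin_um)
  counts <- numeric(length(edges) - 1)
  b <- ctx$boundaries
  lay_edges <- c(0, b[["l12"]], b[["l34"]], b[["l45"]], b[["l56"]], b[["wm"]],
                 Inf)
  lay_names <- c("L1", "L2-3", "L4", "L5", "L6", "WM")
  layers <- stats::setNames(numeric(length(lay_names)), lay_names)
  if (!is.null(segs)) {
    for (i in seq_len(nrow(segs))) {
      counts <- counts + .apportion(segs$d1[i], segs$d2[i], segs$len[i], edges)
      layers <- layers + .apportion(segs$d1[i], segs$d2[i], segs$len[i],
                                    lay_edges)
    }
  }
  list(bins = data.frame(depth_lo = edges[-length(edges)],
                         depth_hi = edges[-1], length_um = counts),
       layers = layers,
       total_um = if (is.null(segs)) 0 else sum(segs$len))
}

# split a segment of 3D length `len` spanning depths [d1, d2] across bins
.apportion <- function(d1, d2, len, edges) {
  out <- numeric(length(edges) - 1)
  lo <- min(d1, d2); hi <- max(d1, d2)
  if (hi - lo < 1e-12) {
    # horizontal segment: deeper bin on an exact edge (half-open, deep-closed)
    k <- findInterval(lo, edges, left.open = TRUE, rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(out))
    out[k] <- len
    return(out)
  }
  for (k in seq_along(out)) {
    ov <- min(hi, edges[k + 1]) - max(lo, edges[k])
    if (ov > 0) out[k] <- len * ov / (hi - lo)
  }
  out
}

#' First principal component of cohort apical laminar distributions
#'
#' Scores each cell by projecting its layer-normalized apical branch-length
#' fractions on the first principal axis of the cohort, with the sign fixed
#' so that a higher score means more apical dendrite in L1.
#'
#' @param hist_mat Cells x layers matrix of apical length fractions, rows
#'   summing to 1; must contain an `"L1"` column.
#' @return Numeric score per cell (all zero for a degenerate cohort of
#'   identical histograms).
#' @export
apical_hist_pc0 <- function(hist_mat) {
  hist_mat <- as.matrix(hist_mat)
  if (nrow(hist_mat) < 3) stop("need >= 3 cells")
  if (is.null(colnames(hist_mat)) || !"L1" %in% colnames(hist_mat))
    stop("hist_mat must have an L1 column")
  if (max(abs(rowSums(hist_mat) - 1)) > 1e-6)
    stop("rows must be normalized to unit sum")
  cen <- scale(hist_mat, center = TRUE, scale = FALSE)
  if (max(abs(cen)) < 1e-12) return(rep(0, nrow(hist_mat)))
  pc <- stats::prcomp(hist_mat, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  if (v[["L1"]] < 0) v <- -v
  as.numeric(cen %*% v)
}

# branch order per node: soma-emanating stem = 1, +1 at each bifurcation
.branch_orders <- function(m) {
  kids <- table(factor(m$parent, levels = m$id))
  ord <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- m$parent[i]
    if (p == -1) { ord[i] <- 0L; next }
    pi_ <- match(p, m$id)
    if (m$type[pi_] == "soma") ord[i] <- 1L
    else ord[i] <- ord[pi_] + (kids[[as.character(p)]] > 1)
  }
  ord
}

#' Scalar morphometric features
#'
#' Computes dendritic scalar features on an aligned, corrected morphology.
#' Features dominated by the z-dimension are excluded (slice compression
#' artefacts); the tangential width uses x only. `basal_max_distance_um` is
#' the maximum Euclidean node-to-soma distance among basal nodes (the radial
#' extent); the maximum path distance is also emitted under a distinct name.
#'
#' @param m A [morphology()].
#' @param ctx A [layer_context()] (used for the apical depth bias reference).
#' @return Named list: `total_length_um` (dendrites), `apical_height_um`,
#'   `basal_max_distance_um`, `basal_max_path_um`, `max_branch_order`,
#'   `tangential_width_um`, `apical_depth_bias_um`, `soma_radius_um`;
#'   a missing compartment yields `NA` for its features.
#' @export
morphometrics <- function(m, ctx = attr(m, "layer_context")) {
  soma <- .soma_xyz(m)
  dend <- m[m$type %in% c("basal", "apical"), ]
  segs <- rbind(.segments(m, "basal"), .segments(m, "apical"))
  total_len <- if (is.null(segs)) NA_real_ else sum(segs$len)
  ap <- m[m$type == "apical", ]
  apical_height <- if (nrow(ap)) max(ap$y) - min(c(ap$y, soma[2])) else
    NA_real_
  bas <- m[m$type == "basal", ]
  if (nrow(bas)) {
    basal_max <- max(sqrt((bas$x - soma[1])^2 + (bas$y - soma[2])^2 +
                            (bas$z - soma[3])^2))
    basal_max_path <- max(.path_distances(m)[m$type == "basal"])
  } else basal_max <- basal_max_path <- NA_real_
  orders <- .branch_orders(m)
  dend_ord <- orders[m$type %in% c("basal", "apical")]
  ap_bias <- if (nrow(ap)) {
    s <- .segments(m, "apical")
    # length-weighted mean apical depth relative to the soma (negative =
    # above the soma, toward the pia)
    sum((s$d1 + s$d2) / 2 * s$len) / sum(s$len) - (-soma[2])
  } else NA_real_
  list(total_length_um = total_len,
       apical_height_um = apical_height,
       basal_max_distance_um = basal_max,
       basal_max_path_um = basal_max_path,
       max_branch_order = if (nrow(dend)) max(dend_ord) else NA_integer_,
       tangential_width_um = if (nrow(dend)) diff(range(dend$x)) else
         NA_real_,
       apical_depth_bias_um = ap_bias,
       soma_radius_um = m$radius[m$type == "soma" & m$parent == -1][1])
}

# path distance from soma to every node along the tree (um)
.path_distances <- function(m) {
  pd <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- m$parent[i]
    if (p == -1) { pd[i] <- 0; next }
    pi_ <- match(p, m$id)
    pd[i] <- pd[pi_] + sqrt((m$x[i] - m$x[pi_])^2 + (m$y[i] - m$y[pi_])^2 +
                              (m$z[i] - m$z[pi_])^2)
  }
  pd
}
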