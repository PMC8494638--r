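#' Laminar context for a specimen
#'
#' Layer boundaries as positive depths below the pia (um). In the aligned
#' morphology coordinate frame the pia sits at y = 0 and y decreases with
#' depth, so a boundary at depth d corresponds to y = -d.
#'
#' @param l12 L1/L2 boundary depth (um).
#' @param l34 L3/L4 boundary depth (um).
#' @param l23 Optional L2/L3 boundary depth (um); `NA` when indistinct.
#' @param l45,l56,wm Deeper boundaries (um).
#' @param soma_depth Soma depth (um), must lie between pia and white matter.
#' @return Object of class `layer_context`.
#' @export
layer_context <- function(l12 = 280, l34 = 1200, l23 = NA, l45 = 1450,
                          l56 = 1700, wm = 2200, soma_depth = NA) {
  b <- c(l12 = l12, l23 = l23, l34 = l34, l45 = l45, l56 = l56, wm = wm)
  bb <- b[!is.na(b)]
  if (any(diff(bb) <= 0) || any(bb <= 0))
    stop("layer boundary depths must be positive and strictly increasing")
  if (!is.na(soma_depth) && (soma_depth <= 0 || soma_depth >= wm))
    stop("soma_depth must lie between pia and white matter")
  structure(list(pia_y = 0, boundaries = b, soma_depth = soma_depth),
            class = "layer_context")
}

#' Simulate a reconstructed pyramidal-neuron morphology
#'
#' Builds a typed node tree with constructively known ground truth, emulating
#' the qualitative contrast between superficial L2/L3 pyramidal cells (apical
#' dendrite tufting inside L1) and deep L3 cells whose apical dendrite
#' terminates before reaching L1. Archetypes are parameter presets, not fits
#' to real reconstructions.
#'
#' @param archetype `"superficial"` (apical tuft inside L1) or `"deep"`
#'   (L1-avoiding apical, wide basals).
#' @param soma_depth Soma depth below pia (um); must lie within L2-L3 of
#'   `ctx`.
#' @param ctx A [layer_context()].
#' @param seed Integer seed (lateral jitter and basal azimuths).
#' @param n_basal Number of basal subtrees.
#' @param basal_max_um Maximum basal radial extent (um); the most distal
#'   basal node is placed at exactly this Euclidean distance from the soma.
#'   Default: 250 for superficial, 450 for deep.
#' @param step_um Node spacing along neurites (um).
#' @return A [morphology()] with attribute `ground_truth`: a list holding
#'   `apical_extent_um` (vertical extent of the apical dendrite),
#'   `basal_max_distance_um`, `l1_apical_length_um` and `soma_depth_um`.
#' @export
simulate_morphology <- function(archetype = c("superficial", "deep"),
                                soma_depth, ctx = layer_context(),
                                seed = 1L, n_basal = 4,
                                basal_max_um = NULL, step_um = 10) {
  archetype <- match.arg(archetype)
  l12 <- ctx$boundaries[["l12"]]; l34 <- ctx$boundaries[["l34"]]
  if (soma_depth <= l12 || soma_depth >= l34)
    stop("soma_depth must lie inside L2-L3 of the layer context")
  set.seed(seed)
  if (is.null(basal_max_um))
    basal_max_um <- if (archetype == "superficial") 250 else 450
  soma_y <- -soma_depth
  nodes <- list(data.frame(id = 1, type = "soma", x = 0, y = soma_y, z = 0,
                           radius = 8, parent = -1))
  nid <- 1L
  add_path <- function(from_id, from_xyz, to_xyz, type, radius = 1) {
    len <- sqrt(sum((to_xyz - from_xyz)^2))
    nseg <- max(1L, ceiling(len / step_um))
    prev <- from_id
    rows <- vector("list", nseg)
    for (i in seq_len(nseg)) {
      p <- from_xyz + (to_xyz - from_xyz) * i / nseg
      nid <<- nid + 1L
      rows[[i]] <- data.frame(id = nid, type = type, x = p[1], y = p[2],
                              z = p[3], radius = radius, parent = prev)
      prev <- nid
    }
    nodes[[length(nodes) + 1L]] <<- do.call(rbind, rows)
    list(id = prev, xyz = to_xyz)
  }
  # apical trunk straight up; tip depth defines the designed vertical extent
  tip_depth <- if (archetype == "superficial") 0.3 * l12 else l12 + 40
  apical_extent <- soma_depth - tip_depth
  trunk_top <- c(0, -tip_depth, 0)
  tip <- add_path(1L, c(0, soma_y, 0), trunk_top, "apical", radius = 2)
  if (archetype == "superficial") {
    # tuft: lateral branches entirely inside L1
    for (ang in c(-60, -20, 20, 60) * pi / 180) {
      reach <- stats::runif(1, 40, 80)
      tgt <- trunk_top + c(sin(ang) * reach, stats::runif(1, 0, 0.5) *
                             (l12 * 0.25), cos(ang) * 2)
      tgt[2] <- min(tgt[2], -1)         # stay below the pia
      add_path(tip$id, trunk_top, tgt, "apical")
    }
    # oblique branches below L1
    ob_y <- soma_y + 0.5 * apical_extent
    ob_from <- c(0, ob_y, 0)
    ob_id <- nodes_id_at <- NULL
  } else {
    # deep archetype: short terminal branchlets below L1
    for (ang in c(-35, 35) * pi / 180) {
      tgt <- trunk_top + c(sin(ang) * 30, -10, 0)
      add_path(tip$id, trunk_top, tgt, "apical")
    }
  }
  # basal subtrees: straight radial paths; the first one realizes exactly
  # the designed maximum Euclidean extent
  az <- stats::runif(n_basal, 0, 2 * pi)
  for (b in seq_len(n_basal)) {
    reach <- if (b == 1) basal_max_um else
      stats::runif(1, 0.4, 0.85) * basal_max_um
    dirv <- c(cos(az[b]), -abs(stats::runif(1, 0.05, 0.4)), sin(az[b]))
    dirv <- dirv / sqrt(sum(dirv^2))
    end <- c(0, soma_y, 0) + dirv * reach
    mid <- c(0, soma_y, 0) + dirv * reach * 0.55
    leg <- add_path(1L, c(0, soma_y, 0), mid, "basal")
    add_path(leg$id, mid, end, "basal")
    # side branch off the midpoint (raises branch order)
    side <- mid + c(-dirv[3], 0, dirv[1]) * reach * 0.3
    add_path(leg$id, mid, side, "basal")
  }
  m <- morphology(do.call(rbind, nodes))
  ap <- m[m$type == "apical", ]
  l1_len <- laminar_histogram(m, "apical", ctx, bin_um = 50)$layers[["L1"]]
  attr(m, "ground_truth") <- list(
    archetype = archetype,
    apical_extent_um = max(ap$y) - soma_y,
    basal_max_distance_um = basal_max_um,
    l1_apical_length_um = unname(l1_len),
    soma_depth_um = soma_depth)
  attr(m, "layer_context") <- ctx
  m
}
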