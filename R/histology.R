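#' Scaled L2/3 depth
#'
#' Normalizes a soma depth to the L2-3 extent: 0 at the L1/L2 boundary, -1
#' at the L3/L4 boundary, i.e. `-(soma_depth - l12) / (l34 - l12)`. The
#' value -0.575 marks the quantitative boundary between superficial and
#' deep L3 (the density nadir).
#'
#' @param soma_depth Soma depth below pia (um); vectorized.
#' @param l12,l34 L1/L2 and L3/L4 boundary depths (um), `l12 < l34`.
#' @return Scaled depth in `[-1, 0]`.
#' @export
scaled_depth <- function(soma_depth, l12, l34) {
  if (any(l12 >= l34)) stop("require l12 < l34")
  if (any(soma_depth < l12 - 1e-9) || any(soma_depth > l34 + 1e-9))
    stop("soma outside [l12, l34]")
  -(soma_depth - l12) / (l34 - l12)
}

# bin index over scaled depth in [-1, 0]: 1 = most superficial bin.
# Half-open bins, deep-closed: a cell exactly on an edge goes to the deeper
# bin.
.depth_bin <- function(d, n_bins) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  # left-closed intervals on positive depth: a cell exactly on an edge
  # falls in the deeper bin
  k <- findInterval(-d, edges)
  pmin(pmax(k, 1L), n_bins)
}

# resolve scaled depths from a histology table
.table_scaled_depth <- function(table) {
  if ("scaled_depth" %in% names(table)) return(table$scaled_depth)
  scaled_depth(table$soma_depth_um, table$l12_um, table$l34_um)
}

#' Binned scaled neuron density per donor
#'
#' Splits L2-3 into `n_bins` evenly sized scaled-depth bins and reports, per
#' donor, the fraction of that donor's neurons in each bin (fractions sum to
#' 1 over all bins), then the cross-donor mean and standard deviation. The
#' first and last bins display boundary effects and are dropped from the
#' reported series (but retained in `per_donor`).
#'
#' @param table data.frame with a `donor` column and either a
#'   `scaled_depth` column or `soma_depth_um`/`l12_um`/`l34_um` columns.
#' @param n_bins Number of bins (default 20).
#' @return List: `per_donor` (donors x n_bins fraction matrix),
#'   `inner` (data.frame `bin`, `center`, `mean`, `sd` for bins
#'   `2:(n_bins-1)`).
#' @export
density_profile <- function(table, n_bins = 20) {
  if (!nrow(table)) stop("empty table")
  d <- .table_scaled_depth(table)
  donors <- sort(unique(table$donor))
  if (any(tabulate(factor(table$donor, donors)) < n_bins))
    warning("a donor has fewer cells than bins; fractions will be sparse")
  bin <- .depth_bin(d, n_bins)
  per <- t(vapply(donors, function(dn) {
    b <- bin[table$donor == dn]
    tabulate(b, n_bins) / length(b)
  }, numeric(n_bins)))
  rownames(per) <- donors
  centers <- -(seq_len(n_bins) - 0.5) / n_bins
  inner <- 2:(n_bins - 1)
  list(per_donor = per,
       inner = data.frame(bin = inner, center = centers[inner],
                          mean = colMeans(per)[inner],
                          sd = apply(per, 2, stats::sd)[inner]))
}

#' Binned soma-area statistics per donor
#'
#' Per-donor mean and standard deviation of soma area within each scaled-
#' depth bin, then the cross-donor average of each statistic. The sd of an
#' empty or singleton bin is missing (`NA`), not 0.
#'
#' @inheritParams density_profile
#' @return List: `mean_per_donor`, `sd_per_donor` (donors x n_bins),
#'   `inner` (data.frame `bin`, `center`, `mean`, `sd` averaged across
#'   donors over bins `2:(n_bins-1)`).
#' @export
soma_area_profile <- function(table, n_bins = 20) {
  if (!nrow(table)) stop("empty table")
  d <- .table_scaled_depth(table)
  donors <- sort(unique(table$donor))
  bin <- .depth_bin(d, n_bins)
  stat <- function(f) t(vapply(donors, function(dn) {
    ix <- table$donor == dn
    vapply(seq_len(n_bins), function(k) {
      a <- table$soma_area_um2[ix & bin == k]
      f(a)
    }, 0)
  }, numeric(n_bins)))
  m <- stat(function(a) if (length(a) >= 1) mean(a) else NA_real_)
  s <- stat(function(a) if (length(a) >= 2) stats::sd(a) else NA_real_)
  centers <- -(seq_len(n_bins) - 0.5) / n_bins
  inner <- 2:(n_bins - 1)
  list(mean_per_donor = m, sd_per_donor = s,
       inner = data.frame(bin = inner, center = centers[inner],
                          mean = colMeans(m, na.rm = TRUE)[inner],
                          sd = colMeans(s, na.rm = TRUE)[inner]))
}

#' Locate the mid-L3 density nadir
#'
#' Finds the minimum of the (3-bin moving-average smoothed) mean scaled-
#' density profile, restricted to scaled depths below `search_max` (default
#' -0.25, avoiding the L2 edge), and returns the bin-centre depth. A
#' monotone or flat profile returns the boundary of the searched range with
#' a low-confidence flag.
#'
#' @param profile data.frame with `center` and `mean` columns (e.g. the
#'   `inner` element of [density_profile()]), or a numeric mean-density
#'   vector with centers in its names.
#' @param search_max Most superficial scaled depth searched.
#' @param smooth_bins Moving-average width in bins (odd).
#' @return List: `nadir` (scaled depth), `confidence` (`"ok"` or `"low"`).
#' @export
find_nadir <- function(profile, search_max = -0.25, smooth_bins = 3) {
  if (is.numeric(profile))
    profile <- data.frame(center = as.numeric(names(profile)),
                          mean = unname(profile))
  ord <- order(profile$center, decreasing = TRUE)  # superficial -> deep
  cen <- profile$center[ord]; y <- profile$mean[ord]
  half <- (smooth_bins - 1) %/% 2
  sm <- vapply(seq_along(y), function(i) {
    ix <- max(1, i - half):min(length(y), i + half)
    mean(y[ix])
  }, 0)
  sel <- which(cen < search_max)
  if (!length(sel)) stop("no bins in the searched depth range")
  i_min <- sel[which.min(sm[sel])]
  flat <- diff(range(sm[sel])) < 1e-12
  at_edge <- i_min == sel[1] || i_min == sel[length(sel)]
  list(nadir = cen[i_min],
       confidence = if (flat || at_edge) "low" else "ok")
}
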