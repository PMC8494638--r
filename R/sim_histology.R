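#' Design for a synthetic laminar histology table
#'
#' Emulates NeuN-style cell tables across L2-3: neuron sampling density is
#' piecewise linear in scaled depth with a minimum (nadir) in mid-L3 and
#' highest density at the L1/L2 border, and mean soma area grows linearly
#' with depth.
#'
#' @param n_donors,cells_per_donor Counts.
#' @param nadir_position Scaled depth of the density minimum, in (-1, 0).
#'   Default -0.575, the superficial/deep L3 boundary value.
#' @param superficial_density_ratio Density at the L1/L2 border relative to
#'   the nadir, > 1 (1 gives a flat, mouse-like profile). Default 2
#'   ("decreasing by half").
#' @param area_slope Soma area change per unit scaled depth (um^2); negative
#'   values make deeper somata larger. Default -120 (area roughly doubles
#'   from L2 to deep L3).
#' @param base_area Mean soma area at scaled depth 0 (um^2).
#' @param area_sd Soma-area noise (um^2).
#' @param seed Integer seed.
#' @return Object of class `histology_design`.
#' @export
histology_design <- function(n_donors = 5, cells_per_donor = 400,
                             nadir_position = -0.575,
                             superficial_density_ratio = 2,
                             area_slope = -120, base_area = 120,
                             area_sd = 25, seed = 1L) {
  if (!(nadir_position > -1 && nadir_position < 0))
    stop("nadir_position must lie in (-1, 0)")
  if (superficial_density_ratio < 1)
    stop("superficial_density_ratio must be >= 1")
  structure(list(n_donors = n_donors, cells_per_donor = cells_per_donor,
                 nadir_position = nadir_position,
                 superficial_density_ratio = superficial_density_ratio,
                 area_slope = area_slope, base_area = base_area,
                 area_sd = area_sd, seed = as.integer(seed)),
            class = "histology_design")
}

# unnormalized piecewise-linear density over scaled depth d in [-1, 0]:
# ratio at d = 0, 1 at the nadir, mild rebound toward the L3/4 border
.hist_density <- function(d, design) {
  r <- design$superficial_density_ratio
  nd <- design$nadir_position
  deep <- 1 + (r - 1) / 2
  ifelse(d >= nd, 1 + (r - 1) * (d - nd) / (0 - nd),
         1 + (deep - 1) * (nd - d) / (nd + 1))
}

#' Simulate a per-donor histology cell table
#'
#' Samples cell depths from the design's piecewise-linear density (inverse
#' CDF on a fine grid) and soma areas from the linear depth trend plus
#' Gaussian noise. Each donor receives its own L1/L2 and L3/4 boundary
#' depths so the scaled-depth normalization is exercised.
#'
#' @param design A [histology_design()].
#' @return data.frame: `donor`, `soma_depth_um`, `soma_area_um2`, `l12_um`,
#'   `l34_um`, `scaled_depth_true`.
#' @export
simulate_histology <- function(design) {
  stopifnot(inherits(design, "histology_design"))
  set.seed(design$seed)
  grid <- seq(-1, 0, length.out = 2001)
  dens <- .hist_density(grid, design)
  cdf <- cumsum(dens); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  out <- vector("list", design$n_donors)
  for (dn in seq_len(design$n_donors)) {
    u <- stats::runif(design$cells_per_donor)
    d <- stats::approx(cdf, grid, xout = u, ties = "ordered")$y
    area <- design$base_area + design$area_slope * d +
      stats::rnorm(design$cells_per_donor, 0, design$area_sd)
    l12 <- stats::rnorm(1, 280, 15)
    l34 <- stats::rnorm(1, 1200, 60)
    out[[dn]] <- data.frame(
      donor = paste0("donor", dn),
      soma_depth_um = l12 + (-d) * (l34 - l12),
      soma_area_um2 = pmax(20, area),
      l12_um = l12, l34_um = l34,
      scaled_depth_true = d)
  }
  do.call(rbind, out)
}
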