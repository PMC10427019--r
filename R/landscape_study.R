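# Canonical 1D effective-landscape studies: one particle against a
# single Gaussian target, or two bonded particles against a two-peak
# target with unequal amplitudes.  These reproduce, at desk scale, the
# qualitative differences between the similarity kinds: the
# relative-entropy potential is long-ranged and near-harmonic for one
# particle, and for two particles has its minima at the two Gaussian
# centers (either assignment) separated by a single swap barrier,
# whereas the inner product prefers both particles stacked on the
# highest peak.

#' Build and scan a canonical 1D landscape study
#'
#' With one particle the target is a single Gaussian of width `sigma` at
#' the origin and the scan covers `+/- scan_range` around it.  With two
#' particles the target is a pair of Gaussians at `+/- peak_sep / 2`
#' with amplitudes `peak_amps` (unequal by default, the second peak
#' higher) and the scan covers both centers.  The spreading truncation is
#' chosen to cover the whole scan domain, so the landscape reflects the
#' similarity potential itself rather than the truncation sphere.
#'
#' @param kind similarity kind or token.
#' @param n_particles 1 or 2.
#' @param sigma Gaussian width of target and model (A).
#' @param peak_sep separation of the two target peaks (A; two-particle
#'   study).
#' @param peak_amps amplitudes of the two target peaks.
#' @param spacing grid spacing (A).
#' @param scan_range half-width of the one-particle scan (units of
#'   sigma).
#' @param scan_step scan step (units of sigma).
#' @param bond_weight weight of the harmonic bond (two-particle study;
#'   `r0 = peak_sep / 2`, the bond that keeps the particles at half the
#'   distance between the Gaussian centers).
#' @param k_bond bond force constant (energy/A^2).
#' @return A list with `system`, `target`, `params`, `centers`, `sigma`,
#'   and `scan` (the [landscape_scan()] result).
#' @export
landscape_study <- function(kind, n_particles = 1, sigma = 1,
                            peak_sep = 6, peak_amps = c(1, 2),
                            spacing = 0.25, scan_range = 3,
                            scan_step = 0.1, bond_weight = 0,
                            k_bond = 1) {
  kind <- similarity_kind(kind)
  if (!n_particles %in% c(1L, 2L)) stop("'n_particles' must be 1 or 2")
  if (n_particles == 1L) {
    centers <- 0
    amps <- 1
    scan <- seq(-scan_range * sigma, scan_range * sigma,
                by = scan_step * sigma)
  } else {
    centers <- c(-peak_sep / 2, peak_sep / 2)
    amps <- peak_amps
    scan <- seq(centers[1] - 2 * sigma, centers[2] + 2 * sigma,
                by = scan_step * sigma)
  }
  extent <- max(abs(scan)) + 6 * sigma
  nx <- 2L * as.integer(ceiling(extent / spacing)) + 1L
  geom <- density_grid(array(0, c(nx, 1L, 1L)),
                       origin = c(-(nx - 1) / 2 * spacing, 0, 0),
                       spacing = spacing)
  # truncation sphere covering the whole grid for every scan position
  cutoff <- (2 * extent + spacing) / sigma
  params <- spread_params(sigma, cutoff_multiple = cutoff,
                          normalize = FALSE)
  src <- atom_set(cbind(centers, 0, 0), amplitudes = amps)
  target <- spread_density(src, geom, params)
  start <- cbind(rep(0, n_particles), 0, 0)
  bonds <- if (n_particles == 2L && bond_weight > 0) {
    data.frame(i = 1, j = 2, k_bond = k_bond, r0 = peak_sep / 2)
  } else NULL
  system <- toy_system(atom_set(start, amplitudes = rep(1, n_particles)),
                       bonds = bonds, kT = 1)
  scan_res <- landscape_scan(system, target, kind, scan, params,
                             bond_weight = bond_weight, fit_weight = 1)
  list(system = system, target = target, params = params,
       centers = centers, sigma = sigma, scan = scan_res)
}
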