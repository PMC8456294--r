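#' Log partition function of the tethered chains
#'
#' `ln Z = sum_i ln qtilde(r_tether_i, N)`, with `qtilde` evaluated at the
#' tether positions by the discretization's interpolation.
#'
#' @param qtilde A solved [solve_qtilde()] propagator.
#' @param tethers A [place_tethers()] tether set.
#' @return `ln Z` (dimensionless; free energy is `-ln Z` in kBT).
#' @export
log_partition <- function(qtilde, tethers) {
  M <- qtilde$domain$interp(tethers$positions)
  qv <- as.numeric(M %*% qtilde$final)
  if (any(qv <= 0)) stop("qtilde <= 0 at a tether (tether unreachable)")
  sum(log(qv))
}

#' Free-energy change of cargo insertion
#'
#' Computes `dF = F_cargo - F_empty = -(ln Z_cargo - ln Z_empty)` in kBT.
#' Both solves use the same grid parameters so discretization bias cancels
#' in the difference.  For an inert, axis-centred cargo the axisymmetric
#' fast path is used automatically.
#'
#' @param pore A [pore_geometry()].
#' @param chain A [chain_parameters()].
#' @param cargo A [cargo_spec()] or `NULL` (returns 0).
#' @param tethers A [place_tethers()] tether set.
#' @param cfg A [solver_config()].
#' @param gamma Interfacial energy in kBT for attractive cargoes (ignored
#'   when the cargo has no spots).
#' @param r_cutoff Adsorption range in nm.
#' @param lnZ_empty Optional precomputed empty-pore `ln Z` (same pore,
#'   chain, cfg) to avoid re-solving during scans.
#' @param method Domain representation passed to [build_domain()].
#' @return `dF` in kBT, with attribute `lnZ_empty` for reuse.
#' @export
free_energy_difference <- function(pore, chain, cargo, tethers,
                                   cfg = solver_config(), gamma = 0,
                                   r_cutoff = 0.86, lnZ_empty = NULL,
                                   method = "auto") {
  if (is.null(cargo)) return(structure(0, lnZ_empty = lnZ_empty))
  attractive <- !is.null(cargo$spots) && cargo$spots$N_bind > 0 && gamma > 0
  dom_method <- if (attractive) "grid3d" else method
  # with the potential switched off the spots are irrelevant to the domain,
  # so a centred cargo can still take the axisymmetric fast path
  cargo_dom <- cargo
  if (!attractive) cargo_dom$spots <- NULL
  dom_c <- build_domain(pore, cargo_dom, cfg_disc_params(cfg),
                        method = dom_method)
  if (is.null(lnZ_empty)) {
    # the empty reference must live on the same kind of grid as the cargo
    # solve so discretization bias cancels in the difference
    e_method <- if (dom_c$type == "grid3d") "grid3d" else "auto"
    dom_e <- build_domain(pore, NULL, cfg_disc_params(cfg), method = e_method)
    lnZ_empty <- log_partition(solve_qtilde(dom_e, chain, cfg = cfg), tethers)
  }
  pot <- if (attractive) adsorption_potential(cargo, gamma, r_cutoff) else NULL
  lnZ_c <- log_partition(solve_qtilde(dom_c, chain, pot = pot, cfg = cfg),
                         tethers)
  structure(-(lnZ_c - lnZ_empty), lnZ_empty = lnZ_empty)
}

#' Orientation-averaged free-energy change
#'
#' For attractive cargoes `F_cargo` depends on the cargo orientation; the
#' averaged free energy is the arithmetic mean of `F_cargo` over the
#' orientation grid (default the 220-point `theta x phi` grid of
#' [orientation_grid()]), minus `F_empty`.
#'
#' @inheritParams free_energy_difference
#' @param orientations Matrix of `(theta, phi)` rows.
#' @return `dF_bar` in kBT, with attribute `lnZ_empty`.
#' @export
orientation_averaged_dF <- function(pore, chain, cargo, tethers,
                                    cfg = solver_config(), gamma = 0,
                                    r_cutoff = 0.86,
                                    orientations = orientation_grid(),
                                    lnZ_empty = NULL) {
  if (is.null(cargo$spots) || cargo$spots$N_bind == 0 || gamma == 0)
    return(free_energy_difference(pore, chain, cargo, tethers, cfg,
                                  gamma = 0, lnZ_empty = lnZ_empty))
  if (is.null(lnZ_empty)) {
    dom_e <- build_domain(pore, NULL, cfg_disc_params(cfg), method = "grid3d")
    lnZ_empty <- log_partition(solve_qtilde(dom_e, chain, cfg = cfg), tethers)
  }
  # geometry (Dirichlet mask) is orientation-independent: build once
  dom_c <- build_domain(pore, cargo, cfg_disc_params(cfg), method = "grid3d")
  Fs <- apply(orientations, 1, function(or) {
    cg <- cargo; cg$orientation <- as.numeric(or[c("theta", "phi")])
    pot <- adsorption_potential(cg, gamma, r_cutoff)
    -log_partition(solve_qtilde(dom_c, chain, pot = pot, cfg = cfg), tethers)
  })
  structure(mean(Fs) - (-lnZ_empty), lnZ_empty = lnZ_empty,
            F_orientations = Fs)
}

#' Mean segment-density map
#'
#' `rho(r) = integral_0^N ds q_c(r, s) qtilde(r, N - s)` by the trapezoidal
#' rule over the stored contour steps; normalized so that
#' `integral(rho) dr = n * N`.
#'
#' @param qtilde,qc Propagators solved with `store_all = TRUE` on the same
#'   domain and contour grid.
#' @param chain The matching [chain_parameters()].
#' @return An object of class `npc_density` with node values `rho`
#'   (segments/nm^3), node volumes and the domain.
#' @export
mean_density <- function(qtilde, qc, chain) {
  if (is.null(qtilde$store) || is.null(qc$store))
    stop("both propagators must be solved with store_all = TRUE")
  if (!identical(dim(qtilde$store), dim(qc$store)) ||
      !isTRUE(all.equal(qtilde$s, qc$s)))
    stop("propagators are on mismatched discretizations or contour grids")
  K <- qc$K
  w <- rep(1, K + 1); w[c(1, K + 1)] <- 0.5      # trapezoid, uniform ds
  # sum_k w_k q_c(., s_k) qtilde(., N - s_k); the qtilde store is indexed by
  # s, so N - s_k is column K + 1 - k
  rho <- as.numeric((qc$store * qtilde$store[, (K + 1):1]) %*% w) * qc$ds
  rho[rho < 0 & rho > -1e-12] <- 0
  structure(list(rho = rho, vol = qtilde$domain$vol,
                 domain = qtilde$domain, chain = chain,
                 total = sum(rho * qtilde$domain$vol)),
            class = "npc_density")
}

#' @export
print.npc_density <- function(x, ...) {
  cat(sprintf("Mean segment density: %d nodes, integral %.1f (target n*N = %.1f)\n",
              length(x$rho), x$total, x$chain$n * x$chain$N))
  invisible(x)
}

#' Critical transportable cargo diameter
#'
#' Linearly interpolates the first upward crossing of `dF = 1 kBT` on the
#' diameter scan.  If the curve never reaches 1 kBT, `NA` is returned (a
#' valid outcome: every scanned cargo passes).  If it crosses more than
#' once (possible for strongly attractive cargoes), the crossing into the
#' final `dF > 1` region is used and a warning is issued.
#'
#' @param scan A data frame with columns `d_cargo_nm` (strictly increasing)
#'   and `dF_kBT`, or an `npc_scan` object.
#' @return `d*` in nm, or `NA` when no crossing exists.
#' @examples
#' critical_diameter(data.frame(d_cargo_nm = c(4, 6), dF_kBT = c(0.8, 1.2)))
#' @export
critical_diameter <- function(scan) {
  df <- as.data.frame(scan)
  if (nrow(df) < 2) stop("scan needs at least two rows")
  d <- df$d_cargo_nm; f <- df$dF_kBT
  if (is.unsorted(d, strictly = TRUE)) stop("diameters must be strictly increasing")
  above <- f > 1
  if (!any(above)) return(NA_real_)
  n_cross <- sum(diff(above) != 0)
  if (n_cross > 1)
    warning("dF crosses 1 kBT more than once; using the final upward crossing")
  up <- which(!above[-length(f)] & above[-1])    # upward crossings
  if (length(up) == 0) {
    # already above 1 at the smallest diameter
    return(d[1])
  }
  i <- up[length(up)]
  d[i] + (d[i + 1] - d[i]) * (1 - f[i]) / (f[i + 1] - f[i])
}

#' Free volume available to the chains
#'
#' `v = pi D_pore^2 h_pore / 4 - pi d_cargo^3 / 6` (cylinder minus sphere,
#' nm^3).
#'
#' @param pore A [pore_geometry()].
#' @param d_cargo Cargo diameter in nm (0 for the empty pore).
#' @return Volume in nm^3.
#' @export
free_volume <- function(pore, d_cargo = 0) {
  pi * pore$diameter^2 * pore$height / 4 - pi * d_cargo^3 / 6
}

#' Mean force along the cargo insertion path
#'
#' Computes `dF` at a sequence of axial cargo-centre positions and takes
#' the central-difference slope `-d(dF)/dz`, converted to piconewtons via
#' 1 kBT/nm = 4.114 pN (T = 298 K).  Two summaries are attached: the
#' *mean insertion force* (insertion work over path length,
#' `|dF(end) - dF(start)| / |z(end) - z(start)|`), which is the quantity
#' meant by "the mean force to insert the cargo", and the maximum local
#' slope magnitude.
#'
#' @inheritParams free_energy_difference
#' @param d_cargo Cargo diameter in nm.
#' @param z_path Axial centre positions (nm), from the pore mouth towards
#'   the pore centre; the sphere may protrude through the open ends but
#'   must not touch the side wall.
#' @return An object of class `npc_force_profile`: data frame of
#'   `(z_nm, dF_kBT, force_pN)` with attributes `mean_force_pN` and
#'   `max_force_pN`.
#' @export
mean_insertion_force <- function(pore, chain, d_cargo, tethers,
                                 cfg = solver_config(),
                                 z_path = NULL, lnZ_empty = NULL) {
  if (is.null(z_path))
    z_path <- seq(pore$height, pore$height / 2, by = -2)
  if (length(z_path) < 3) stop("z_path needs at least three positions")
  dFs <- numeric(length(z_path))
  for (i in seq_along(z_path)) {
    cg <- cargo_spec(d_cargo, center = c(0, 0, z_path[i]))
    v <- free_energy_difference(pore, chain, cg, tethers, cfg,
                                lnZ_empty = lnZ_empty)
    lnZ_empty <- attr(v, "lnZ_empty")
    dFs[i] <- as.numeric(v)
  }
  kBT_per_nm_to_pN <- 4.114            # kBT = 4.114 pN nm at 298 K
  m <- length(z_path)
  force <- rep(NA_real_, m)
  force[2:(m - 1)] <- -(dFs[3:m] - dFs[1:(m - 2)]) /
    (z_path[3:m] - z_path[1:(m - 2)]) * kBT_per_nm_to_pN
  out <- data.frame(z_nm = z_path, dF_kBT = dFs, force_pN = force)
  structure(out,
            mean_force_pN = abs(dFs[m] - dFs[1]) /
              abs(z_path[m] - z_path[1]) * kBT_per_nm_to_pN,
            max_force_pN = max(abs(force), na.rm = TRUE),
            lnZ_empty = lnZ_empty,
            class = c("npc_force_profile", "data.frame"))
}

#' Free energy versus cargo position
#'
#' Scans `dF` over axial (along the pore axis) and lateral (radial)
#' displacements of the cargo centre from the pore midpoint.
#'
#' @inheritParams mean_insertion_force
#' @param axial Axial offsets from `h/2` (nm).
#' @param lateral Lateral (x) offsets from the axis (nm); these require the
#'   3-D domain.
#' @return Data frame `(direction, offset_nm, dF_kBT)`.
#' @export
position_scan <- function(pore, chain, d_cargo, tethers,
                          cfg = solver_config(), axial = c(-4, 0, 4),
                          lateral = c(0, 2, 4), lnZ_empty = NULL) {
  rows <- list()
  for (dz in axial) {
    cg <- cargo_spec(d_cargo, center = c(0, 0, pore$height / 2 + dz))
    v <- free_energy_difference(pore, chain, cg, tethers, cfg,
                                lnZ_empty = lnZ_empty)
    lnZ_empty <- attr(v, "lnZ_empty")
    rows[[length(rows) + 1]] <- data.frame(direction = "axial",
                                           offset_nm = dz,
                                           dF_kBT = as.numeric(v))
  }
  # lateral displacements break axisymmetry: use the 3-D grid throughout,
  # with a matched 3-D empty reference
  lnZ_empty3 <- NULL
  for (dx in lateral) {
    cg <- cargo_spec(d_cargo, center = c(dx, 0, pore$height / 2))
    v <- free_energy_difference(pore, chain, cg, tethers, cfg,
                                lnZ_empty = lnZ_empty3, method = "grid3d")
    lnZ_empty3 <- attr(v, "lnZ_empty")
    rows[[length(rows) + 1]] <- data.frame(direction = "lateral",
                                           offset_nm = dx,
                                           dF_kBT = as.numeric(v))
  }
  do.call(rbind, rows)
}
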