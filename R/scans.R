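#' Run configuration with reference NPC parameters
#'
#' Bundles all geometry, chain, cargo, binding and numerics parameters.
#' Defaults are the reference NPC values: n = 80 FG-Nups, Kuhn length
#' b = 0.86 nm, contour length l = 180 nm, pore diameter 40 nm, pore
#' height 40 nm.
#'
#' @param pore_diameter_nm,pore_height_nm Pore geometry (nm).
#' @param chain_kuhn_nm,chain_contour_nm,chain_count Chain parameters.
#' @param cargo_grid_nm Diameter scan grid (nm).
#' @param gamma_kBT Interfacial energy (kBT) for attractive scans.
#' @param coverage `S/S*` values for uniform-cap scans.
#' @param kappa Kent concentration values for clustered scans.
#' @param ds Contour step.
#' @param spacing_nm Grid spacing (`NULL` = representation default).
#' @param orientations Orientation subset for averaged scans (`NULL` = the
#'   full 220-point grid).
#' @param vertex_density Cargo-surface vertex density (vertices/nm^2).
#' @param r_cutoff_nm Adsorption range (nm).
#' @param tether_rings Rings of the synthetic tether layout.
#' @param tether_file Optional CSV overriding the synthetic tethers.
#' @param seed Base RNG seed for randomized spot layouts.
#' @param out_dir Output directory for CSV/JSON artifacts (`NULL` = none).
#' @return An object of class `npc_config`.
#' @export
npc_config <- function(pore_diameter_nm = 40, pore_height_nm = 40,
                       chain_kuhn_nm = 0.86, chain_contour_nm = 180,
                       chain_count = 80,
                       cargo_grid_nm = seq(2, 38, by = 2),
                       gamma_kBT = 1.0, coverage = 0.2, kappa = NULL,
                       ds = 0.4, spacing_nm = NULL, orientations = NULL,
                       vertex_density = 1, r_cutoff_nm = 0.86,
                       tether_rings = 2, tether_file = NULL,
                       seed = 1L, out_dir = NULL) {
  structure(list(pore_diameter_nm = pore_diameter_nm,
                 pore_height_nm = pore_height_nm,
                 chain_kuhn_nm = chain_kuhn_nm,
                 chain_contour_nm = chain_contour_nm,
                 chain_count = chain_count,
                 cargo_grid_nm = cargo_grid_nm,
                 gamma_kBT = gamma_kBT, coverage = coverage, kappa = kappa,
                 ds = ds, spacing_nm = spacing_nm,
                 orientations = orientations,
                 vertex_density = vertex_density,
                 r_cutoff_nm = r_cutoff_nm,
                 tether_rings = tether_rings, tether_file = tether_file,
                 seed = seed, out_dir = out_dir),
            class = "npc_config")
}

#' Read/write a run configuration (YAML)
#'
#' `read_config()` and `write_config()` round-trip an [npc_config()]
#' through a YAML file.
#'
#' @param file YAML path.
#' @param config An `npc_config`.
#' @return `read_config` returns an `npc_config`; `write_config` the path,
#'   invisibly.
#' @export
read_config <- function(file) {
  vals <- yaml::read_yaml(file)
  cfg <- do.call(npc_config, vals[names(vals) %in% names(formals(npc_config))])
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, file) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, file)
  invisible(file)
}

config_objects <- function(config) {
  pore <- pore_geometry(config$pore_diameter_nm, config$pore_height_nm)
  chain <- chain_parameters(b = config$chain_kuhn_nm,
                            l = config$chain_contour_nm,
                            n = config$chain_count)
  tethers <- if (is.null(config$tether_file))
    place_tethers(pore, n = config$chain_count, rings = config$tether_rings)
  else place_tethers(pore, mode = "from-file", source = config$tether_file)
  cfg <- solver_config(ds = config$ds, spacing = config$spacing_nm)
  list(pore = pore, chain = chain, tethers = tethers, cfg = cfg)
}

new_scan <- function(df, meta) {
  structure(df, meta = meta, class = c("npc_scan", "data.frame"))
}

#' Inert-cargo free-energy scan
#'
#' Runs [free_energy_difference()] with V = 0 over the configured cargo
#' diameter grid (axisymmetric fast path) and extracts the critical
#' diameter.  A failure at one diameter is recorded as `NA` and does not
#' abort the scan.
#'
#' @param config An [npc_config()].
#' @param verbose Print per-diameter progress.
#' @return An `npc_scan` data frame with columns
#'   `d_cargo_nm, dF_kBT, dF_is_averaged, gamma_kBT, S_over_Sstar, kappa,
#'   seed` and attributes `meta` (including `d_star_nm`).
#' @export
run_inert_scan <- function(config = npc_config(), verbose = FALSE) {
  ob <- config_objects(config)
  lnZ_empty <- NULL
  dFs <- rep(NA_real_, length(config$cargo_grid_nm))
  for (i in seq_along(config$cargo_grid_nm)) {
    d <- config$cargo_grid_nm[i]
    t0 <- proc.time()[3]
    res <- tryCatch({
      cg <- cargo_spec(d, center = c(0, 0, ob$pore$height / 2))
      v <- free_energy_difference(ob$pore, ob$chain, cg, ob$tethers, ob$cfg,
                                  lnZ_empty = lnZ_empty)
      lnZ_empty <- attr(v, "lnZ_empty")
      as.numeric(v)
    }, error = function(e) {
      warning(sprintf("d = %g nm failed: %s", d, conditionMessage(e)))
      NA_real_
    })
    dFs[i] <- res
    if (verbose)
      message(sprintf("d = %5.1f nm  dF = %10.4f kBT  (%.1f s)",
                      d, res, proc.time()[3] - t0))
  }
  df <- data.frame(d_cargo_nm = config$cargo_grid_nm, dF_kBT = dFs,
                   dF_is_averaged = FALSE, gamma_kBT = 0,
                   S_over_Sstar = 0, kappa = NA_real_, seed = NA_integer_)
  ok <- !is.na(df$dF_kBT)
  d_star <- if (sum(ok) >= 2) critical_diameter(df[ok, ]) else NA_real_
  scan <- new_scan(df, meta = list(kind = "inert", d_star_nm = d_star,
                                   config = config))
  maybe_write_scan(scan, config, "inert_scan")
  scan
}

#' Attractive-cargo orientation-averaged scan
#'
#' For each diameter, builds the binding-spot layout (uniform cap at the
#' configured `S/S*`, or Kent-distributed spots when `config$kappa` is
#' set), computes the orientation-averaged free-energy difference, and
#' extracts the critical diameter.  The absolute binding area
#' `S = coverage * S*` is held fixed across cargo sizes; when a small cargo
#' cannot host it the coverage is clamped at 1 with a warning.
#'
#' @inheritParams run_inert_scan
#' @return An `npc_scan` (orientation-averaged `dF_kBT`).
#' @export
run_attractive_scan <- function(config = npc_config(), verbose = FALSE) {
  ob <- config_objects(config)
  if (config$gamma_kBT < 0.9 || config$gamma_kBT > 1.2)
    warning("gamma outside the reference range 0.9-1.2 kBT")
  ors <- config$orientations
  if (is.null(ors)) ors <- orientation_grid()
  S_abs <- config$coverage * pi * 20^2
  lnZ_empty <- NULL
  dFs <- rep(NA_real_, length(config$cargo_grid_nm))
  for (i in seq_along(config$cargo_grid_nm)) {
    d <- config$cargo_grid_nm[i]
    dFs[i] <- tryCatch({
      verts <- sphere_vertices(d, density = config$vertex_density)
      cov_d <- S_abs / (pi * d^2)
      if (cov_d > 1) {
        warning(sprintf("d = %g nm cannot host S/S* = %g; clamping coverage at 1",
                        d, config$coverage))
        cov_d <- 1
      }
      spots <- if (is.null(config$kappa))
        uniform_cap_spots(verts, cov_d)
      else kent_spots(verts, n_bind = round(cov_d * nrow(verts)),
                      params = kent_params(config$kappa),
                      seed = config$seed)
      cg <- cargo_spec(d, center = c(0, 0, ob$pore$height / 2), spots = spots)
      v <- orientation_averaged_dF(ob$pore, ob$chain, cg, ob$tethers, ob$cfg,
                                   gamma = config$gamma_kBT,
                                   r_cutoff = config$r_cutoff_nm,
                                   orientations = ors,
                                   lnZ_empty = lnZ_empty)
      lnZ_empty <- attr(v, "lnZ_empty")
      if (verbose) message(sprintf("d = %5.1f nm  dF_bar = %9.4f kBT", d, v))
      as.numeric(v)
    }, error = function(e) {
      warning(sprintf("d = %g nm failed: %s", d, conditionMessage(e)))
      NA_real_
    })
  }
  df <- data.frame(d_cargo_nm = config$cargo_grid_nm, dF_kBT = dFs,
                   dF_is_averaged = TRUE, gamma_kBT = config$gamma_kBT,
                   S_over_Sstar = config$coverage,
                   kappa = if (is.null(config$kappa)) NA_real_ else config$kappa,
                   seed = config$seed)
  ok <- !is.na(df$dF_kBT)
  d_star <- if (sum(ok) >= 2) critical_diameter(df[ok, ]) else NA_real_
  scan <- new_scan(df, meta = list(kind = "attractive", d_star_nm = d_star,
                                   config = config))
  maybe_write_scan(scan, config, "attractive_scan")
  scan
}

maybe_write_scan <- function(scan, config, stem) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_scan_csv(scan, file.path(config$out_dir, paste0(stem, ".csv")))
  meta <- attr(scan, "meta")
  jsonlite::write_json(list(kind = meta$kind, d_star_nm = meta$d_star_nm),
                       file.path(config$out_dir, paste0(stem, "_dstar.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Write a scan table to CSV
#'
#' @param scan An `npc_scan`.
#' @param file Output path.
#' @export
write_scan_csv <- function(scan, file) {
  utils::write.csv(as.data.frame(scan), file, row.names = FALSE)
  invisible(file)
}

#' @export
print.npc_scan <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Free-energy scan (%s), %d diameters\n", meta$kind, nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (!is.null(meta$d_star_nm))
    cat(sprintf("critical diameter d* = %s nm\n",
                if (is.na(meta$d_star_nm)) "none (no dF = 1 kBT crossing)"
                else sprintf("%.2f", meta$d_star_nm)))
  invisible(x)
}

#' @export
plot.npc_scan <- function(x, ...) {
  f <- pmax(x$dF_kBT, 1e-3)
  graphics::plot(x$d_cargo_nm, f, log = "y", type = "b", pch = 16,
                 xlab = "cargo diameter (nm)",
                 ylab = expression(Delta * F ~ (k[B] * T)), ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Run the built-in validation suite
#'
#' Executes the package's main consistency checks on small instances:
#' half-space erf oracle, pure-Neumann identity (dF = 0 in an obstacle-free
#' domain), density normalization, inert-monotonicity, resolution
#' convergence of the empty-pore free energy, and Green-function symmetry.
#' Failures are report rows, not errors.
#'
#' @param config An [npc_config()]; the checks use scaled-down instances
#'   derived from it.
#' @return Data frame `(check, value, threshold, pass)` of class
#'   `npc_validation`.
#' @export
run_validation_suite <- function(config = npc_config()) {
  rows <- list()
  add <- function(check, value, threshold, pass)
    rows[[length(rows) + 1]] <<- data.frame(check = check, value = value,
                                            threshold = threshold, pass = pass)
  b <- config$chain_kuhn_nm
  # 1. half-space erf oracle at the production resolution
  er <- error_ratio_control(b = b, spacing = 0.4, ds = config$ds)
  add("halfspace-erf-max-ratio", er$max_ratio, 0.05, er$max_ratio < 0.05)

  # 2. small pore: density normalization
  pore <- pore_geometry(16, 16)
  chain <- chain_parameters(b = b, l = 40, n = 8)
  tethers <- place_tethers(pore, n = 8)
  cfg <- solver_config(ds = config$ds, store_all = TRUE)
  dom <- build_domain(pore, NULL, disc_params())
  qt <- solve_qtilde(dom, chain, cfg = cfg)
  qc <- solve_qc(dom, chain, tethers, qt, cfg = cfg)
  rho <- mean_density(qt, qc, chain)
  err <- abs(rho$total - chain$n * chain$N) / (chain$n * chain$N)
  add("density-normalization", err, 0.01, err < 0.01)

  # 3. inert monotonicity on a short scan
  cfg2 <- solver_config(ds = config$ds)
  lnZ <- NULL
  ds_scan <- c(4, 8, 12)
  dFs <- vapply(ds_scan, function(d) {
    v <- free_energy_difference(pore, chain, cargo_spec(d, c(0, 0, 8)),
                                tethers, cfg2, lnZ_empty = lnZ)
    lnZ <<- attr(v, "lnZ_empty")
    as.numeric(v)
  }, numeric(1))
  add("inert-monotone", min(diff(dFs)), 0, all(diff(dFs) > 0))

  # 4. resolution convergence: a 2x spatial refinement moves dF by < 15%
  # (the staircase cargo boundary converges first order in the spacing)
  f_coarse <- free_energy_difference(pore, chain, cargo_spec(8, c(0, 0, 8)),
                                     tethers, solver_config(ds = config$ds,
                                                            spacing = 0.8))
  f_fine <- free_energy_difference(pore, chain, cargo_spec(8, c(0, 0, 8)),
                                   tethers, solver_config(ds = config$ds,
                                                          spacing = 0.4))
  dd <- abs(as.numeric(f_coarse) - as.numeric(f_fine)) / abs(as.numeric(f_fine))
  add("resolution-convergence-dF", dd, 0.15, dd < 0.15)

  # 5. Green-function symmetry on the small pore
  gs <- green_symmetry_gap(dom, chain, cfg2)
  add("green-symmetry", gs, 1e-8, gs < 1e-8)

  out <- do.call(rbind, rows)
  class(out) <- c("npc_validation", "data.frame")
  out
}

# relative gap between propagated point-source masses a->b and b->a
green_symmetry_gap <- function(domain, chain, cfg) {
  n <- domain$n
  ia <- max(1L, round(n / 3)); ib <- min(n, round(2 * n / 3))
  ga <- mde_march(domain, chain, cfg, unit_source(domain, ia))$final[ib]
  gb <- mde_march(domain, chain, cfg, unit_source(domain, ib))$final[ia]
  abs(ga - gb) / max(abs(ga), .Machine$double.xmin)
}

unit_source <- function(domain, id) {
  q0 <- numeric(domain$n); q0[id] <- 1 / domain$vol[id]; q0
}

#' @export
print.npc_validation <- function(x, ...) {
  cat("Validation suite:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(if (all(x$pass)) "all checks passed\n" else "SOME CHECKS FAILED\n")
  invisible(x)
}
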