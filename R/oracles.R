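#' Closed-form half-space propagator
#'
#' The end-integrated propagator of a Gaussian chain next to an absorbing
#' plane at z = 0 (method of images for the modified diffusion equation
#' with diffusivity b^2/6):
#' `qtilde(z, s) = erf(z * sqrt(3 / (2 b^2 s)))`.
#'
#' @param z Distance from the wall (nm, >= 0).
#' @param s Contour position (> 0).
#' @param b Kuhn length (nm).
#' @return `qtilde` value(s) in `[0, 1]`.
#' @examples
#' halfspace_qtilde(1, 180 / 0.86, 0.86)  # ~0.111
#' @export
halfspace_qtilde <- function(z, s, b = 0.86) {
  stopifnot(all(z >= 0), s > 0, b > 0)
  x <- z * sqrt(3 / (2 * b^2 * s))
  2 * stats::pnorm(x * sqrt(2)) - 1      # erf(x)
}

#' Monte Carlo survival of a chain next to an absorbing plane
#'
#' Brute-force sampler for the half-space problem: discrete Gaussian-step
#' chains (per-coordinate step variance `b^2 ds / 3`, matching the MDE
#' diffusivity) started at distance `z0` from an absorbing plane, with
#' Brownian-bridge crossing corrections to remove the O(sqrt(ds))
#' discrete-absorption bias.
#'
#' @param z0 Start distance from the wall (nm).
#' @param N Reduced chain length.
#' @param b Kuhn length (nm).
#' @param ds Contour step of the sampler.
#' @param n_samples Number of chains.
#' @param seed RNG seed.
#' @return List with `estimate`, `se` and `method` (an `oracle_result`).
#' @export
mc_halfspace_survival <- function(z0, N, b = 0.86, ds = 0.1,
                                  n_samples = 2000, seed = 1L) {
  K <- ceiling(N / ds); ds_eff <- N / K
  sd_step <- b * sqrt(ds_eff / 3)
  with_local_seed(seed, {
    steps <- matrix(stats::rnorm(K * n_samples, sd = sd_step), nrow = K)
    z <- z0 + apply(steps, 2, cumsum)
    # hard absorption at discrete positions
    alive <- matrix(z > 0, nrow = K)
    surv <- colSums(alive) == K
    # bridge correction: probability of not crossing between steps
    zprev <- rbind(rep(z0, n_samples), z[-K, , drop = FALSE])
    p_nocross <- 1 - exp(-2 * pmax(zprev, 0) * pmax(z, 0) / sd_step^2)
    w <- surv * apply(p_nocross, 2, prod)
    oracle_result(mean(w), stats::sd(w) / sqrt(n_samples), "mc-halfspace")
  })
}

oracle_result <- function(estimate, se, method) {
  structure(list(estimate = estimate, se = se, method = method),
            class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("%s oracle: %.5g +/- %.2g\n", x$method, x$estimate, x$se))
  invisible(x)
}

#' Monte Carlo estimate of the insertion free-energy difference
#'
#' Direct sampling of the chain partition function: discrete Gaussian-step
#' chains are grown from each tether, rejected when they touch the pore
#' wall or the cargo (with planar Brownian-bridge crossing corrections on
#' both surfaces), reflected at the open ends (the zero-flux condition),
#' and Boltzmann-weighted by the adsorption potential.  `Z_i` is the mean
#' chain weight; the estimate is
#' `dF = -sum_i (ln Z_cargo_i - ln Z_empty_i)` with a delta-method
#' standard error.  Intended for small instances as an independent check of
#' the PDE solver, not for production-scale runs.
#'
#' @param pore A [pore_geometry()].
#' @param chain A [chain_parameters()] (small N recommended).
#' @param tethers A [place_tethers()] tether set.
#' @param cargo A [cargo_spec()] or `NULL`.
#' @param gamma Interfacial energy (kBT) when the cargo carries spots.
#' @param r_cutoff Adsorption range (nm).
#' @param ds Sampler contour step.
#' @param n_samples Chains per tether.
#' @param seed RNG seed.
#' @return An `oracle_result` with `estimate` (dF in kBT) and `se`.
#' @export
mc_chain_free_energy <- function(pore, chain, tethers, cargo = NULL,
                                 gamma = 0, r_cutoff = 0.86, ds = 0.05,
                                 n_samples = 2000, seed = 1L) {
  w_cargo <- mc_run_weights(pore, chain, tethers, cargo, gamma, r_cutoff,
                            ds, n_samples, seed)
  w_empty <- mc_run_weights(pore, chain, tethers, NULL, 0, r_cutoff,
                            ds, n_samples, seed + 10000L)
  if (any(w_cargo$mean == 0) || any(w_empty$mean == 0))
    stop("zero accepted samples for at least one tether; ",
         "increase n_samples or enlarge the geometry")
  est <- -sum(log(w_cargo$mean) - log(w_empty$mean))
  # delta method: var(log mean) ~ var(w) / (n mean^2)
  v <- sum(w_cargo$var / (n_samples * w_cargo$mean^2)) +
    sum(w_empty$var / (n_samples * w_empty$mean^2))
  oracle_result(est, sqrt(v), "mc-chain")
}

mc_run_weights <- function(pore, chain, tethers, cargo, gamma, r_cutoff,
                           ds, n_samples, seed) {
  K <- ceiling(chain$N / ds); ds_eff <- chain$N / K
  sd_step <- chain$b * sqrt(ds_eff / 3)
  R <- pore$radius; H <- pore$height
  spots <- NULL
  if (!is.null(cargo) && !is.null(cargo$spots) && cargo$spots$N_bind > 0 &&
      gamma > 0)
    spots <- spot_world_coords(cargo)
  means <- numeric(tethers$n); vars <- numeric(tethers$n)
  for (i in seq_len(tethers$n)) {
    w <- with_local_seed(seed + i, {
      x0 <- tethers$positions[i, ]
      x <- x0[1] + apply(matrix(stats::rnorm(K * n_samples, sd = sd_step), K),
                         2, cumsum)
      y <- x0[2] + apply(matrix(stats::rnorm(K * n_samples, sd = sd_step), K),
                         2, cumsum)
      z <- x0[3] + apply(matrix(stats::rnorm(K * n_samples, sd = sd_step), K),
                         2, cumsum)
      # reflecting (Neumann) open ends: fold z into [0, H]
      z <- abs(z); z <- H - abs(H - (z %% (2 * H)))
      rr <- sqrt(x^2 + y^2)
      wall_d <- R - rr                               # distance to side wall
      ok <- colSums(wall_d > 0) == K
      # bridge correction at the wall (locally planar)
      d_prev <- rbind(rep(R - sqrt(x0[1]^2 + x0[2]^2), n_samples),
                      wall_d[-K, , drop = FALSE])
      p_nc <- 1 - exp(-2 * pmax(d_prev, 0) * pmax(wall_d, 0) / sd_step^2)
      w <- ok * apply(p_nc, 2, prod)
      if (!is.null(cargo)) {
        cc <- cargo$center; rad <- cargo$diameter / 2
        sph_d <- sqrt((x - cc[1])^2 + (y - cc[2])^2 + (z - cc[3])^2) - rad
        ok_s <- colSums(sph_d > 0) == K
        d0 <- sqrt(sum((x0 - cc)^2)) - rad
        dp <- rbind(rep(d0, n_samples), sph_d[-K, , drop = FALSE])
        p_nc_s <- 1 - exp(-2 * pmax(dp, 0) * pmax(sph_d, 0) / sd_step^2)
        w <- w * ok_s * apply(p_nc_s, 2, prod)
        if (!is.null(spots)) {
          # adsorption weight exp(gamma * ds * #steps within cutoff)
          inb <- matrix(FALSE, K, n_samples)
          for (sidx in seq_len(nrow(spots))) {
            sp <- spots[sidx, ]
            inb <- inb | ((x - sp[1])^2 + (y - sp[2])^2 +
                            (z - sp[3])^2 < r_cutoff^2)
          }
          w <- w * exp(gamma * ds_eff * colSums(inb))
        }
      }
      w
    })
    means[i] <- mean(w); vars[i] <- stats::var(w)
  }
  list(mean = means, var = vars)
}
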