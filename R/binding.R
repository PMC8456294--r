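#' Near-uniform vertex layout on the cargo surface
#'
#' Discretizes the sphere surface into `N_all = round(density * pi *
#' d_cargo^2)` unit direction vectors using the deterministic Fibonacci
#' (golden-spiral) lattice, so the vertex surface density is conserved
#' across cargo sizes.
#'
#' @param d_cargo Cargo diameter in nm.
#' @param density Vertex surface density in vertices/nm^2 (default 1,
#'   roughly one vertex per Kuhn-length square).
#' @return `N_all x 3` matrix of unit vectors (cargo-frame directions).
#' @examples
#' nrow(sphere_vertices(20))  # round(pi * 400) = 1257
#' @export
sphere_vertices <- function(d_cargo, density = 1) {
  if (d_cargo <= 0) stop("cargo diameter must be positive")
  n <- max(4L, round(density * pi * d_cargo^2))
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i          # golden-angle longitude
  cz <- 1 - 2 * i / n                     # uniform in cos(polar angle)
  st <- sqrt(pmax(0, 1 - cz^2))
  cbind(x = st * cos(phi), y = st * sin(phi), z = cz)
}

#' Binding-spot set on the cargo surface
#'
#' Container pairing the full vertex layout with the subset selected as
#' binding spots and the distribution metadata.
#'
#' @param vertices Unit-vector matrix from [sphere_vertices()].
#' @param spots Integer indices of the binding-spot vertices.
#' @param distribution `"uniform-cap"` or `"kent"`.
#' @param params Distribution parameters (coverage fraction or
#'   [kent_params()]).
#' @param seed RNG seed used in the selection, if any.
#' @return An object of class `binding_spot_set`.
#' @export
binding_spot_set <- function(vertices, spots, distribution = "uniform-cap",
                             params = NULL, seed = NULL) {
  spots <- as.integer(spots)
  if (length(spots) > 0 &&
      (min(spots) < 1 || max(spots) > nrow(vertices)))
    stop("spot indices outside the vertex set")
  structure(list(vertices = vertices, spots = spots,
                 N_all = nrow(vertices), N_bind = length(spots),
                 distribution = distribution, params = params, seed = seed),
            class = "binding_spot_set")
}

#' @export
print.binding_spot_set <- function(x, ...) {
  cat(sprintf("Binding spots: %d of %d vertices (%s)\n",
              x$N_bind, x$N_all, x$distribution))
  invisible(x)
}

#' Uniform spherical-cap binding spots
#'
#' Selects every vertex below the latitude whose spherical-cap area
#' fraction equals `coverage`: the cap is centred on the cargo-frame south
#' pole (0, 0, -1) and covers polar angles (measured from that pole) up to
#' `theta_c` with `(1 - cos(theta_c))/2 = coverage`.
#'
#' @param vertices Vertex matrix from [sphere_vertices()].
#' @param coverage Cap area fraction in `[0, 1]` (`S/S'` relative to the
#'   sphere's own area).
#' @return A [binding_spot_set()].
#' @export
uniform_cap_spots <- function(vertices, coverage) {
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  cos_from_pole <- -vertices[, 3]          # angle from (0,0,-1)
  cos_thc <- 1 - 2 * coverage
  sel <- which(cos_from_pole > cos_thc - 1e-12)
  if (coverage == 0) sel <- integer(0)
  binding_spot_set(vertices, sel, "uniform-cap",
                   params = list(coverage = coverage))
}

#' Kent (Fisher-Bingham) distribution parameters
#'
#' Direction distribution on the unit sphere with concentration `kappa` and
#' ellipticity `beta`; `beta = 0` gives the von Mises-Fisher special case
#' used throughout this package.
#'
#' @param kappa Concentration (>= 0).
#' @param beta Ellipticity (default 0).
#' @param mean_direction Unit 3-vector gamma1 (default the cargo-frame
#'   south pole, matching the uniform cap's centre).
#' @return An object of class `kent_params` with an orthonormal frame
#'   `gamma1, gamma2, gamma3`.
#' @export
kent_params <- function(kappa, beta = 0, mean_direction = c(0, 0, -1)) {
  if (kappa < 0) stop("kappa must be non-negative")
  g1 <- mean_direction / sqrt(sum(mean_direction^2))
  # complete an orthonormal frame
  a <- if (abs(g1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  g2 <- a - sum(a * g1) * g1; g2 <- g2 / sqrt(sum(g2^2))
  g3 <- c(g1[2] * g2[3] - g1[3] * g2[2],
          g1[3] * g2[1] - g1[1] * g2[3],
          g1[1] * g2[2] - g1[2] * g2[1])
  structure(list(kappa = kappa, beta = beta,
                 gamma1 = g1, gamma2 = g2, gamma3 = g3),
            class = "kent_params")
}

# normalization constant c(kappa, beta): closed form for beta = 0
# (4*pi*sinh(kappa)/kappa), Gauss-Legendre x trapezoid quadrature otherwise
kent_normalization <- function(params) {
  k <- params$kappa; b <- params$beta
  if (b == 0) {
    if (k == 0) return(4 * pi)
    # expm1-based form is stable for small kappa
    return(2 * pi * (exp(k) - exp(-k)) / k)
  }
  nq <- 200
  u <- seq(-1 + 1 / nq, 1 - 1 / nq, length.out = nq)  # cos(theta) midpoints
  du <- 2 / nq
  ph <- seq(0, 2 * pi, length.out = 401)[-401]
  dph <- 2 * pi / 400
  tot <- 0
  st <- sqrt(1 - u^2)
  for (p in ph) {
    x <- cbind(st * cos(p), st * sin(p), u)
    e <- exp(k * (x %*% params$gamma1) +
               b * ((x %*% params$gamma2)^2 - (x %*% params$gamma3)^2))
    tot <- tot + sum(e) * du * dph
  }
  tot
}

#' Kent probability density on the unit sphere
#'
#' `f(x) = exp(kappa*g1.x + beta*((g2.x)^2 - (g3.x)^2)) / c(kappa, beta)`
#' per steradian; integrates to 1 over the sphere.
#'
#' @param x Unit 3-vector or matrix of row unit vectors.
#' @param params A [kent_params()].
#' @return Density value(s), 1/steradian.
#' @examples
#' kent_density(c(0, 0, 1), kent_params(0))        # 1/(4*pi)
#' @export
kent_density <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nr <- sqrt(rowSums(x^2))
  if (any(abs(nr - 1) > 1e-8)) stop("x must be (a) unit vector(s)")
  e <- exp(params$kappa * (x %*% params$gamma1) +
             params$beta * ((x %*% params$gamma2)^2 -
                              (x %*% params$gamma3)^2))
  as.numeric(e) / kent_normalization(params)
}

#' Kent-distributed binding spots
#'
#' Samples `n_bind` vertices without replacement with selection weight
#' proportional to the Kent density at each vertex.  Reproducible under a
#' fixed seed; the seed is recorded in the returned object.
#'
#' @param vertices Vertex matrix from [sphere_vertices()].
#' @param n_bind Number of binding spots to select.
#' @param params A [kent_params()].
#' @param seed Integer RNG seed.
#' @return A [binding_spot_set()].
#' @export
kent_spots <- function(vertices, n_bind, params, seed = 1L) {
  if (n_bind > nrow(vertices))
    stop("cannot select more binding spots than vertices")
  w <- kent_density(vertices, params)
  sel <- with_local_seed(seed, sample.int(nrow(vertices), n_bind,
                                          replace = FALSE, prob = w))
  binding_spot_set(vertices, sort(sel), "kent", params = params, seed = seed)
}

# evaluate expr under a temporary RNG seed without disturbing the caller's
# random stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# world-frame coordinates (nm) of the binding spots for a given cargo pose:
# rotate the cargo-frame directions by Rz(phi) %*% Ry(theta), scale by the
# radius and translate to the centre
rotation_matrix <- function(theta, phi) {
  Ry <- matrix(c(cos(theta), 0, -sin(theta),
                 0, 1, 0,
                 sin(theta), 0, cos(theta)), 3, 3)
  Rz <- matrix(c(cos(phi), sin(phi), 0,
                 -sin(phi), cos(phi), 0,
                 0, 0, 1), 3, 3)
  Rz %*% Ry
}

#' World coordinates of the binding spots of a posed cargo
#'
#' @param cargo A [cargo_spec()] whose `spots` is non-empty.
#' @return `N_bind x 3` matrix of positions in nm.
#' @export
spot_world_coords <- function(cargo) {
  sp <- cargo$spots
  if (is.null(sp) || sp$N_bind == 0)
    return(matrix(numeric(0), ncol = 3))
  Rm <- rotation_matrix(cargo$orientation[1], cargo$orientation[2])
  dirs <- sp$vertices[sp$spots, , drop = FALSE] %*% t(Rm)
  sweep(dirs * (cargo$diameter / 2), 2, cargo$center, `+`)
}

#' Short-range adsorption potential around the binding spots
#'
#' `V(r) = -gamma` when the minimal distance from `r` to any binding spot
#' is strictly below `r_cutoff`, else 0.  The reference cutoff is one Kuhn
#' length, 0.86 nm; `gamma` is the interfacial energy in kBT (reference
#' range 0.9-1.2).
#'
#' @param cargo A posed [cargo_spec()] with binding spots.
#' @param gamma Interfacial energy in kBT (>= 0).
#' @param r_cutoff Interaction range in nm.
#' @return An object of class `adsorption_potential` carrying the
#'   world-frame spot coordinates.
#' @export
adsorption_potential <- function(cargo, gamma, r_cutoff = 0.86) {
  if (gamma < 0) stop("gamma must be non-negative")
  if (r_cutoff <= 0) stop("r_cutoff must be positive")
  structure(list(gamma = gamma, r_cutoff = r_cutoff,
                 spots_world = spot_world_coords(cargo), cargo = cargo),
            class = "adsorption_potential")
}

#' Evaluate the adsorption potential at points
#'
#' @param r 3-vector or matrix of row positions (nm).
#' @param pot An [adsorption_potential()].
#' @return Potential value(s) in kBT, each either `-gamma` or 0.
#' @export
potential_at <- function(r, pot) {
  if (is.null(dim(r))) r <- matrix(r, nrow = 1)
  sp <- pot$spots_world
  if (nrow(sp) == 0) return(numeric(nrow(r)))
  out <- numeric(nrow(r))
  for (i in seq_len(nrow(r))) {
    d2 <- (sp[, 1] - r[i, 1])^2 + (sp[, 2] - r[i, 2])^2 +
      (sp[, 3] - r[i, 3])^2
    if (min(d2) < pot$r_cutoff^2) out[i] <- -pot$gamma
  }
  out
}

#' Binding surface area
#'
#' `S = (N_bind / N_all) * pi * d_cargo^2`, together with the ratio
#' `S/S*` where `S* = pi * (20 nm)^2` is the full surface of the
#' 20-nm reference cargo.
#'
#' @param spots A [binding_spot_set()].
#' @param d_cargo Cargo diameter in nm.
#' @return List with `S` (nm^2) and `S_over_Sstar`.
#' @export
binding_surface_area <- function(spots, d_cargo) {
  S <- (spots$N_bind / spots$N_all) * pi * d_cargo^2
  list(S = S, S_over_Sstar = S / (pi * 20^2))
}

#' Clustering degree of a binding-spot layout
#'
#' Finds the (binding spot, tether) pair at minimal Euclidean distance; the
#' spot of that pair is the nearest-to-wall point.  Counts the surface
#' vertices and binding spots within `r_cluster` of it (world coordinates)
#' and returns their ratio `p_cluster = N_nw_bind / N_nw_all`.
#'
#' @param cargo A posed [cargo_spec()] with a non-empty spot set.
#' @param tethers A [place_tethers()] tether set.
#' @param r_cluster Neighbourhood radius in nm (reference `10 b` = 8.6 nm).
#' @return `p_cluster` in `(0, 1]`.
#' @export
clustering_degree <- function(cargo, tethers, r_cluster = 8.6) {
  sp <- cargo$spots
  if (is.null(sp) || sp$N_bind == 0)
    stop("clustering degree is undefined for an empty spot set")
  spots_w <- spot_world_coords(cargo)
  Rm <- rotation_matrix(cargo$orientation[1], cargo$orientation[2])
  all_w <- sweep(sp$vertices %*% t(Rm) * (cargo$diameter / 2), 2,
                 cargo$center, `+`)
  # nearest (spot, tether) pair
  best <- c(Inf, NA)
  for (i in seq_len(nrow(spots_w))) {
    d2 <- (tethers$positions[, 1] - spots_w[i, 1])^2 +
      (tethers$positions[, 2] - spots_w[i, 2])^2 +
      (tethers$positions[, 3] - spots_w[i, 3])^2
    m <- min(d2)
    if (m < best[1]) best <- c(m, i)
  }
  nw <- spots_w[best[2], ]
  d2_all <- (all_w[, 1] - nw[1])^2 + (all_w[, 2] - nw[2])^2 +
    (all_w[, 3] - nw[3])^2
  in_all <- d2_all <= r_cluster^2
  in_bind <- in_all[sp$spots]
  sum(in_bind) / sum(in_all)
}

#' Export binding spots to CSV (+ JSON sidecar)
#'
#' Writes `vertex_id,x_nm,y_nm,z_nm,is_spot` rows for the posed cargo and a
#' JSON sidecar with the distribution metadata.
#'
#' @param cargo A posed [cargo_spec()] with spots.
#' @param file CSV output path; the sidecar is `<file>.json`.
#' @return The CSV path, invisibly.
#' @export
write_binding_spots <- function(cargo, file) {
  sp <- cargo$spots
  Rm <- rotation_matrix(cargo$orientation[1], cargo$orientation[2])
  all_w <- sweep(sp$vertices %*% t(Rm) * (cargo$diameter / 2), 2,
                 cargo$center, `+`)
  df <- data.frame(vertex_id = seq_len(sp$N_all),
                   x_nm = all_w[, 1], y_nm = all_w[, 2], z_nm = all_w[, 3],
                   is_spot = seq_len(sp$N_all) %in% sp$spots)
  utils::write.csv(df, file, row.names = FALSE)
  area <- binding_surface_area(sp, cargo$diameter)
  meta <- list(distribution = sp$distribution,
               kappa = if (inherits(sp$params, "kent_params"))
                 sp$params$kappa else NULL,
               beta = if (inherits(sp$params, "kent_params"))
                 sp$params$beta else NULL,
               coverage = if (!inherits(sp$params, "kent_params"))
                 sp$params$coverage else NULL,
               seed = sp$seed, N_all = sp$N_all, N_bind = sp$N_bind,
               S_nm2 = area$S, S_over_Sstar = area$S_over_Sstar)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}
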