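#' Cylindrical pore geometry
#'
#' The NPC central channel is modelled as a cylinder of diameter `diameter`
#' and height `height`.  The cylinder axis is the z axis with
#' `z` in `[0, height]`; the origin sits on the axis at the bottom face.
#' The side wall is a hard (absorbing) surface, the two end faces are open.
#'
#' @param diameter Pore diameter D_pore in nm (reference 40).
#' @param height Pore height h_pore in nm (reference 40).
#' @return An object of class `pore_geometry`.
#' @examples
#' pore_geometry(40, 40)
#' @export
pore_geometry <- function(diameter = 40, height = 40) {
  stopifnot(is.numeric(diameter), is.numeric(height))
  if (diameter <= 0 || height <= 0)
    stop("pore diameter and height must be positive")
  structure(list(diameter = diameter, height = height,
                 radius = diameter / 2),
            class = "pore_geometry")
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat(sprintf("Cylindrical pore: D = %g nm, h = %g nm (hard wall, open ends)\n",
              x$diameter, x$height))
  invisible(x)
}

#' Spherical cargo specification
#'
#' A cargo is a hard sphere of diameter `diameter` centred at `center`
#' (world frame, nm).  `orientation = c(theta, phi)` rotates the cargo
#' frame (used to orient binding-spot layouts); `spots` is an optional
#' [binding_spot_set()] giving the surface vertices and the selected
#' binding spots in the cargo frame.  A cargo without spots is inert.
#'
#' @param diameter Sphere diameter d_cargo in nm.
#' @param center Numeric length-3 cargo centre (nm).
#' @param orientation Numeric length-2 `(theta, phi)` in radians.
#' @param spots Optional `binding_spot_set`.
#' @return An object of class `cargo_spec`.
#' @export
cargo_spec <- function(diameter, center = c(0, 0, 0),
                       orientation = c(0, 0), spots = NULL) {
  stopifnot(length(center) == 3, length(orientation) == 2)
  if (diameter <= 0) stop("cargo diameter must be positive")
  if (!is.null(spots) && !inherits(spots, "binding_spot_set"))
    stop("'spots' must be a binding_spot_set or NULL")
  structure(list(diameter = diameter, center = as.numeric(center),
                 orientation = as.numeric(orientation), spots = spots),
            class = "cargo_spec")
}

#' @export
print.cargo_spec <- function(x, ...) {
  cat(sprintf("Spherical cargo: d = %g nm, center (%g, %g, %g) nm%s\n",
              x$diameter, x$center[1], x$center[2], x$center[3],
              if (is.null(x$spots)) " [inert]"
              else sprintf(" [%d binding spots]", length(x$spots$spots))))
  invisible(x)
}

# validate cargo-in-pore constraint; protrusion through the open ends is
# allowed (models a cargo entering from the mouth), wall contact is not
check_cargo_fits <- function(pore, cargo) {
  if (cargo$diameter >= pore$diameter)
    stop("cargo diameter must be strictly smaller than the pore diameter")
  r_lat <- sqrt(sum(cargo$center[1:2]^2))
  if (r_lat + cargo$diameter / 2 >= pore$radius)
    stop("cargo touches or overlaps the pore wall")
  invisible(TRUE)
}

#' Place FG-Nup tether points on the pore wall
#'
#' Tether points sit 1 nm radially inward from the cylinder wall, i.e. at
#' radius `D_pore/2 - 1` (the inward shift avoids evaluating the propagator
#' on the absorbing boundary).  Two modes:
#'
#' * `"synthetic-rings"`: `n` points distributed over `rings` equally
#'   spaced horizontal rings at heights `h * j / (rings + 1)`; points on a
#'   ring have equal angular spacing and consecutive rings are staggered by
#'   half a spacing.  Fully deterministic.
#' * `"from-file"`: reads a CSV with header `x_nm,y_nm,z_nm` and radially
#'   projects every point to radius `D_pore/2 - 1`.
#'
#' @param pore A [pore_geometry()].
#' @param n Number of tethers (reference 80); ignored in `"from-file"` mode.
#' @param mode `"synthetic-rings"` or `"from-file"`.
#' @param source CSV path for `"from-file"`.
#' @param rings Number of rings for the synthetic layout (default 2).
#' @return An object of class `tether_set`: list with `positions`
#'   (n x 3 matrix, nm) and `n`.
#' @examples
#' te <- place_tethers(pore_geometry(40, 40), n = 80)
#' range(sqrt(rowSums(te$positions[, 1:2]^2)))  # all at radius 19
#' @export
place_tethers <- function(pore, n = 80,
                          mode = c("synthetic-rings", "from-file"),
                          source = NULL, rings = 2) {
  mode <- match.arg(mode)
  r_t <- pore$radius - 1
  if (r_t <= 0) stop("pore too narrow to place tethers 1 nm inward")
  if (mode == "synthetic-rings") {
    if (n < 1) stop("need at least one tether")
    if (n == 1) rings <- 1
    counts <- rep(n %/% rings, rings)
    if (n %% rings > 0) counts[seq_len(n %% rings)] <- counts[seq_len(n %% rings)] + 1
    zs <- pore$height * seq_len(rings) / (rings + 1)
    pos <- do.call(rbind, lapply(seq_len(rings), function(j) {
      m <- counts[j]
      ang <- 2 * pi * (seq_len(m) - 1) / m + (j - 1) * pi / max(m, 1)
      cbind(r_t * cos(ang), r_t * sin(ang), rep(zs[j], m))
    }))
  } else {
    if (is.null(source) || !file.exists(source))
      stop("tether file not found: ", source)
    tab <- utils::read.csv(source)
    need <- c("x_nm", "y_nm", "z_nm")
    if (!all(need %in% names(tab)))
      stop("tether CSV must have columns x_nm,y_nm,z_nm")
    xy <- as.matrix(tab[, c("x_nm", "y_nm")])
    rr <- sqrt(rowSums(xy^2))
    if (any(rr == 0)) stop("tether on the pore axis cannot be projected to the wall")
    pos <- cbind(xy * (r_t / rr), tab$z_nm)
    n <- nrow(pos)
  }
  if (any(pos[, 3] < 0 | pos[, 3] > pore$height))
    stop("tether z outside the pore height")
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos, n = as.integer(n), radius = r_t),
            class = "tether_set")
}

#' @export
print.tether_set <- function(x, ...) {
  cat(sprintf("Tether set: %d FG-Nup anchors at radius %g nm\n", x$n, x$radius))
  invisible(x)
}

#' Cargo orientation grid for rotational averaging
#'
#' The 220 orientations used for orientation-averaged free energies:
#' `theta = p*pi/5` for `p = 0..19` (latitudinal) crossed with
#' `phi = m*pi/10` for `m = 0..10` (longitudinal).
#'
#' @return A 220 x 2 matrix with columns `theta`, `phi` (radians).
#' @export
orientation_grid <- function() {
  g <- expand.grid(phi = (0:10) * pi / 10, theta = (0:19) * pi / 5)
  out <- cbind(theta = g$theta, phi = g$phi)
  out
}

#' Edge length of a regular tetrahedron of given volume
#'
#' Inverts V = a^3 / (6 sqrt(2)); used to express a target cell volume as a
#' characteristic mesh edge length.
#'
#' @param volume Cell volume in nm^3.
#' @return Edge length in nm.
#' @examples
#' regular_tet_edge(0.1)  # ~0.95 nm, i.e. about one Kuhn length
#' @export
regular_tet_edge <- function(volume) {
  stopifnot(volume > 0)
  (6 * sqrt(2) * volume)^(1 / 3)
}

#' Spatial discretization parameters
#'
#' @param spacing Target grid spacing in nm.  Defaults to 0.4 nm for the
#'   axisymmetric path and one Kuhn length (0.86 nm) for the 3-D grid; must
#'   not exceed the Kuhn length when `strict = TRUE`.
#' @param cell_volume Alternative specification: target cell volume in nm^3;
#'   translated to a spacing via [regular_tet_edge()].
#' @param strict If `TRUE` (default) a spacing coarser than the Kuhn length
#'   b = 0.86 nm is refused; if `FALSE` it only warns.
#' @return An object of class `disc_params`.
#' @export
disc_params <- function(spacing = NULL, cell_volume = NULL, strict = TRUE) {
  if (!is.null(cell_volume)) spacing <- regular_tet_edge(cell_volume)
  structure(list(spacing = spacing, strict = strict), class = "disc_params")
}

resolve_spacing <- function(params, type, b_ref = 0.86) {
  sp <- params$spacing
  if (is.null(sp)) sp <- if (type == "axisym") 0.4 else b_ref
  if (sp > b_ref * 1.0000001) {
    msg <- sprintf("grid spacing %.3g nm is coarser than the Kuhn length %.3g nm",
                   sp, b_ref)
    if (isTRUE(params$strict)) stop(msg) else warning(msg)
  }
  sp
}

#' Build the computational domain
#'
#' Discretizes the fluid region (cylinder minus the optional cargo sphere)
#' with a finite-volume scheme and assembles the volume-weighted Laplacian.
#' Boundary handling: homogeneous Dirichlet (absorbing) on the cylinder side
#' wall and the cargo surface, zero-flux Neumann on the two open ends.
#'
#' Two representations are available:
#' * `"axisym"`: 2-D (r, z) grid, valid when the cargo (if any) is centred
#'   on the pore axis and carries no binding potential.  This is the fast
#'   path used for inert-cargo scans.
#' * `"grid3d"`: full 3-D Cartesian grid, required for off-axis cargoes and
#'   for attractive cargoes (the adsorption potential breaks axisymmetry).
#'
#' @param pore A [pore_geometry()].
#' @param cargo A [cargo_spec()] or `NULL` for the empty pore.
#' @param params A [disc_params()].
#' @param method `"auto"`, `"axisym"` or `"grid3d"`.
#' @return An object of class `npc_domain` with fields `type`, `nodes`
#'   (world coordinates of fluid nodes), `vol` (finite-volume node volumes,
#'   nm^3), `L` (volume-weighted sparse Laplacian, negative semi-definite),
#'   `interp(points)` and `nearest(points)` accessors, and boundary facet
#'   counts `n_dirichlet_faces`, `n_neumann_faces`.
#' @export
build_domain <- function(pore, cargo = NULL, params = disc_params(),
                         method = c("auto", "axisym", "grid3d")) {
  method <- match.arg(method)
  if (!is.null(cargo)) check_cargo_fits(pore, cargo)
  on_axis <- is.null(cargo) ||
    (all(abs(cargo$center[1:2]) < 1e-12) &&
       (is.null(cargo$spots) || length(cargo$spots$spots) == 0))
  if (method == "auto") method <- if (on_axis) "axisym" else "grid3d"
  if (method == "axisym" && !on_axis)
    stop("axisymmetric domain requires a centred cargo without binding spots")
  if (method == "axisym") build_domain_axisym(pore, cargo, params)
  else build_domain_grid3d(pore, cargo, params)
}

# ---- axisymmetric (r, z) finite-volume domain -------------------------------

build_domain_axisym <- function(pore, cargo, params) {
  sp <- resolve_spacing(params, "axisym")
  R <- pore$radius; H <- pore$height
  J <- max(3L, round(R / sp)); dr <- R / J     # r_J = R is the Dirichlet wall
  K <- max(3L, round(H / sp)); dz <- H / K     # z ends are Neumann
  rj <- (0:J) * dr; zk <- (0:K) * dz
  # fluid nodes: j = 0..J-1 (j = J is the wall), minus the sphere
  grid <- expand.grid(j = 0:(J - 1), k = 0:K)
  rr <- rj[grid$j + 1]; zz <- zk[grid$k + 1]
  in_sphere <- rep(FALSE, nrow(grid))
  if (!is.null(cargo)) {
    zc <- cargo$center[3]
    in_sphere <- (rr^2 + (zz - zc)^2) <= (cargo$diameter / 2)^2
  }
  fluid <- !in_sphere
  idx <- matrix(0L, nrow = J + 1, ncol = K + 1)   # wall row j = J stays 0
  idx[cbind(grid$j[fluid] + 1, grid$k[fluid] + 1)] <- seq_len(sum(fluid))
  n <- sum(fluid)
  jf <- grid$j[fluid]; kf <- grid$k[fluid]
  r_f <- rj[jf + 1]; z_f <- zk[kf + 1]

  # finite-volume face areas (full 3-D volumes of the revolved cells)
  a_z  <- function(j) ifelse(j == 0, pi * dr^2 / 4, 2 * pi * rj[j + 1] * dr) # z-face area
  volj <- function(j) a_z(j) * dz                                           # cell volume
  vol <- volj(jf)
  c_rad <- function(j) 2 * pi * (rj[j + 1] + dr / 2) * dz / dr  # face j <-> j+1
  c_ax  <- function(j) a_z(j) / dz                              # face k <-> k+1

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(n)
  n_dir <- 0L; n_neu <- 0L
  add_faces <- function(pj, pk, qj, qk, coef) {
    # faces between node sets p (fluid, indices 1..n order) and neighbours q
    pid <- idx[cbind(pj + 1, pk + 1)]
    valid_q <- qj >= 0 & qj <= J & qk >= 0 & qk <= K
    qid <- integer(length(pid)); qid[valid_q] <- idx[cbind(qj[valid_q] + 1, qk[valid_q] + 1)]
    is_neu <- !valid_q                        # beyond z range (qj always valid here)
    is_dir <- valid_q & qid == 0L             # wall node, sphere node
    is_fl  <- qid > 0L
    # fluid-fluid: off-diagonal + diagonal
    if (any(is_fl)) {
      ii <<- c(ii, pid[is_fl]); jj <<- c(jj, qid[is_fl]); xx <<- c(xx, coef[is_fl])
      diag_acc[pid[is_fl]] <<- diag_acc[pid[is_fl]] - coef[is_fl]
    }
    if (any(is_dir)) {
      diag_acc[pid[is_dir]] <<- diag_acc[pid[is_dir]] - coef[is_dir]
      n_dir <<- n_dir + sum(is_dir)
    }
    n_neu <<- n_neu + sum(is_neu)
  }
  # radial +: face coefficient belongs to the lower-j side
  add_faces(jf, kf, jf + 1L, kf, c_rad(jf))
  # radial -: only j >= 1 has an inner face
  has_in <- jf >= 1
  add_faces(jf[has_in], kf[has_in], jf[has_in] - 1L, kf[has_in], c_rad(jf[has_in] - 1L))
  # axial +/-
  add_faces(jf, kf, jf, kf + 1L, c_ax(jf))
  add_faces(jf, kf, jf, kf - 1L, c_ax(jf))

  L <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_acc), dims = c(n, n))
  L <- Matrix::forceSymmetric((L + Matrix::t(L)) / 2)

  interp <- function(points) axisym_interp(points, rj, zk, idx, J, K, n)
  nearest <- function(points) {
    pr <- sqrt(points[, 1]^2 + points[, 2]^2)
    j0 <- pmin(pmax(round(pr / dr), 0), J); k0 <- pmin(pmax(round(points[, 3] / dz), 0), K)
    id <- idx[cbind(j0 + 1, k0 + 1)]
    if (any(id == 0L)) stop("point maps to a non-fluid (boundary) node")
    id
  }
  structure(list(type = "axisym", pore = pore, cargo = cargo,
                 spacing = c(dr = dr, dz = dz), dims = c(J = J, K = K),
                 nodes = cbind(r = r_f, z = z_f), vol = vol, L = L, n = n,
                 idx = idx, r_grid = rj, z_grid = zk,
                 interp = interp, nearest = nearest,
                 n_dirichlet_faces = n_dir, n_neumann_faces = n_neu),
            class = "npc_domain")
}

# bilinear interpolation of nodal values at world points; non-fluid corners
# carry the boundary value 0
axisym_interp <- function(points, rj, zk, idx, J, K, n) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  pr <- sqrt(points[, 1]^2 + points[, 2]^2); pz <- points[, 3]
  dr <- rj[2] - rj[1]; dz <- zk[2] - zk[1]
  fj <- pmin(pmax(pr / dr, 0), J - 1e-9); fk <- pmin(pmax(pz / dz, 0), K - 1e-9)
  j0 <- floor(fj); k0 <- floor(fk); tj <- fj - j0; tk <- fk - k0
  m <- nrow(points)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  corners <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  wts <- cbind((1 - tj) * (1 - tk), tj * (1 - tk), (1 - tj) * tk, tj * tk)
  for (c_i in 1:4) {
    cj <- j0 + corners[[c_i]][1]; ck <- k0 + corners[[c_i]][2]
    id <- idx[cbind(cj + 1, ck + 1)]
    keep <- id > 0L & wts[, c_i] > 0
    ii <- c(ii, which(keep)); jj <- c(jj, id[keep]); xx <- c(xx, wts[keep, c_i])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n))
}

# ---- full 3-D Cartesian finite-volume domain --------------------------------

build_domain_grid3d <- function(pore, cargo, params) {
  sp <- resolve_spacing(params, "grid3d")
  R <- pore$radius; H <- pore$height
  nxh <- max(3L, round(R / sp)); hx <- R / nxh      # x,y in [-R, R]
  nz <- max(3L, round(H / sp)); hz <- H / nz        # z in [0, H]
  xs <- (-nxh:nxh) * hx; zs <- (0:nz) * hz
  nx <- length(xs); nzp <- length(zs)
  grid <- expand.grid(i = seq_len(nx), j = seq_len(nx), k = seq_len(nzp))
  X <- xs[grid$i]; Y <- xs[grid$j]; Z <- zs[grid$k]
  in_cyl <- (X^2 + Y^2) < R^2 * (1 - 1e-12)
  in_sph <- rep(FALSE, length(X))
  if (!is.null(cargo)) {
    cc <- cargo$center
    in_sph <- ((X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2) <=
      (cargo$diameter / 2)^2
  }
  fluid <- in_cyl & !in_sph
  idx <- array(0L, dim = c(nx, nx, nzp))
  idx[cbind(grid$i[fluid], grid$j[fluid], grid$k[fluid])] <- seq_len(sum(fluid))
  n <- sum(fluid)
  fi <- grid$i[fluid]; fj <- grid$j[fluid]; fk <- grid$k[fluid]
  nodes <- cbind(x = X[fluid], y = Y[fluid], z = Z[fluid])
  vol <- rep(hx * hx * hz, n)
  cx <- hx * hz / hx   # x-face: area hy*hz over distance hx (hy = hx)
  cy <- cx
  cz <- hx * hx / hz

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(n); n_dir <- 0L; n_neu <- 0L
  add3 <- function(di, dj, dk, coef) {
    qi <- fi + di; qj <- fj + dj; qk <- fk + dk
    inrange <- qi >= 1 & qi <= nx & qj >= 1 & qj <= nx & qk >= 1 & qk <= nzp
    pid <- seq_len(n)
    qid <- integer(n); qid[inrange] <- idx[cbind(qi[inrange], qj[inrange], qk[inrange])]
    # z-overflow is the open (Neumann) end; x/y-overflow cannot happen for
    # fluid nodes (the cylinder is strictly inside the box)
    is_neu <- !inrange
    is_dir <- inrange & qid == 0L
    is_fl <- qid > 0L
    if (any(is_fl)) {
      ii <<- c(ii, pid[is_fl]); jj <<- c(jj, qid[is_fl])
      xx <<- c(xx, rep(coef, sum(is_fl)))
      diag_acc[pid[is_fl]] <<- diag_acc[pid[is_fl]] - coef
    }
    if (any(is_dir)) {
      diag_acc[pid[is_dir]] <<- diag_acc[pid[is_dir]] - coef
      n_dir <<- n_dir + sum(is_dir)
    }
    n_neu <<- n_neu + sum(is_neu)
  }
  add3( 1L, 0L, 0L, cx); add3(-1L, 0L, 0L, cx)
  add3(0L,  1L, 0L, cy); add3(0L, -1L, 0L, cy)
  add3(0L, 0L,  1L, cz); add3(0L, 0L, -1L, cz)

  L <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_acc), dims = c(n, n))
  L <- Matrix::forceSymmetric((L + Matrix::t(L)) / 2)

  interp <- function(points) grid3d_interp(points, xs, zs, idx, n)
  nearest <- function(points) {
    if (is.null(dim(points))) points <- matrix(points, nrow = 1)
    i0 <- pmin(pmax(round(points[, 1] / hx) + nxh + 1, 1), nx)
    j0 <- pmin(pmax(round(points[, 2] / hx) + nxh + 1, 1), nx)
    k0 <- pmin(pmax(round(points[, 3] / hz) + 1, 1), nzp)
    id <- idx[cbind(i0, j0, k0)]
    if (any(id == 0L)) stop("point maps to a non-fluid (boundary) node")
    id
  }
  structure(list(type = "grid3d", pore = pore, cargo = cargo,
                 spacing = c(h = hx, hz = hz), dims = c(nx = nx, nz = nzp),
                 nodes = nodes, vol = vol, L = L, n = n,
                 idx = idx, x_grid = xs, z_grid = zs,
                 interp = interp, nearest = nearest,
                 n_dirichlet_faces = n_dir, n_neumann_faces = n_neu),
            class = "npc_domain")
}

grid3d_interp <- function(points, xs, zs, idx, n) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  hx <- xs[2] - xs[1]; hz <- zs[2] - zs[1]
  nx <- length(xs); nz <- length(zs)
  fx <- pmin(pmax((points[, 1] - xs[1]) / hx, 0), nx - 1 - 1e-9)
  fy <- pmin(pmax((points[, 2] - xs[1]) / hx, 0), nx - 1 - 1e-9)
  fz <- pmin(pmax((points[, 3] - zs[1]) / hz, 0), nz - 1 - 1e-9)
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  m <- nrow(points)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (ci in 0:1) for (cj in 0:1) for (ck in 0:1) {
    w <- (if (ci) tx else 1 - tx) * (if (cj) ty else 1 - ty) *
      (if (ck) tz else 1 - tz)
    id <- idx[cbind(i0 + ci + 1, j0 + cj + 1, k0 + ck + 1)]
    keep <- id > 0L & w > 0
    ii <- c(ii, which(keep)); jj <- c(jj, id[keep]); xx <- c(xx, w[keep])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n))
}

#' @export
print.npc_domain <- function(x, ...) {
  cat(sprintf("NPC domain [%s]: %d fluid nodes, spacing %s nm\n", x$type, x$n,
              paste(signif(x$spacing, 3), collapse = " x ")))
  cat(sprintf("  fluid volume %.1f nm^3; boundary faces: %d Dirichlet, %d Neumann\n",
              sum(x$vol), x$n_dirichlet_faces, x$n_neumann_faces))
  invisible(x)
}
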