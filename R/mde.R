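#' Gaussian-chain parameters
#'
#' FG-Nups are continuous Gaussian chains with Kuhn length `b`, contour
#' length `l` and reduced chain length `N = l/b` (the contour variable of
#' the modified diffusion equation runs over `s` in `[0, N]`).
#'
#' @param b Kuhn length in nm (reference 0.86).
#' @param l Contour length in nm (reference 180).
#' @param n Number of chains (reference 80).
#' @return An object of class `chain_parameters` with `N = l/b`.
#' @examples
#' chain_parameters()$N  # 180/0.86 = 209.3
#' @export
chain_parameters <- function(b = 0.86, l = 180, n = 80) {
  if (b <= 0 || l <= 0) stop("Kuhn length and contour length must be positive")
  structure(list(b = b, l = l, n = n, N = l / b), class = "chain_parameters")
}

#' Solver configuration for the modified diffusion equation
#'
#' @param ds Contour step size (dimensionless, reference 0.4; must be < 1 so
#'   `b*ds < b` keeps the contour resolution below the Kuhn length).  The
#'   actual step used is `N / ceiling(N/ds)` so the endpoint `s = N` is hit
#'   exactly with uniform steps.
#' @param spacing Target spatial grid spacing in nm (`NULL` = the
#'   representation default, see [disc_params()]).
#' @param store_all Keep the propagator at every contour step (needed for
#'   density maps); otherwise only the final slice is kept.
#' @param rel_tol Maximum admissible relative residual of each linear solve.
#' @param strict Refuse (rather than warn about) sub-Kuhn-length violations.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(ds = 0.4, spacing = NULL, store_all = FALSE,
                          rel_tol = 1e-10, strict = TRUE) {
  if (ds <= 0 || ds >= 1) stop("contour step ds must lie in (0, 1)")
  structure(list(ds = ds, spacing = spacing, store_all = store_all,
                 rel_tol = rel_tol, strict = strict), class = "solver_config")
}

cfg_disc_params <- function(cfg) disc_params(spacing = cfg$spacing,
                                             strict = cfg$strict)

# contour grid: uniform steps, endpoint exact
contour_grid <- function(N, ds) {
  K <- max(1L, ceiling(N / ds - 1e-12))
  list(K = K, ds = N / K, s = (0:K) * (N / K))
}

# adsorption potential evaluated on domain nodes (kBT units, <= 0)
potential_on_nodes <- function(domain, pot) {
  if (is.null(pot)) return(NULL)
  if (domain$type == "axisym")
    stop("an adsorption potential requires a 3-D domain (it breaks axisymmetry)")
  v <- numeric(domain$n)
  spots <- pot$spots_world
  if (is.null(spots) || nrow(spots) == 0 || pot$gamma == 0) return(v)
  nd <- domain$nodes
  rc <- pot$r_cutoff
  # restrict the search to nodes near the cargo surface shell
  cand <- seq_len(domain$n)
  if (!is.null(domain$cargo)) {
    cc <- domain$cargo$center
    dist_c <- sqrt((nd[, 1] - cc[1])^2 + (nd[, 2] - cc[2])^2 +
                     (nd[, 3] - cc[3])^2)
    shell <- rc + sqrt(sum(domain$spacing^2)) * 2
    cand <- which(abs(dist_c - domain$cargo$diameter / 2) <= shell)
  }
  if (length(cand) == 0) return(v)
  ndc <- nd[cand, , drop = FALSE]
  hit <- rep(FALSE, length(cand))
  for (i in seq_len(nrow(spots))) {
    s <- spots[i, ]
    near <- abs(ndc[, 1] - s[1]) < rc & abs(ndc[, 2] - s[2]) < rc &
      abs(ndc[, 3] - s[3]) < rc
    if (!any(near)) next
    d2 <- (ndc[near, 1] - s[1])^2 + (ndc[near, 2] - s[2])^2 +
      (ndc[near, 3] - s[3])^2
    hit[which(near)[d2 < rc^2]] <- TRUE
  }
  v[cand[hit]] <- -pot$gamma
  v
}

# backward-Euler step operator: A q_new = W q_old with
# A = diag(vol * (1 + ds*V)) - ds*(b^2/6) * L  (symmetric positive definite)
mde_operator <- function(domain, chain, ds, Vnode = NULL) {
  dvec <- domain$vol
  if (!is.null(Vnode)) {
    if (any(1 + ds * Vnode <= 0))
      stop("contour step too large for the potential depth (1 + ds*V <= 0); ",
           "reduce ds")
    dvec <- dvec * (1 + ds * Vnode)
  }
  A <- Matrix::Diagonal(x = dvec) - ds * (chain$b^2 / 6) * domain$L
  Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
}

mde_march <- function(domain, chain, cfg, q0, pot = NULL) {
  cg <- contour_grid(chain$N, cfg$ds)
  Vnode <- potential_on_nodes(domain, pot)
  ch <- mde_operator(domain, chain, cg$ds, Vnode)
  W <- domain$vol
  q <- as.numeric(q0)
  store <- if (cfg$store_all) matrix(NA_real_, nrow = domain$n, ncol = cg$K + 1)
  else NULL
  if (!is.null(store)) store[, 1] <- q
  qprev <- q
  for (k in seq_len(cg$K)) {
    qprev <- q
    q <- as.numeric(Matrix::solve(ch, W * q))
    if (!is.null(store)) store[, k + 1] <- q
  }
  # residual control on the final step (direct solve; this is a guard, not
  # an iteration criterion)
  dvec <- W; if (!is.null(Vnode)) dvec <- W * (1 + cg$ds * Vnode)
  A <- Matrix::Diagonal(x = dvec) - cg$ds * (chain$b^2 / 6) * domain$L
  res <- sqrt(sum((as.numeric(A %*% q) - W * qprev)^2)) /
    max(sqrt(sum((W * qprev)^2)), .Machine$double.xmin)
  if (res > cfg$rel_tol)
    stop(sprintf("linear solve residual %.3g exceeds tolerance %.3g",
                 res, cfg$rel_tol))
  list(final = q, store = store, s = cg$s, ds = cg$ds, K = cg$K)
}

#' Solve the modified diffusion equation for the end-integrated propagator
#'
#' Advances `qtilde(r, s)` from the uniform initial condition
#' `qtilde(r, 0) = 1` through `s = N` by implicit (backward-Euler) contour
#' steps of the diffusion-reaction operator with diffusivity `b^2/6` and
#' reaction `V(r)` (in kBT).  Homogeneous Dirichlet conditions apply on the
#' pore wall and cargo surface, zero-flux conditions on the open ends.
#'
#' @param domain An [build_domain()] discretization.
#' @param chain A [chain_parameters()].
#' @param pot An [adsorption_potential()] or `NULL` (inert).
#' @param cfg A [solver_config()].
#' @return An object of class `npc_propagator` with the final slice
#'   `final`, optionally the full contour history `store`
#'   (nodes x steps), the contour grid `s`, and the generating `domain`.
#' @export
solve_qtilde <- function(domain, chain, pot = NULL, cfg = solver_config()) {
  out <- mde_march(domain, chain, cfg, rep(1, domain$n), pot)
  structure(list(which = "qtilde", final = out$final, store = out$store,
                 s = out$s, ds = out$ds, K = out$K,
                 domain = domain, chain = chain),
            class = "npc_propagator")
}

#' Solve the modified diffusion equation for the tether-sourced propagator
#'
#' The complementary propagator `q_c(r, s)` starts from point sources at
#' the tether positions, each carrying integral weight
#' `1 / qtilde(r_tether, N)` (so that the contour integral of
#' `q_c(r, s) * qtilde(r, N - s)` reproduces the mean segment density with
#' the exact normalization `integral(rho) = n * N`).  Sources are lumped
#' onto the nearest fluid node; the normalizing `qtilde` is taken at that
#' same node, which keeps the discrete normalization identity exact.
#'
#' @inheritParams solve_qtilde
#' @param tethers A [place_tethers()] tether set.
#' @param qtilde The matching [solve_qtilde()] result (same domain, same
#'   configuration).
#' @return An `npc_propagator` (requires `cfg$store_all = TRUE` for
#'   subsequent density computation).
#' @export
solve_qc <- function(domain, chain, tethers, qtilde, pot = NULL,
                     cfg = solver_config()) {
  if (!inherits(qtilde, "npc_propagator") || qtilde$which != "qtilde")
    stop("'qtilde' must be a solved qtilde propagator")
  if (!identical(dim(domain$L), dim(qtilde$domain$L)))
    stop("qtilde was solved on a different discretization")
  ids <- domain$nearest(tethers$positions)
  qN <- qtilde$final[ids]
  if (any(qN <= 0))
    stop("qtilde vanishes at a tether (tether in a forbidden region)")
  q0 <- numeric(domain$n)
  w <- 1 / (qN * domain$vol[ids])          # unit-integral nodal delta / qtilde
  for (i in seq_along(ids)) q0[ids[i]] <- q0[ids[i]] + w[i]
  out <- mde_march(domain, chain, cfg, q0, pot)
  structure(list(which = "qc", final = out$final, store = out$store,
                 s = out$s, ds = out$ds, K = out$K,
                 domain = domain, chain = chain, tether_ids = ids),
            class = "npc_propagator")
}

#' @export
print.npc_propagator <- function(x, ...) {
  cat(sprintf("MDE propagator %s: %d nodes, %d contour steps (ds = %.4g)%s\n",
              x$which, length(x$final), x$K, x$ds,
              if (is.null(x$store)) "" else " [full contour history]"))
  invisible(x)
}

#' Numerical error control against the half-space closed form
#'
#' Solves the 1-D half-space problem (absorbing plane at z = 0, open far
#' end) with the production discretization machinery and compares against
#' the closed-form solution `erf(z * sqrt(3/(2 b^2 s)))`.  Returns the
#' maximal relative error over nodes at least one Kuhn length away from the
#' absorbing wall — the error-ratio statistic used to set the reliability
#' floor on free-energy differences.
#'
#' @param b Kuhn length (nm).
#' @param s Contour extent at which to compare (default the reference
#'   `N = 180/0.86`).
#' @param spacing Grid spacing (nm).
#' @param ds Contour step.
#' @param z_max Domain depth (nm); should be several diffusion lengths.
#' @return List with `max_ratio`, and the node-wise `z`, `numeric`,
#'   `analytic` profiles.
#' @export
error_ratio_control <- function(b = 0.86, s = 180 / 0.86, spacing = 0.4,
                                ds = 0.4, z_max = 60) {
  dom <- halfspace_domain(z_max, spacing)
  chain <- chain_parameters(b = b, l = b * s, n = 1)
  q <- solve_qtilde(dom, chain, cfg = solver_config(ds = ds))
  zq <- dom$nodes[, "z"]
  ana <- halfspace_qtilde(zq, s, b)
  keep <- zq >= b
  ratio <- abs(q$final[keep] - ana[keep]) / q$final[keep]
  list(max_ratio = max(ratio), z = zq[keep],
       numeric = q$final[keep], analytic = ana[keep])
}

# 1-D all-Neumann box (flux-free segment): used to exercise conservation
# identities and potential-only limits where the exact solution is known
neumann_box_domain <- function(n = 20, h = 0.5) {
  z <- (seq_len(n) - 0.5) * h
  coef <- 1 / h
  ii <- c(seq_len(n - 1), 2:n); jj <- c(2:n, seq_len(n - 1))
  xx <- rep(coef, 2 * (n - 1))
  dg <- -c(coef, rep(2 * coef, n - 2), coef)
  L <- Matrix::forceSymmetric(Matrix::sparseMatrix(
    i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
    x = c(xx, dg), dims = c(n, n)))
  nodes <- cbind(x = numeric(n), y = numeric(n), z = z)
  structure(list(type = "neumann_box", nodes = nodes, vol = rep(h, n),
                 L = L, n = n, spacing = c(h = h),
                 interp = function(points) {
                   pz <- if (is.null(dim(points))) points[3] else points[, 3]
                   f <- pmin(pmax(pz / h - 0.5, 0), n - 1 - 1e-9)
                   k0 <- floor(f); t <- f - k0
                   m <- length(pz)
                   Matrix::sparseMatrix(i = c(seq_len(m), seq_len(m)),
                                        j = c(k0 + 1, pmin(k0 + 2, n)),
                                        x = c(1 - t, t), dims = c(m, n))
                 },
                 nearest = function(points) {
                   pz <- if (is.null(dim(points))) points[3] else points[, 3]
                   pmin(pmax(ceiling(pz / h), 1), n)
                 },
                 n_dirichlet_faces = 0L, n_neumann_faces = 2L),
            class = "npc_domain")
}

# 1-D half-space finite-volume domain: Dirichlet at z = 0, Neumann at z_max
halfspace_domain <- function(z_max, spacing) {
  K <- max(4L, round(z_max / spacing)); dz <- z_max / K
  z <- (1:K) * dz                      # node z = 0 is the absorbing wall
  n <- K
  coef <- 1 / dz
  ii <- c(seq_len(n - 1), 2:n); jj <- c(2:n, seq_len(n - 1))
  xx <- rep(coef, 2 * (n - 1))
  dg <- numeric(n)
  dg[1] <- -2 * coef                   # wall face (Dirichlet) + inner face
  dg[2:(n - 1)] <- -2 * coef
  dg[n] <- -coef                       # far end: Neumann (no flux)
  L <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, dg), dims = c(n, n))
  L <- Matrix::forceSymmetric(L)
  nodes <- cbind(x = numeric(n), y = numeric(n), z = z)
  structure(list(type = "grid1d", nodes = nodes, vol = rep(dz, n), L = L,
                 n = n, spacing = c(dz = dz),
                 interp = function(points) {
                   pz <- if (is.null(dim(points))) points[3] else points[, 3]
                   f <- pmin(pmax(pz / dz, 1), n - 1e-9)
                   k0 <- floor(f); t <- f - k0
                   m <- length(pz)
                   Matrix::sparseMatrix(i = c(seq_len(m), seq_len(m)),
                                        j = c(k0, pmin(k0 + 1, n)),
                                        x = c(1 - t, t), dims = c(m, n))
                 },
                 nearest = function(points) {
                   pz <- if (is.null(dim(points))) points[3] else points[, 3]
                   pmin(pmax(round(pz / dz), 1), n)
                 },
                 n_dirichlet_faces = 1L, n_neumann_faces = 1L),
            class = "npc_domain")
}
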