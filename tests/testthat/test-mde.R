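test_that("pure-Neumann box preserves the constant solution exactly", {
  dom <- npcbarrier:::neumann_box_domain(n = 20, h = 0.5)
  chain <- chain_parameters(b = 0.86, l = 8.6, n = 1)
  q <- solve_qtilde(dom, chain)
  expect_equal(q$final, rep(1, dom$n), tolerance = 1e-12)
  expect_equal(log_partition(q, structure(list(
    positions = matrix(c(0.1, 0, 5), 1, dimnames = list(NULL, c("x", "y", "z"))),
    n = 1L), class = "tether_set")), 0, tolerance = 1e-12)
})

test_that("uniform attractive potential reproduces the exponential ODE limit", {
  # dq/ds = gamma*q in a flux-free domain -> q(N) = exp(gamma*N); the
  # backward-Euler error is first order in ds, so use a small step
  dom <- npcbarrier:::neumann_box_domain(n = 10, h = 0.5)
  gamma <- 0.2; N <- 5
  chain <- chain_parameters(b = 0.86, l = 0.86 * N, n = 1)
  # apply the uniform potential through the internal node-potential hook
  Vn <- rep(-gamma, dom$n)
  cg <- npcbarrier:::contour_grid(chain$N, 0.005)
  ch <- npcbarrier:::mde_operator(dom, chain, cg$ds, Vn)
  qq <- rep(1, dom$n)
  for (k in seq_len(cg$K)) qq <- as.numeric(Matrix::solve(ch, dom$vol * qq))
  expect_equal(qq, rep(exp(gamma * N), dom$n), tolerance = 2e-3)
})

test_that("half-space solution matches the erf closed form beyond one Kuhn length", {
  er <- error_ratio_control()
  expect_lt(er$max_ratio, 0.05)
  # closed-form values
  expect_equal(halfspace_qtilde(0, 209.3), 0)
  expect_equal(halfspace_qtilde(1e4, 209.3), 1, tolerance = 1e-12)
  expect_equal(halfspace_qtilde(1, 209.3, 0.86), 0.11073, tolerance = 1e-3)
})

test_that("error ratio falls with refinement and grows with the contour step", {
  coarse <- error_ratio_control(spacing = 0.8, ds = 0.4)
  fine <- error_ratio_control(spacing = 0.2, ds = 0.1)
  expect_lt(fine$max_ratio, coarse$max_ratio)
  big_ds <- error_ratio_control(spacing = 0.4, ds = 0.8)
  ref <- error_ratio_control(spacing = 0.4, ds = 0.4)
  expect_gt(big_ds$max_ratio, ref$max_ratio)
})

test_that("discrete maximum principle holds for the inert propagator", {
  sys <- small_system()
  dom <- build_domain(sys$pore, cargo_spec(6, c(0, 0, 8)), disc_params())
  q <- solve_qtilde(dom, sys$chain)
  expect_gte(min(q$final), 0)
  expect_lte(max(q$final), 1 + 1e-12)
})

test_that("point-source propagation is symmetric (Green-function reciprocity)", {
  sys <- small_system()
  dom <- build_domain(sys$pore, NULL, disc_params())
  gap <- npcbarrier:::green_symmetry_gap(dom, sys$chain, solver_config())
  expect_lt(gap, 1e-8)
})

test_that("q_c conserves tether-normalized mass in a flux-free domain", {
  dom <- npcbarrier:::neumann_box_domain(n = 16, h = 0.5)
  chain <- chain_parameters(b = 0.86, l = 20 * 0.86, n = 1)
  cfg <- solver_config(store_all = TRUE)
  qt <- solve_qtilde(dom, chain, cfg = cfg)
  te <- structure(list(positions = matrix(c(1.1, 2.3, 3.2), 1,
                                          dimnames = list(NULL, c("x", "y", "z"))),
                       n = 1L), class = "tether_set")
  qc <- solve_qc(dom, chain, te, qt, cfg = cfg)
  masses <- colSums(qc$store * dom$vol)
  # qtilde = 1 everywhere, so the source integrates to exactly 1 and pure
  # Neumann stepping conserves it at every contour step
  expect_equal(masses, rep(1, qc$K + 1), tolerance = 1e-10)
})

test_that("a tether on the absorbing boundary is rejected", {
  sys <- small_system()
  dom <- build_domain(sys$pore, NULL, disc_params())
  qt <- solve_qtilde(dom, sys$chain)
  bad <- structure(list(positions = matrix(c(8, 0, 8), 1,
                                           dimnames = list(NULL, c("x", "y", "z"))),
                        n = 1L), class = "tether_set")
  expect_error(solve_qc(dom, sys$chain, bad, qt), "non-fluid")
})

test_that("halving the contour step barely moves the free-energy difference", {
  sys <- small_system()
  cg <- cargo_spec(8, c(0, 0, 8))
  f1 <- free_energy_difference(sys$pore, sys$chain, cg, sys$tethers,
                               solver_config(ds = 0.4))
  f2 <- free_energy_difference(sys$pore, sys$chain, cg, sys$tethers,
                               solver_config(ds = 0.2))
  expect_lt(abs(as.numeric(f1) - as.numeric(f2)), 0.05)
})

test_that("axisymmetric and 3-D representations agree on inert dF", {
  sys <- small_system()
  cg <- cargo_spec(8, c(0, 0, 8))
  f2 <- free_energy_difference(sys$pore, sys$chain, cg, sys$tethers,
                               solver_config(spacing = 0.6))
  f3 <- free_energy_difference(sys$pore, sys$chain, cg, sys$tethers,
                               solver_config(spacing = 0.6), method = "grid3d")
  expect_lt(abs(as.numeric(f2) - as.numeric(f3)) / abs(as.numeric(f2)), 0.1)
})
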