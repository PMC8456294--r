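test_that("log partition sums tether-wise log propagators", {
  # n identical tethers give n times the single-tether value
  sys <- small_system()
  dom <- build_domain(sys$pore, NULL, disc_params())
  qt <- solve_qtilde(dom, sys$chain)
  mk <- function(k) structure(list(
    positions = matrix(rep(c(7, 0, 8), k), ncol = 3, byrow = TRUE,
                       dimnames = list(NULL, c("x", "y", "z"))),
    n = as.integer(k)), class = "tether_set")
  l1 <- log_partition(qt, mk(1))
  expect_equal(log_partition(qt, mk(3)), 3 * l1, tolerance = 1e-12)
  expect_lt(l1, 0)   # qtilde < 1 inside an absorbing pore
})

test_that("critical diameter interpolates the dF = 1 kBT crossing linearly", {
  expect_equal(critical_diameter(data.frame(d_cargo_nm = c(4, 6),
                                            dF_kBT = c(0.8, 1.2))), 5.0)
  expect_true(is.na(critical_diameter(data.frame(d_cargo_nm = c(4, 6, 8),
                                                 dF_kBT = c(0.2, 0.5, 0.9)))))
  # multiple crossings: final upward crossing used, with a warning
  expect_warning(
    d <- critical_diameter(data.frame(d_cargo_nm = c(2, 4, 6, 8),
                                      dF_kBT = c(1.5, 0.5, 1.5, 3))),
    "more than once")
  expect_equal(d, 5.0)
  # already above 1 kBT at the smallest diameter
  expect_equal(suppressWarnings(critical_diameter(
    data.frame(d_cargo_nm = c(2, 4), dF_kBT = c(1.4, 2)))), 2)
  expect_error(critical_diameter(data.frame(d_cargo_nm = 2, dF_kBT = 1)),
               "two rows")
})

test_that("free volume matches the cylinder-minus-sphere formula", {
  pore <- pore_geometry(40, 40)
  expect_equal(free_volume(pore, 0), 50265.48, tolerance = 1e-6)
  expect_equal(free_volume(pore, 20), 46076.69, tolerance = 1e-6)
  v <- free_volume(pore, seq(2, 38, by = 2))
  expect_true(all(diff(v) < 0))
})

test_that("mean density is normalized, non-negative, and wall-enriched", {
  sys <- small_system()
  cfg <- solver_config(store_all = TRUE)
  dom <- build_domain(sys$pore, NULL, disc_params())
  qt <- solve_qtilde(dom, sys$chain, cfg = cfg)
  qc <- solve_qc(dom, sys$chain, sys$tethers, qt, cfg = cfg)
  rho <- mean_density(qt, qc, sys$chain)
  target <- sys$chain$n * sys$chain$N
  expect_lt(abs(rho$total - target) / target, 0.01)
  expect_gte(min(rho$rho), 0)
  # mean density near the wall (within 2 nm) exceeds the axis value
  r <- rho$domain$nodes[, "r"]
  expect_gt(mean(rho$rho[r > max(r) - 2]), mean(rho$rho[r < 1]))
  # mismatched contour grids are rejected
  qt2 <- solve_qtilde(dom, sys$chain, cfg = solver_config(ds = 0.2,
                                                          store_all = TRUE))
  expect_error(mean_density(qt2, qc, sys$chain), "mismatched")
})

test_that("no cargo means zero free-energy change", {
  sys <- small_system()
  expect_equal(as.numeric(free_energy_difference(sys$pore, sys$chain, NULL,
                                                 sys$tethers)), 0)
})

test_that("insertion-force profile is a consistent unit conversion of dF slopes", {
  sys <- small_system()
  fp <- mean_insertion_force(sys$pore, sys$chain, 6, sys$tethers,
                             z_path = seq(16, 8, by = -2))
  m <- nrow(fp)
  # central differences recomputed from the returned dF column
  expect_equal(fp$force_pN[2:(m - 1)],
               -(fp$dF_kBT[3:m] - fp$dF_kBT[1:(m - 2)]) /
                 (fp$z_nm[3:m] - fp$z_nm[1:(m - 2)]) * 4.114,
               tolerance = 1e-12)
  expect_equal(attr(fp, "mean_force_pN"),
               abs(fp$dF_kBT[m] - fp$dF_kBT[1]) / 8 * 4.114,
               tolerance = 1e-12)
  # pushing towards the centre costs free energy: dF increases inward
  expect_true(all(diff(fp$dF_kBT) > 0))
})

test_that("cargo position scan: centred cargo is the free-energy minimum", {
  sys <- small_system()
  ps <- position_scan(sys$pore, sys$chain, 6, sys$tethers,
                      axial = c(-2, 0, 2), lateral = c(0, 1.5, 3))
  ax <- ps[ps$direction == "axial", ]
  lat <- ps[ps$direction == "lateral", ]
  # zero offsets agree with the direct calculation on matching grids
  f0 <- free_energy_difference(sys$pore, sys$chain,
                               cargo_spec(6, c(0, 0, 8)), sys$tethers)
  expect_equal(ax$dF_kBT[ax$offset_nm == 0], as.numeric(f0), tolerance = 1e-10)
  # lateral displacement raises the free energy monotonically
  expect_true(all(diff(lat$dF_kBT[order(lat$offset_nm)]) > 0))
  # axial variation is small relative to the lateral one
  expect_lt(max(ax$dF_kBT) - min(ax$dF_kBT),
            max(lat$dF_kBT) - min(lat$dF_kBT))
})

test_that("orientation averaging reduces to the inert value when spots are idle", {
  sys <- small_system()
  cg_inert <- cargo_spec(8, c(0, 0, 8))
  f_inert <- free_energy_difference(sys$pore, sys$chain, cg_inert, sys$tethers)
  # no spot set at all
  f_no <- orientation_averaged_dF(sys$pore, sys$chain, cg_inert, sys$tethers,
                                  gamma = 1.1)
  expect_equal(as.numeric(f_no), as.numeric(f_inert), tolerance = 1e-10)
  # spots present but gamma = 0
  v <- sphere_vertices(8)
  cg_sp <- cargo_spec(8, c(0, 0, 8), spots = uniform_cap_spots(v, 0.5))
  f_g0 <- orientation_averaged_dF(sys$pore, sys$chain, cg_sp, sys$tethers,
                                  gamma = 0)
  expect_equal(as.numeric(f_g0), as.numeric(f_inert), tolerance = 1e-10)
})

test_that("full-coverage spot layouts are orientation-insensitive", {
  sys <- small_system()
  v <- sphere_vertices(6)
  cg <- cargo_spec(6, c(0, 0, 8), spots = uniform_cap_spots(v, 1))
  f <- orientation_averaged_dF(sys$pore, sys$chain, cg, sys$tethers,
                               gamma = 0.9,
                               orientations = test_orientations())
  Fo <- attr(f, "F_orientations")
  # the Fibonacci vertex cloud is only statistically isotropic, so allow a
  # small spread relative to the overall scale
  expect_lt(diff(range(Fo)), 0.02 * abs(mean(Fo)))
})
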