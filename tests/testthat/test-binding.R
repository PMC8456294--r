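test_that("sphere vertex count follows the conserved surface density", {
  v20 <- sphere_vertices(20)
  expect_equal(nrow(v20), 1257)      # round(pi * 400) at 1 vertex/nm^2
  expect_equal(sqrt(rowSums(v20^2)), rep(1, nrow(v20)), tolerance = 1e-12)
  # doubling the diameter quadruples the count (up to rounding)
  v40 <- sphere_vertices(40)
  expect_lt(abs(nrow(v40) - 4 * nrow(v20)), 3)
  # vertices are pairwise distinct
  v <- sphere_vertices(4)
  d <- as.matrix(dist(v))
  expect_gt(min(d[upper.tri(d)]), 0)
})

test_that("uniform cap selects the correct area fraction and latitude", {
  v <- sphere_vertices(20)
  expect_identical(uniform_cap_spots(v, 1)$N_bind, nrow(v))
  expect_identical(uniform_cap_spots(v, 0)$N_bind, 0L)
  half <- uniform_cap_spots(v, 0.5)
  # hemisphere about the -z pole: every selected vertex has z <= ~0
  expect_lt(max(v[half$spots, 3]), 0.05)
  # selected fraction converges to the coverage with N_all
  for (cov in c(0.2, 0.5, 0.8)) {
    sel <- uniform_cap_spots(v, cov)
    expect_lt(abs(sel$N_bind / sel$N_all - cov), 2 / sqrt(nrow(v)))
  }
})

test_that("Kent density matches closed forms and normalizes on the sphere", {
  # uniform limit
  expect_equal(kent_density(c(0, 0, 1), kent_params(0)), 1 / (4 * pi),
               tolerance = 1e-12)
  # vMF closed form at the mean direction, kappa = 1
  p1 <- kent_params(1, mean_direction = c(0, 0, 1))
  expect_equal(kent_density(c(0, 0, 1), p1), exp(1) / (4 * pi * sinh(1)),
               tolerance = 1e-10)
  # quadrature normalization, independent midpoint rule over the sphere
  quad_integral <- function(params) {
    nu <- 400; nph <- 400
    u <- seq(-1 + 1 / nu, 1 - 1 / nu, length.out = nu)
    ph <- (seq_len(nph) - 0.5) * 2 * pi / nph
    st <- sqrt(1 - u^2)
    tot <- 0
    for (p in ph) {
      x <- cbind(st * cos(p), st * sin(p), u)
      tot <- tot + sum(kent_density(x, params)) * (2 / nu) * (2 * pi / nph)
    }
    tot
  }
  for (k in c(0, 0.5, 2, 10))
    expect_equal(quad_integral(kent_params(k)), 1, tolerance = 1e-3)
  expect_error(kent_params(-1), "non-negative")
})

test_that("Kent sampling is seeded, uniform at kappa=0, concentrated at high kappa", {
  v <- sphere_vertices(20)
  s1 <- kent_spots(v, 100, kent_params(2), seed = 42)
  s2 <- kent_spots(v, 100, kent_params(2), seed = 42)
  expect_identical(s1$spots, s2$spots)
  expect_false(identical(s1$spots,
                         kent_spots(v, 100, kent_params(2), seed = 43)$spots))
  expect_error(kent_spots(v, nrow(v) + 1, kent_params(1)), "more binding spots")
  # kappa = 0: z-coordinates of selected spots are uniform on [-1, 1]
  # (chi-squared on equal-area latitude bands, pooled over seeds)
  zsel <- unlist(lapply(1:40, function(s)
    v[kent_spots(v, 60, kent_params(0), seed = s)$spots, 3]))
  counts <- table(cut(zsel, breaks = seq(-1, 1, length.out = 11)))
  expect_gt(chisq.test(counts)$p.value, 0.01)
  # strong concentration: mean resultant length near 1, spots near the pole
  shi <- kent_spots(v, 30, kent_params(200), seed = 1)
  dirs <- v[shi$spots, ]
  expect_gt(sqrt(sum(colMeans(dirs)^2)), 0.95)
  expect_lt(max(dirs[, 3]), -0.8)       # all close to the -z mean direction
})

test_that("adsorption potential is a strict-cutoff two-level field", {
  v <- sphere_vertices(10)
  cg <- cargo_spec(10, c(0, 0, 0), spots = uniform_cap_spots(v, 1))
  pot <- adsorption_potential(cg, gamma = 1.1, r_cutoff = 0.86)
  spot1 <- pot$spots_world[1, ]
  expect_equal(potential_at(spot1, pot), -1.1)
  expect_equal(potential_at(c(0, 0, 20), pot), 0)
  # exactly at the cutoff: strict inequality gives 0
  far <- matrix(c(0, 0, 30), 1)
  d_unit <- c(0, 0, 1)
  at_cut <- spot1 + 0.86 * d_unit
  dmin <- sqrt(min(rowSums(sweep(pot$spots_world, 2, at_cut)^2)))
  if (abs(dmin - 0.86) < 1e-9)
    expect_equal(potential_at(at_cut, pot), 0)
  # two-level property over random probes
  set.seed(1)
  probes <- cbind(runif(200, -6, 6), runif(200, -6, 6), runif(200, -6, 6))
  vals <- potential_at(probes, pot)
  expect_true(all(vals %in% c(-1.1, 0)))
  expect_error(adsorption_potential(cg, gamma = -1), "non-negative")
})

test_that("binding surface area follows S = (N_bind/N_all) pi d^2", {
  v <- sphere_vertices(20)
  full <- binding_surface_area(uniform_cap_spots(v, 1), 20)
  expect_equal(full$S, pi * 400, tolerance = 1e-12)
  expect_equal(full$S_over_Sstar, 1, tolerance = 1e-12)
  expect_equal(binding_surface_area(uniform_cap_spots(v, 0), 20)$S, 0)
  # S/S* = 0.2 configuration on the 20-nm cargo
  n02 <- round(0.2 * nrow(v))
  s02 <- binding_surface_area(
    binding_spot_set(v, seq_len(n02)), 20)
  expect_equal(s02$S, 251.33, tolerance = 0.01)
})

test_that("clustering degree counts spot enrichment near the wall-proximal spot", {
  # toy configuration: two antipodal tight vertex clusters on a d=2 cargo;
  # the +x cluster (8 vertices, 4 of them spots) faces the tether
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  near <- t(sapply(ang, function(a)
    c(cos(0.15), sin(0.15) * cos(a), sin(0.15) * sin(a))))
  far <- -near
  verts <- rbind(near, far)
  spots <- binding_spot_set(verts, 1:4, distribution = "uniform-cap")
  cg <- cargo_spec(2, c(0, 0, 8), spots = spots)
  te <- structure(list(positions = matrix(c(7, 0, 8), 1,
                                          dimnames = list(NULL, c("x", "y", "z"))),
                       n = 1L, radius = 7), class = "tether_set")
  expect_equal(clustering_degree(cg, te, r_cluster = 1), 0.5)
  # all vertices spots -> p_cluster 1 regardless of radius
  all_sp <- binding_spot_set(verts, 1:16)
  expect_equal(clustering_degree(cargo_spec(2, c(0, 0, 8), spots = all_sp),
                                 te, r_cluster = 1), 1)
  expect_error(clustering_degree(cargo_spec(2, c(0, 0, 8)), te), "undefined")
})

test_that("clustering degree increases with kappa in expectation over seeds", {
  sys <- ref_system()
  v <- sphere_vertices(20)
  nb <- round(0.2 * nrow(v))
  pc <- sapply(1:50, function(s) sapply(c(0.5, 2), function(k) {
    cg <- cargo_spec(20, c(0, 0, 20),
                     spots = kent_spots(v, nb, kent_params(k), seed = s))
    clustering_degree(cg, sys$tethers)
  }))
  expect_gt(mean(pc[2, ]), mean(pc[1, ]))
})

test_that("binding-spot export writes CSV rows plus a JSON sidecar", {
  v <- sphere_vertices(6)
  cg <- cargo_spec(6, c(0, 0, 8), spots = kent_spots(v, 20, kent_params(1),
                                                     seed = 5))
  f <- tempfile(fileext = ".csv")
  write_binding_spots(cg, f)
  tab <- read.csv(f)
  expect_identical(names(tab), c("vertex_id", "x_nm", "y_nm", "z_nm", "is_spot"))
  expect_identical(sum(tab$is_spot), 20L)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$kappa, 1)
  expect_equal(meta$seed, 5)
  expect_equal(meta$N_bind, 20)
})
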