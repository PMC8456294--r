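# shared fixtures: small study systems and memoised expensive results

.npc_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .npc_cache)) assign(name, expr, envir = .npc_cache)
  get(name, envir = .npc_cache)
}

# small pore used by most unit tests: 16 x 16 nm, 8 short chains
small_system <- function() {
  list(pore = pore_geometry(16, 16),
       chain = chain_parameters(b = 0.86, l = 40, n = 8),
       tethers = place_tethers(pore_geometry(16, 16), n = 8))
}

# reference system (Table-style parameters)
ref_system <- function() {
  list(pore = pore_geometry(40, 40),
       chain = chain_parameters(b = 0.86, l = 180, n = 80),
       tethers = place_tethers(pore_geometry(40, 40), n = 80))
}

# reference inert diameter scan (shared by the critical-diameter and
# monotonicity/convexity checks)
ref_inert_scan <- function() cached("ref_inert_scan", run_inert_scan(npc_config()))

# four-orientation subset used by scaled-down attractive checks
test_orientations <- function()
  cbind(theta = c(0, pi / 2, pi, 3 * pi / 2), phi = rep(0, 4))
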