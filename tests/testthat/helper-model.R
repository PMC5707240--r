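# Shared fixtures.  Expensive cardiac-cycle runs are computed once per test
# session, lazily, and reused across test files (including acceptance).
.lv_cache <- new.env(parent = emptyenv())

cached_run <- function(key, builder) {
  if (is.null(.lv_cache[[key]])) .lv_cache[[key]] <- builder()
  .lv_cache[[key]]
}

normal_geometry <- function() lv_geometry("normal")

default_fibers <- function(geom = normal_geometry()) lv_fibers(geom)

# light solver for tests that only need a qualitative trajectory
quick_solver <- function(...) lv_solver(n_cycles = 2, ...)

# the three full 12-cycle runs at study conditions (shared by several
# acceptance checks)
full_run <- function(shape) {
  cached_run(paste0("run_", shape), function() {
    run_cycles(lv_model(shape), 12)
  })
}

# matched-volume rebuilds with the basal truncation at the equator
equator_run <- function(shape) {
  cached_run(paste0("eq_run_", shape), function() {
    g0 <- lv_geometry(shape)
    g <- build_matched_shape(cavity_volume(g0), wall_volume(g0),
                             a0 = g0$a0, nu_up = pi / 2)
    run_cycles(lv_model(g), 12)
  })
}

converged_work <- function(sim, cycles = 6:12) {
  w <- sim$work
  w[w$cycle %in% cycles, ]
}
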