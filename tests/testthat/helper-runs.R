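# Shared meshes and memoized expensive runs (computed once per session).
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

ref_mesh <- function() memo("ref_mesh", make_mesh(lung_geometry(), hmax = 0.2))

# steady state of the calibrated reference point on the standard domain
ref_steady <- function() memo("ref_steady",
  run_to_steady(ref_mesh(), reference_params(), t_max = 500, tol = 1e-6))

# steady state of the bifurcation variant
bif_steady <- function() memo("bif_steady",
  run_to_steady(ref_mesh(), bifurcation_params(), t_max = 500, tol = 1e-6))

# fast tip growth covering one simulated day after pattern establishment
fast_growth <- function() memo("fast_growth", {
  v <- 14 / 180
  t_end <- 30 + 86.4
  gm <- make_mesh(lung_geometry(), hmax = 0.2, final_height = 6 + v * t_end)
  grow_and_solve(gm, reference_params(), growth_spec("tip", v = v),
                 t_end = t_end, record_every = 2)
})
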