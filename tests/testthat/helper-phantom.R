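# Shared phantom fixtures, built once per test run.

small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                              spacing = c(0.2, 0.2, 0.2),
                                              seed = 42L))
    cache
  }
})

phantom_bundle <- function(ph) {
  atlas_bundle(ph$volume,
               subset_fiducials(ph$fiducials, c("round_window", "basal_turn")),
               subset_fiducials(ph$fiducials,
                                c("apex", "modiolus", "round_window", "oval_window")),
               ph$fiducials$laterality)
}

init_landmarks_of <- function(fids)
  subset_fiducials(fids, c("apex", "modiolus", "round_window", "oval_window"))

# fast registration settings for the smaller fixtures
quick_config <- function(...)
  registration_config(max_iterations_affine = 80L,
                      max_iterations_bspline = 60L, ...)
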