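# Shared fixtures, built lazily and cached for the whole suite.
ff_cache <- new.env(parent = emptyenv())

fix_screen <- function() {
  if (is.null(ff_cache$screen)) ff_cache$screen <- screen_geometry()
  ff_cache$screen
}

fix_view <- function(d = 15) viewing_geometry(d, fix_screen())

fix_pose <- function() {
  if (is.null(ff_cache$pose))
    ff_cache$pose <- projector_pose(fix_screen())
  ff_cache$pose
}

fix_model <- function() {
  if (is.null(ff_cache$model)) {
    cal <- synth_calibration(fix_pose(), fix_screen(), n_per_edge = 9)
    ff_cache$model <- fit_calibration(cal)
  }
  ff_cache$model
}

fix_map <- function() {
  if (is.null(ff_cache$map)) ff_cache$map <- build_warp_map(fix_model())
  ff_cache$map
}

fix_retinotopy_bold <- function() {
  if (is.null(ff_cache$ret_bold)) {
    run <- protocol_retinotopy(seed = 11)
    amp <- synth_retinotopic_population(200, margin = 0.8,
                                        extra_conditions = 2)
    ff_cache$ret_run <- run
    ff_cache$ret_amp <- amp
    ff_cache$ret_bold <- synth_bold(
      sim_spec(amp, sigma = 2, phi = 0.3, drift_order = 2, seed = 21), run)
    ff_cache$ret_X <- build_design_matrix(run$blocks, 2, run$timing$TRs)
    ff_cache$ret_fit <- fit_glm(ff_cache$ret_bold, ff_cache$ret_X)
  }
  list(run = ff_cache$ret_run, amp = ff_cache$ret_amp,
       bold = ff_cache$ret_bold, X = ff_cache$ret_X, fit = ff_cache$ret_fit)
}

# surface -> source-canvas oracle used to compare ray tracing with the warp
trace_to_canvas <- function(pixels, pose, screen, src = c(1024, 768)) {
  tr <- trace_projector_ray(pixels, pose, screen)
  cbind((tr$s_cm / screen$surface_width_cm + 0.5) * src[1],
        (tr$h_cm / screen$surface_height_cm + 0.5) * src[2],
        tr$on_screen)
}
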