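## Experiment drivers: preset handling, batch evaluation, ablation,
## drop-out sweep, input-removal (CAN) test, connection-mode comparison,
## field sharpening.

preset_file <- function() {
  system.file("extdata", "presets.yaml", package = "fieldcode",
              mustWork = TRUE)
}

#' List the bundled model presets
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  names(yaml::read_yaml(preset_file())$presets)
}

#' Retrieve a bundled model preset
#'
#' Presets carry the published parameter columns of the optimized and
#' original model tables (see `inst/extdata/presets.yaml`), together
#' with the published summary metrics under `reported` for reference.
#'
#' @param name Preset name, e.g. `"G-Opt-1"`, `"F-Org-2"`, `"D-Org-1"`.
#' @return A list with `name`, `family`, `params`, `reported`.
#' @export
get_preset <- function(name) {
  all <- yaml::read_yaml(preset_file())$presets
  if (!name %in% names(all))
    stop("unknown preset '", name, "'; see list_presets()", call. = FALSE)
  c(list(name = name), all[[name]])
}

#' Assumed (non-published) constants used by the experiment drivers
#'
#' @return Named list: `tau_s`, `dt_s`, `i_pos`, `speed_mps`,
#'   `theta_field`, per-family `lateral` weight defaults and the default
#'   constant background `i_bck`.
#' @export
assumed_constants <- function() {
  yaml::read_yaml(preset_file())$assumed
}

#' Build a model from a preset
#'
#' @param preset A preset name or a [get_preset()] list.
#' @param env Environment.
#' @param lateral Build lateral connections (`w_exc`/`w_inh` from the
#'   assumed defaults unless overridden)?
#' @param w_exc,w_inh Optional lateral weight overrides.
#' @param ... Extra arguments forwarded to the family builder
#'   (e.g. `p_fc` for D-MF models, `w_ratio` for grid models).
#' @return An `fc_model`.
#' @export
build_preset_model <- function(preset, env, lateral = FALSE,
                               w_exc = NULL, w_inh = NULL, ...) {
  if (is.character(preset)) preset <- get_preset(preset)
  p <- preset$params
  if (lateral) {
    lat <- assumed_constants()$lateral[[tolower(preset$family)]]
    w_exc <- w_exc %||% lat$w_exc
    w_inh <- w_inh %||% lat$w_inh
  } else {
    w_exc <- 0   # 'lateral' is authoritative: overrides only shape the
    w_inh <- 0   # "+" variant, they never re-enable connections
  }
  extra <- list(...)
  switch(preset$family,
    FMF = build_fmf(env,
                    n_attractors = c(p$n_al_0, p$n_al_1, p$n_al_2),
                    p_att = p$p_att, n_neurons = p$n_neurons,
                    w_exc = w_exc, w_inh = w_inh),
    DMF = do.call(build_dmf, c(
      list(env = env, shape = p$shape, scale = p$scale, sum_fs = p$sum_fs,
           n_neurons = p$n_neurons,
           th_fsr = if (is.null(extra$p_fc)) p$th_fsr else NULL,
           w_exc = w_exc, w_inh = w_inh),
      extra)),
    GRID = do.call(build_grid, c(
      list(env = env, n_modules = p$n_modules,
           n_per_module = p$n_per_module,
           scale_factor = p$scale_factor, min_scale = p$min_scale),
      extra)),
    SSSF = build_sssf(env, n_neurons = p$n_neurons,
                      w_exc = w_exc, w_inh = w_inh),
    stop("unknown family: ", preset$family, call. = FALSE))
}

#' Evaluate a model builder over a batch of seeded runs
#'
#' The workhorse of all experiments: for each run `r`, the RNG is seeded
#' with `base_seed + r - 1`, a fresh model realization is built, one
#' traversal is simulated, templates are built from the model's own
#' noiseless rate map, and the traversal is decoded.  When `dyn` carries
#' background input or noise the decoded traversal is simulated
#' separately from the (always noiseless) templates.
#'
#' @param builder A function `() -> fc_model` using the current RNG.
#' @param env Environment.
#' @param n_runs Number of independent realizations (default 20).
#' @param base_seed Base seed; run `r` uses `base_seed + r - 1`.
#' @param dyn Dynamics parameters for the decoded traversal.
#' @param trajectory Trajectory (default: standard traversal).
#' @param theta_field Field-extraction threshold.
#' @param p_dro Optional drop-out probability applied to each
#'   realization (templates are rebuilt from the lesioned model).
#' @param removal_window Optional `c(start, end)` input-removal window;
#'   inside it the scoring target is the last driven position.
#' @return A data.frame with one row per run: `run`, `seed`,
#'   `e_pos_mean`, `n_f_mean` (mean extracted fields/neuron), `c_eng`.
#' @export
evaluate_batch <- function(builder, env, n_runs = 20, base_seed = 1L,
                           dyn = dynamics_params(), trajectory = NULL,
                           theta_field = 0.2, p_dro = 0,
                           removal_window = NULL) {
  if (is.null(trajectory))
    trajectory <- make_trajectory(env, dt_s = dyn$tau / 10)
  seeds <- run_seeds(base_seed, n_runs)
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    model <- builder()
    if (p_dro > 0) model <- apply_dropout(model, p_dro)
    noiseless <- !dyn$noisy && dyn$i_bck == 0 && is.null(removal_window)
    sim <- simulate_network(model, trajectory, dyn,
                            removal_window = removal_window)
    tmpl <- build_templates(model, env, dyn, trajectory = trajectory,
                            simulation = if (noiseless) sim else NULL)
    target <- NULL
    if (!is.null(removal_window))
      target <- removal_target_positions(trajectory, removal_window)
    dec <- positional_error(sim, tmpl, target_positions = target)
    fields <- extract_fields(tmpl, theta_field)
    c_eng <- if (nrow(fields)) env$n_bins * mean(fields$mean_rate) else 0
    out[[r]] <- data.frame(
      run = r, seed = seeds[r], e_pos_mean = dec$e_pos_mean,
      n_f_mean = nrow(fields) / model$n_neurons, c_eng = c_eng)
  }
  do.call(rbind, out)
}

## scoring target inside an input-removal window: the last driven
## position (standing still); outside the window, the true position.
removal_target_positions <- function(trajectory, removal_window) {
  pos <- trajectory$positions
  inside <- pos >= removal_window[1] & pos <= removal_window[2]
  target <- pos
  target[inside] <- removal_window[1]
  target
}

#' Baseline ablation of lateral connections and background input
#'
#' Evaluates a preset under the four combinations of (with/without
#' lateral connections) x (with/without constant background input) and
#' reports the per-run errors plus batch summaries.
#'
#' @param preset Preset name or [get_preset()] list.
#' @param env Environment.
#' @param n_runs Runs per condition.
#' @param base_seed Base seed (shared across conditions so field
#'   realizations are paired).
#' @param i_bck Background amplitude for the "+background" conditions
#'   (default from [assumed_constants()]).
#' @param ... Passed to [evaluate_batch()].
#' @return A data.frame with columns `preset`, `lateral`, `background`
#'   plus the [evaluate_batch()] columns.
#' @export
run_baseline <- function(preset, env, n_runs = 20, base_seed = 1L,
                         i_bck = NULL, ...) {
  if (is.character(preset)) preset <- get_preset(preset)
  i_bck <- i_bck %||% assumed_constants()$background$i_bck
  grid <- expand.grid(lateral = c(FALSE, TRUE),
                      background = c(FALSE, TRUE))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    lat <- grid$lateral[i]
    dyn <- dynamics_params(i_bck = if (grid$background[i]) i_bck else 0)
    res <- evaluate_batch(function() build_preset_model(preset, env,
                                                        lateral = lat),
                          env, n_runs = n_runs, base_seed = base_seed,
                          dyn = dyn, ...)
    res$preset <- preset$name
    res$lateral <- lat
    res$background <- grid$background[i]
    out[[i]] <- res
  }
  do.call(rbind, out)
}

#' Drop-out robustness sweep
#'
#' For each drop-out probability, `n_runs` independently built and
#' lesioned realizations are evaluated; decoder templates are rebuilt
#' from the lesioned model, mirroring a downstream readout that adapts
#' to the surviving population.
#'
#' @param preset Preset name or list.
#' @param env Environment.
#' @param p_dro_grid Drop-out probabilities (default `seq(0, 0.95, 0.05)`).
#' @param n_runs Runs per grid point.
#' @param base_seed Base seed.
#' @param ... Passed to [evaluate_batch()].
#' @return Long data.frame with `preset`, `p_dro` and per-run metrics.
#' @export
run_dropout_sweep <- function(preset, env,
                              p_dro_grid = seq(0, 0.95, by = 0.05),
                              n_runs = 20, base_seed = 1L, ...) {
  if (is.character(preset)) preset <- get_preset(preset)
  if (any(p_dro_grid < 0 | p_dro_grid > 1))
    stop("'p_dro_grid' must lie in [0, 1]", call. = FALSE)
  out <- vector("list", length(p_dro_grid))
  for (i in seq_along(p_dro_grid)) {
    res <- evaluate_batch(function() build_preset_model(preset, env),
                          env, n_runs = n_runs, base_seed = base_seed,
                          p_dro = p_dro_grid[i], ...)
    res$preset <- preset$name
    res$p_dro <- p_dro_grid[i]
    out[[i]] <- res
  }
  do.call(rbind, out)
}

#' Input-removal (continuous-attractor) test
#'
#' The positional input is removed for `l_rem` meters of the traversal
#' and the preset is evaluated with and without lateral connections
#' under a constant background input.  Inside the window the scoring
#' target is the last driven position: a network that sustains its
#' activity bump there decodes it correctly, whereas one whose activity
#' collapses to the background does not.  A continuous attractor should
#' therefore show a *lower* error with lateral connections than without.
#'
#' @param preset Preset name or list.
#' @param env Environment.
#' @param l_rem Removal window length in meters (default 20).
#' @param removal_start Window start (default: centered on the track).
#' @param n_runs Runs per condition.
#' @param base_seed Base seed (paired across conditions).
#' @param i_bck Constant background amplitude (default from
#'   [assumed_constants()]).
#' @param ... Passed to [evaluate_batch()].
#' @return Data.frame with `preset`, `lateral` and per-run metrics.
#' @export
run_can_test <- function(preset, env, l_rem = 20, removal_start = NULL,
                         n_runs = 20, base_seed = 1L, i_bck = NULL, ...) {
  if (is.character(preset)) preset <- get_preset(preset)
  removal_start <- removal_start %||% ((env$length_m - l_rem) / 2)
  if (removal_start < 0 || removal_start + l_rem > env$length_m)
    stop("removal window must lie within the track", call. = FALSE)
  i_bck <- i_bck %||% assumed_constants()$background$i_bck
  window <- if (l_rem > 0) c(removal_start, removal_start + l_rem)
  out <- vector("list", 2L)
  for (i in 1:2) {
    lat <- c(FALSE, TRUE)[i]
    res <- evaluate_batch(function() build_preset_model(preset, env,
                                                        lateral = lat),
                          env, n_runs = n_runs, base_seed = base_seed,
                          dyn = dynamics_params(i_bck = i_bck),
                          removal_window = window, ...)
    res$preset <- preset$name
    res$lateral <- lat
    out[[i]] <- res
  }
  do.call(rbind, out)
}

#' Size-gated versus random lateral connectivity (D-MF)
#'
#' Compares a D-MF preset built with its field-size ratio threshold
#' against the same preset built with a field connection probability
#' matched to the empirical connection fraction the threshold produces
#' on calibration builds.  Both modes are evaluated `n_runs` times with
#' lateral connections active.
#'
#' @param preset A D-MF preset name or list.
#' @param env Environment.
#' @param th_fsr Ratio threshold (default: the preset's).
#' @param p_fc Matched connection probability; when `NULL` it is
#'   calibrated as the mean qualifying-pair fraction over
#'   `n_calibration` builds.
#' @param n_runs Runs per mode (published protocol uses 100).
#' @param n_calibration Calibration builds for the matching.
#' @param base_seed Base seed.
#' @param ... Passed to [evaluate_batch()].
#' @return List with `p_fc_matched` and `results` (long data.frame with
#'   column `mode` = "th_fsr" / "p_fc").
#' @export
run_connection_mode <- function(preset, env, th_fsr = NULL, p_fc = NULL,
                                n_runs = 100, n_calibration = 5,
                                base_seed = 1L, ...) {
  if (is.character(preset)) preset <- get_preset(preset)
  if (preset$family != "DMF")
    stop("connection-mode comparison requires a D-MF preset",
         call. = FALSE)
  th_fsr <- th_fsr %||% preset$params$th_fsr
  p <- preset$params
  if (is.null(p_fc)) {
    fr <- vapply(run_seeds(base_seed + 900L, n_calibration), function(s) {
      set.seed(s)
      m <- build_dmf(env, shape = p$shape, scale = p$scale,
                     sum_fs = p$sum_fs, n_neurons = p$n_neurons,
                     th_fsr = th_fsr, connectivity = TRUE)
      m$conn$connection_fraction
    }, numeric(1))
    p_fc <- mean(fr)
  }
  modes <- list(th_fsr = list(th_fsr = th_fsr, p_fc = NULL),
                p_fc = list(th_fsr = NULL, p_fc = p_fc))
  out <- vector("list", 2L)
  for (i in seq_along(modes)) {
    mo <- modes[[i]]
    lat <- assumed_constants()$lateral$dmf
    res <- evaluate_batch(function()
      build_dmf(env, shape = p$shape, scale = p$scale, sum_fs = p$sum_fs,
                n_neurons = p$n_neurons, th_fsr = mo$th_fsr,
                p_fc = mo$p_fc, w_exc = lat$w_exc, w_inh = lat$w_inh),
      env, n_runs = n_runs, base_seed = base_seed, ...)
    res$preset <- preset$name
    res$mode <- names(modes)[i]
    out[[i]] <- res
  }
  list(p_fc_matched = p_fc, results = do.call(rbind, out))
}

#' Field sharpening by lateral connections
#'
#' Builds the same field realization with and without lateral
#' connections (identical seed) and compares the resulting rate maps:
#' lateral inhibition trims out-of-field activity, sharpening the
#' fields.
#'
#' @param preset Preset name or list.
#' @param env Environment.
#' @param seed Seed for the shared field realization.
#' @param k Number of neurons whose rate-map pairs are returned.
#' @param theta_field Field-extraction threshold.
#' @param w_exc,w_inh Optional lateral weight overrides.
#' @return A list: `maps_off`/`maps_on` (k x n_bins), and the sharpening
#'   statistics `out_of_field_fraction_off`/`_on` (fraction of total
#'   activity outside extracted fields) and `mean_field_width_off`/`_on`
#'   (meters).
#' @export
run_sharpening <- function(preset, env, seed = 1L, k = 5,
                           theta_field = 0.2, w_exc = NULL, w_inh = NULL) {
  if (is.character(preset)) preset <- get_preset(preset)
  build <- function(lateral) {
    set.seed(seed)
    build_preset_model(preset, env, lateral = lateral,
                       w_exc = w_exc, w_inh = w_inh)
  }
  m_off <- build(FALSE)
  m_on <- build(TRUE)
  t_off <- build_templates(m_off, env)
  t_on <- build_templates(m_on, env)
  oof <- function(tmpl) {
    fields <- extract_fields(tmpl, theta_field)
    infield <- matrix(FALSE, nrow(tmpl$map), ncol(tmpl$map))
    for (i in seq_len(nrow(fields)))
      infield[fields$neuron[i],
              fields$start_bin[i]:fields$end_bin[i]] <- TRUE
    total <- sum(tmpl$map)
    list(frac = if (total > 0) sum(tmpl$map[!infield]) / total else 0,
         width = if (nrow(fields)) mean(fields$size_m) else NA_real_)
  }
  s_off <- oof(t_off)
  s_on <- oof(t_on)
  kk <- seq_len(min(k, m_off$n_neurons))
  list(maps_off = t_off$map[kk, , drop = FALSE],
       maps_on = t_on$map[kk, , drop = FALSE],
       out_of_field_fraction_off = s_off$frac,
       out_of_field_fraction_on = s_on$frac,
       mean_field_width_off = s_off$width,
       mean_field_width_on = s_on$width)
}

#' Summarize a long result table
#'
#' @param results A data.frame from an experiment driver.
#' @param by Grouping columns (default: all non-metric columns present).
#' @return Data.frame of group-wise median/mean/min/max/sd of
#'   `e_pos_mean`.
#' @export
summarize_results <- function(results,
                              by = intersect(c("preset", "lateral",
                                               "background", "p_dro",
                                               "mode"),
                                             names(results))) {
  agg <- function(f) stats::aggregate(results$e_pos_mean, results[by], f)
  out <- agg(stats::median)
  names(out)[ncol(out)] <- "e_pos_median"
  out$e_pos_mean <- agg(mean)$x
  out$e_pos_min <- agg(min)$x
  out$e_pos_max <- agg(max)$x
  out$e_pos_sd <- agg(stats::sd)$x
  out
}
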