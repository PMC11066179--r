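# Shared fixtures: a standard 200 m track and a small 20 m track for
# fast unit tests.  All fixtures are built in code; nothing is stored.

std_env <- function() make_environment(200, 0.5)
small_env <- function() make_environment(20, 0.5)

# a hand-made rate map (for decoder unit tests)
make_ratemap <- function(map, env) {
  structure(list(map = map, env = env), class = "fc_ratemap")
}

# a minimal hand-made model with explicit fields (center, width per row)
make_toy_model <- function(env, centers, widths, neurons = NULL, W = NULL) {
  neurons <- neurons %||% seq_along(centers)
  n <- max(neurons)
  fields <- data.frame(neuron = neurons, center = centers, width = widths,
                       attractor = NA_character_)
  fieldcode:::new_fc_model("SSSF", n, fields, W,
                           params = list(), env = env)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build + simulate + self-decode one seeded realization; returns the
# per-run mean positional error
run_once <- function(builder, env, traj, seed,
                     dyn = dynamics_params()) {
  set.seed(seed)
  model <- builder()
  sim <- simulate_network(model, traj, dyn)
  tmpl <- build_templates(model, env, dyn, trajectory = traj,
                          simulation = if (!dyn$noisy && dyn$i_bck == 0)
                            sim else NULL)
  positional_error(sim, tmpl)$e_pos_mean
}
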