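## Evolutionary (genetic) optimization over discretized model parameters:
## generate -> evaluate -> select -> mate -> mutate, with elitism.

#' Define a discretized, bounded parameter space
#'
#' @param names Parameter names.
#' @param lower,upper Finite bounds per parameter.
#' @param step Discretization step per parameter (> 0); genome values
#'   always lie on the grid `lower + k * step` within the bounds.
#' @return A data.frame of class `fc_param_space`.
#' @export
ga_param_space <- function(names, lower, upper, step) {
  stopifnot(length(names) == length(lower),
            length(lower) == length(upper),
            length(upper) == length(step))
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(step <= 0) ||
      any(upper < lower))
    stop("bounds must be finite with upper >= lower and step > 0",
         call. = FALSE)
  structure(
    data.frame(name = names, lower = lower, upper = upper, step = step,
               stringsAsFactors = FALSE),
    class = c("fc_param_space", "data.frame"))
}

ga_grid_values <- function(space, i) {
  seq(space$lower[i], space$upper[i], by = space$step[i])
}

#' Draw a random genome on the parameter grid
#'
#' @param space An [ga_param_space()].
#' @return Named numeric vector, in-bounds and on-grid.
#' @export
ga_random_genome <- function(space) {
  g <- vapply(seq_len(nrow(space)),
              function(i) sample(ga_grid_values(space, i), 1L),
              numeric(1))
  names(g) <- space$name
  g
}

#' GA configuration
#'
#' @param n_pop Population size (default 20).
#' @param r_sel Selection rate (default 0.2).
#' @param p_mut Mutation probability (default 0.2).
#' @param epochs Number of generations (default 3000).
#' @param n_eval_runs Independent model realizations per fitness
#'   evaluation (default 20).
#' @param aggregate How per-run errors are aggregated, `"median"` or
#'   `"mean"`.
#' @return A list of class `fc_ga_config`.
#' @export
ga_config <- function(n_pop = 20, r_sel = 0.2, p_mut = 0.2, epochs = 3000,
                      n_eval_runs = 20, aggregate = c("median", "mean")) {
  if (r_sel <= 0 || r_sel > 1) stop("'r_sel' must lie in (0, 1]",
                                    call. = FALSE)
  if (p_mut < 0 || p_mut > 1) stop("'p_mut' must lie in [0, 1]",
                                   call. = FALSE)
  structure(
    list(n_pop = as.integer(n_pop), r_sel = r_sel, p_mut = p_mut,
         epochs = as.integer(epochs), n_eval_runs = as.integer(n_eval_runs),
         aggregate = match.arg(aggregate)),
    class = "fc_ga_config")
}

#' Fitness of an aggregated positional error
#'
#' `f = exp(-E * 5 / L_env) / n_neurons`: strictly decreasing in the
#' error, with the neuron count as a divisor so that smaller networks of
#' equal accuracy score higher.  The factor 5 merely rescales the
#' exponent.
#'
#' @param e_pos Aggregated (mean or median over runs) mean positional
#'   error in meters.
#' @param l_env Track length in meters.
#' @param n_neurons Total neuron count.
#' @return Fitness value, `> 0`.
#' @export
ga_fitness <- function(e_pos, l_env, n_neurons) {
  stopifnot(e_pos >= 0, l_env > 0, n_neurons >= 1)
  exp(-e_pos * 5 / l_env) / n_neurons
}

#' Select the fittest fraction of a population
#'
#' Genomes are ordered by decreasing fitness (stable: ties keep insertion
#' order) and the top `ceiling(r_sel * n)` survive.
#'
#' @param fitness Numeric fitness vector (one per genome).
#' @param r_sel Selection rate.
#' @return Integer indices of the survivors, best first.
#' @export
ga_select <- function(fitness, r_sel) {
  if (!length(fitness)) stop("empty population", call. = FALSE)
  k <- ceiling(r_sel * length(fitness))
  order(-fitness)[seq_len(k)]   # order() is stable: ties by index
}

#' Single-point crossover of two genomes
#'
#' A crossover point `k` is drawn uniformly from `1:(n_params - 1)`; the
#' child inherits parameters `1:k` from `a` and the rest from `b`.
#' Single-parameter genomes are copied from `a`.
#'
#' @param a,b Parent genomes (equal length, same parameter space).
#' @return The child genome.
#' @export
ga_mate <- function(a, b) {
  n <- length(a)
  if (n != length(b)) stop("parents must share a parameter space",
                           call. = FALSE)
  if (n == 1L) return(a)
  k <- sample.int(n - 1L, 1L)
  c(a[seq_len(k)], b[seq.int(k + 1L, n)])
}

#' Mutate a genome on its parameter grid
#'
#' Each parameter is independently selected for mutation with
#' probability `p_mut`; a selected parameter is re-drawn uniformly from
#' its discretized range.
#'
#' @param genome Named numeric genome.
#' @param p_mut Mutation probability.
#' @param space The [ga_param_space()].
#' @return The (possibly) mutated genome, in-bounds and on-grid.
#' @export
ga_mutate <- function(genome, p_mut, space) {
  if (p_mut <= 0) return(genome)
  sel <- stats::runif(length(genome)) < p_mut
  for (i in which(sel))
    genome[i] <- sample(ga_grid_values(space, i), 1L)
  genome
}

## fitness-proportional (roulette) parent sampling with replacement
ga_pick_parents <- function(survivors, fitness) {
  p <- fitness[survivors]
  p <- if (sum(p) > 0) p / sum(p) else rep(1 / length(p), length(p))
  survivors[sample.int(length(survivors), 2L, replace = TRUE, prob = p)]
}

#' Run the genetic algorithm
#'
#' Loop of evaluate / select / mate / mutate for `config$epochs`
#' generations with elitism: the best genome of each generation is
#' carried unchanged into the next, so the best-so-far fitness is
#' non-decreasing.
#'
#' @param space An [ga_param_space()].
#' @param fitness_fn Function `genome -> fitness` (scalar, `> 0`).  Use
#'   [ga_model_fitness_fn()] for a full build/simulate/decode
#'   evaluation, or any surrogate for desk-scale testing.
#' @param config An [ga_config()].
#' @param seed Integer seed for the whole run.
#' @return A list with `history` (data.frame: generation, one column per
#'   parameter, fitness, best flag), `best_genome` and `best_fitness`.
#' @export
run_ga <- function(space, fitness_fn, config = ga_config(), seed = 1L) {
  stopifnot(inherits(space, "fc_param_space"))
  set.seed(as.integer(seed))
  n_par <- nrow(space)
  pop <- replicate(config$n_pop, ga_random_genome(space), simplify = FALSE)
  history <- vector("list", config$epochs)
  best_genome <- NULL
  best_fitness <- -Inf

  for (gen in seq_len(config$epochs)) {
    fitness <- vapply(pop, fitness_fn, numeric(1))
    gen_best <- which.max(fitness)
    if (fitness[gen_best] > best_fitness) {
      best_fitness <- fitness[gen_best]
      best_genome <- pop[[gen_best]]
    }
    h <- as.data.frame(do.call(rbind, pop))
    names(h) <- space$name
    h$fitness <- fitness
    h$generation <- gen
    h$best <- seq_along(pop) == gen_best
    history[[gen]] <- h

    if (gen == config$epochs) break
    survivors <- ga_select(fitness, config$r_sel)
    children <- vector("list", config$n_pop - 1L)
    for (i in seq_along(children)) {
      par <- ga_pick_parents(survivors, fitness)
      child <- ga_mate(pop[[par[1]]], pop[[par[2]]])
      children[[i]] <- ga_mutate(child, config$p_mut, space)
    }
    pop <- c(list(pop[[gen_best]]), children)   # elite survives unchanged
  }
  list(history = do.call(rbind, history),
       best_genome = best_genome, best_fitness = best_fitness)
}

#' Full-simulation fitness evaluator for a model family
#'
#' Returns a closure mapping a genome to its fitness: it builds
#' `config$n_eval_runs` independent model realizations (seeds
#' `base_seed + run - 1`), simulates a noiseless traversal, decodes it
#' against the model's own templates, aggregates the per-run mean errors
#' (mean or median) and applies [ga_fitness()].  A diverged simulation
#' yields the smallest representable positive fitness.
#'
#' @param family One of `"FMF"`, `"DMF"`, `"GRID"`, `"SSSF"`.  Genome
#'   names must match the corresponding builder arguments (e.g. for
#'   `"GRID"`: `n_modules`, `n_per_module`, `scale_factor`, `min_scale`).
#' @param env Environment.
#' @param config An [ga_config()].
#' @param base_seed Base seed for evaluation runs.
#' @param dyn Dynamics parameters for the evaluation traversal.
#' @return Function `genome -> fitness`.
#' @export
ga_model_fitness_fn <- function(family, env, config = ga_config(),
                                base_seed = 1000L,
                                dyn = dynamics_params()) {
  traj <- make_trajectory(env)
  function(genome) {
    errs <- tryCatch({
      vapply(run_seeds(base_seed, config$n_eval_runs), function(s) {
        set.seed(s)
        model <- build_from_genome(family, genome, env)
        sim <- simulate_network(model, traj, dyn)
        tmpl <- build_templates(model, env, dyn, simulation = sim)
        positional_error(sim, tmpl)$e_pos_mean
      }, numeric(1))
    }, error = function(e) NULL)
    if (is.null(errs)) return(.Machine$double.xmin)
    agg <- if (config$aggregate == "median") stats::median(errs)
           else mean(errs)
    n_neu <- genome_n_neurons(family, genome)
    ga_fitness(agg, env$length_m, n_neu)
  }
}

build_from_genome <- function(family, genome, env) {
  g <- as.list(genome)
  switch(family,
    GRID = build_grid(env, n_modules = round(g$n_modules),
                      n_per_module = round(g$n_per_module),
                      scale_factor = g$scale_factor,
                      min_scale = g$min_scale),
    FMF = build_fmf(env,
                    n_attractors = round(c(g$n_al_0, g$n_al_1, g$n_al_2)),
                    p_att = g$p_att,
                    n_neurons = round(g$n_neurons %||% 50),
                    w_exc = g$w_exc %||% 0, w_inh = g$w_inh %||% 0),
    DMF = build_dmf(env, shape = g$shape, scale = g$scale,
                    sum_fs = g$sum_fs,
                    n_neurons = round(g$n_neurons %||% 50),
                    th_fsr = g$th_fsr,
                    w_exc = g$w_exc %||% 0, w_inh = g$w_inh %||% 0),
    SSSF = build_sssf(env, n_neurons = round(g$n_neurons %||% 50),
                      w_exc = g$w_exc %||% 0, w_inh = g$w_inh %||% 0),
    stop("unknown model family: ", family, call. = FALSE))
}

genome_n_neurons <- function(family, genome) {
  g <- as.list(genome)
  if (family == "GRID") round(g$n_modules) * round(g$n_per_module)
  else round(g$n_neurons %||% 50)
}

#' Write a GA history to CSV
#'
#' @param ga_result Result of [run_ga()].
#' @param path Output CSV path.
#' @export
write_ga_history <- function(ga_result, path) {
  utils::write.csv(ga_result$history, path, row.names = FALSE)
  invisible(path)
}
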