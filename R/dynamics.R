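#' Dynamics parameter set
#'
#' Parameters of the threshold-linear rate dynamics
#' `tau * dh/dt = -h + W g(h) + I_bck + I_pos(t)` with gain
#' `g(h) = max(h, 0)`.  When `i_noise_sd > 0` (or `i_noise_mu` is set),
#' a per-neuron, per-step Gaussian background `N(i_noise_mu, i_noise_sd)`
#' replaces the constant background `i_bck`.
#'
#' @param tau Membrane time constant in seconds (default 0.1).
#' @param i_bck Constant background input (default 0).
#' @param i_noise_mu,i_noise_sd Mean/SD of the Gaussian background; the
#'   noisy background is active when `i_noise_sd > 0` or `i_noise_mu`
#'   is non-`NULL`.
#' @param i_pos Positional input amplitude (default 1).
#' @return An object of class `fc_dynamics`.
#' @export
dynamics_params <- function(tau = 0.1, i_bck = 0, i_noise_mu = NULL,
                            i_noise_sd = 0, i_pos = 1) {
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  if (i_noise_sd < 0) stop("'i_noise_sd' must be >= 0", call. = FALSE)
  noisy <- !is.null(i_noise_mu) || i_noise_sd > 0
  structure(
    list(tau = tau, i_bck = i_bck,
         i_noise_mu = if (noisy) (i_noise_mu %||% 0) else NULL,
         i_noise_sd = i_noise_sd, i_pos = i_pos, noisy = noisy),
    class = "fc_dynamics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Positional input to every neuron at one position
#'
#' Each field `p` of neuron `i`, with center `x_ip` and length constant
#' `L_p` (the field's own width), contributes
#' `i_pos * exp(-|x_ip - pos| / L_p)`; contributions of a neuron's fields
#' add.  Field-less neurons receive 0.
#'
#' @param model An `fc_model`.
#' @param pos Position in meters.
#' @param i_pos Input amplitude.
#' @return Numeric vector of length `model$n_neurons`.
#' @export
positional_input <- function(model, pos, i_pos = 1) {
  stopifnot(inherits(model, "fc_model"))
  if (pos < 0 || pos > model$env$length_m)
    stop("'pos' must lie on the track", call. = FALSE)
  f <- model$fields
  out <- numeric(model$n_neurons)
  if (nrow(f) == 0L) return(out)
  contrib <- i_pos * exp(-abs(f$center - pos) / f$width)
  agg <- rowsum(contrib, group = f$neuron)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

## n_neurons x n_positions positional input matrix, accumulated over
## fields in chunks to bound memory on large models.
positional_input_matrix <- function(model, positions, i_pos = 1,
                                    chunk = 2000L) {
  f <- model$fields
  n_t <- length(positions)
  out <- matrix(0, model$n_neurons, n_t)
  if (nrow(f) == 0L) return(out)
  starts <- seq.int(1L, nrow(f), by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, nrow(f))
    E <- i_pos * exp(-abs(outer(f$center[idx], positions, "-")) /
                       f$width[idx])
    agg <- rowsum(E, group = f$neuron[idx])
    rows <- as.integer(rownames(agg))
    out[rows, ] <- out[rows, ] + agg
  }
  out
}

#' Simulate the rate dynamics along a trajectory
#'
#' Forward-Euler integration of
#' `tau * dh/dt = -h + W g(h) + I_bck + I_pos(t)` with `h(0) = 0` and
#' threshold-linear gain `g(h) = max(h, 0)`.  The positional input
#' follows the trajectory; inside an optional removal window it is forced
#' to zero while any background input persists.
#'
#' @param model An `fc_model`.
#' @param trajectory An [make_trajectory()] object.
#' @param dyn A [dynamics_params()] object.
#' @param removal_window Optional `c(start, end)` position interval in
#'   meters within which positional input is zeroed.
#' @return An object of class `fc_simulation` with matrices `h` and
#'   `rates` (`n_neurons` x `n_samples`), plus `positions`, `times` and
#'   `dt_s` copied from the trajectory.
#' @export
simulate_network <- function(model, trajectory, dyn = dynamics_params(),
                             removal_window = NULL) {
  stopifnot(inherits(model, "fc_model"), inherits(trajectory, "fc_trajectory"),
            inherits(dyn, "fc_dynamics"))
  dt <- trajectory$dt_s
  if (dt >= dyn$tau)
    stop("integration step 'dt_s' must be smaller than 'tau'", call. = FALSE)
  pos <- trajectory$positions
  n_t <- length(pos)
  n <- model$n_neurons

  ipos <- positional_input_matrix(model, pos, i_pos = dyn$i_pos)
  if (!is.null(removal_window)) {
    inside <- pos >= removal_window[1] & pos <= removal_window[2]
    ipos[, inside] <- 0
  }

  W <- model$W
  h <- matrix(0, n, n_t)
  hv <- numeric(n)
  a <- dt / dyn$tau
  for (t in 2:n_t) {
    drive <- ipos[, t - 1L]
    if (dyn$noisy) {
      drive <- drive + stats::rnorm(n, dyn$i_noise_mu, dyn$i_noise_sd)
    } else if (dyn$i_bck != 0) {
      drive <- drive + dyn$i_bck
    }
    if (!is.null(W)) drive <- drive + as.vector(W %*% pmax(hv, 0))
    hv <- hv + a * (drive - hv)
    if (anyNA(hv) || any(!is.finite(hv)))
      stop(sprintf("simulation diverged at step %d (t = %.3f s)",
                   t - 1L, trajectory$times[t]), call. = FALSE)
    h[, t] <- hv
  }
  structure(
    list(h = h, rates = pmax(h, 0), positions = pos,
         times = trajectory$times, dt_s = dt,
         removal_window = removal_window),
    class = "fc_simulation")
}

#' Simulate with a positional-input removal window
#'
#' Identical to [simulate_network()] except that the positional input is
#' forced to zero while the agent is inside
#' `[removal_start, removal_start + l_rem]`; background input is
#' unaffected.  Used to probe continuous-attractor behavior: a network
#' that sustains its activity bump keeps encoding the last driven
#' position throughout the window.
#'
#' @inheritParams simulate_network
#' @param removal_start Window start in meters.
#' @param l_rem Window length in meters (default 20).
#' @return An `fc_simulation`.
#' @export
simulate_with_removal <- function(model, trajectory, dyn = dynamics_params(),
                                  removal_start, l_rem = 20) {
  if (l_rem < 0 || removal_start < 0 ||
      removal_start + l_rem > model$env$length_m)
    stop("removal window must lie within the track", call. = FALSE)
  if (l_rem == 0)
    return(simulate_network(model, trajectory, dyn))
  simulate_network(model, trajectory, dyn,
                   removal_window = c(removal_start, removal_start + l_rem))
}

#' @export
print.fc_simulation <- function(x, ...) {
  cat(sprintf("Simulation: %d neurons, %d samples (dt = %g s)\n",
              nrow(x$h), ncol(x$h), x$dt_s))
  invisible(x)
}
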