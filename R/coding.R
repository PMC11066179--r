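#' Build decoding templates (rate map) from a noiseless traversal
#'
#' Simulates one noiseless calibration traversal (no background input,
#' no noise, the model's own recurrent weights) and averages each
#' neuron's rate within every environment bin.  The resulting
#' `n_neurons x n_bins` rate map serves both as the tuning-curve estimate
#' and as the template bank of the population-vector decoder.
#'
#' @param model An `fc_model`.
#' @param env The environment (defaults to the model's own).
#' @param dyn Dynamics parameters; background/noise terms are ignored
#'   (templates are always noiseless).
#' @param trajectory Optional trajectory (defaults to a standard
#'   constant-speed traversal).
#' @param simulation Optional precomputed noiseless `fc_simulation` to
#'   bin-average instead of re-simulating.
#' @return An object of class `fc_ratemap`: list with `map`
#'   (`n_neurons x n_bins`), `env`.
#' @export
build_templates <- function(model, env = model$env, dyn = dynamics_params(),
                            trajectory = NULL, simulation = NULL) {
  stopifnot(inherits(model, "fc_model"))
  if (is.null(simulation)) {
    if (is.null(trajectory)) trajectory <- make_trajectory(env)
    quiet <- dynamics_params(tau = dyn$tau, i_bck = 0, i_noise_sd = 0,
                             i_pos = dyn$i_pos)
    simulation <- simulate_network(model, trajectory, quiet)
  }
  bin_average(simulation, env)
}

#' Average simulated rates within environment bins
#'
#' @param simulation An `fc_simulation`.
#' @param env An `fc_environment`.
#' @return An `fc_ratemap`.
#' @export
bin_average <- function(simulation, env) {
  stopifnot(inherits(simulation, "fc_simulation"),
            inherits(env, "fc_environment"))
  bins <- position_to_bin(env, simulation$positions)
  n <- nrow(simulation$rates)
  map <- matrix(0, n, env$n_bins)
  agg <- t(rowsum(t(simulation$rates), group = bins))
  counts <- tabulate(bins, nbins = env$n_bins)
  filled <- as.integer(colnames(agg))
  map[, filled] <- sweep(agg, 2, counts[filled], "/")
  structure(list(map = map, env = env), class = "fc_ratemap")
}

#' @export
print.fc_ratemap <- function(x, ...) {
  cat(sprintf("Rate map: %d neurons x %d bins (peak %.3g)\n",
              nrow(x$map), ncol(x$map), max(x$map)))
  invisible(x)
}

#' Decode position by maximum cosine similarity
#'
#' Population-vector decoding: each instantaneous rate vector is matched
#' against every template column by cosine similarity and the best bin is
#' returned.  The decoder is scale-invariant; ties break toward the
#' lowest bin index, and an all-zero rate vector falls back to bin 1
#' (the documented degenerate case).
#'
#' @param rates A rate vector of length `n_neurons`, or an
#'   `n_neurons x T` matrix, or an `fc_simulation`.
#' @param templates An `fc_ratemap`.
#' @return Integer vector of decoded 1-based bin indices.
#' @export
decode_position <- function(rates, templates) {
  stopifnot(inherits(templates, "fc_ratemap"))
  if (inherits(rates, "fc_simulation")) rates <- rates$rates
  if (is.null(dim(rates))) rates <- matrix(rates, ncol = 1L)
  if (nrow(rates) != nrow(templates$map))
    stop("rate vector length must equal the neuron count", call. = FALSE)
  tn <- sqrt(colSums(templates$map^2))
  tn[tn == 0] <- Inf            # silent bins never win
  tmpl <- sweep(templates$map, 2, tn, "/")
  sim <- crossprod(rates, tmpl)            # T x n_bins
  rn <- sqrt(rowSums(t(rates)^2))
  sim[rn == 0, ] <- 0                      # zero rates: fall back to bin 1
  max.col(sim, ties.method = "first")
}

#' Positional decoding error of a simulation
#'
#' Decodes every timestep and measures the absolute distance between the
#' decoded bin center and the target position (by default the true
#' position; an input-removal protocol may substitute the last driven
#' position inside the window).
#'
#' @param simulation An `fc_simulation`.
#' @param templates An `fc_ratemap` from the same environment.
#' @param target_positions Optional vector of target positions (meters),
#'   defaulting to the simulation's true positions.
#' @return An object of class `fc_decoding`: `decoded_bin`,
#'   `decoded_pos`, `error` (per step, meters) and `e_pos_mean`.
#' @export
positional_error <- function(simulation, templates,
                             target_positions = NULL) {
  stopifnot(inherits(simulation, "fc_simulation"))
  target <- target_positions %||% simulation$positions
  bins <- decode_position(simulation, templates)
  decoded <- templates$env$bin_centers[bins]
  err <- abs(decoded - target)
  structure(
    list(decoded_bin = bins, decoded_pos = decoded, error = err,
         e_pos_mean = mean(err)),
    class = "fc_decoding")
}

#' @export
print.fc_decoding <- function(x, ...) {
  cat(sprintf("Decoding: mean positional error %.3f m over %d steps\n",
              x$e_pos_mean, length(x$error)))
  invisible(x)
}

#' Summary statistics of per-run mean errors
#'
#' @param e_pos_means Numeric vector of per-run mean positional errors.
#' @return Named vector: median, mean, min, max, sd.
#' @export
error_batch_stats <- function(e_pos_means) {
  c(median = stats::median(e_pos_means), mean = mean(e_pos_means),
    min = min(e_pos_means), max = max(e_pos_means),
    sd = stats::sd(e_pos_means))
}

#' Extract firing fields from a rate map
#'
#' Bins whose rate exceeds `theta_field` times the neuron's peak rate are
#' grouped into maximal contiguous runs; each run is one extracted field.
#' Neurons with zero peak yield no fields.
#'
#' @param templates An `fc_ratemap` (or a single rate-map row as a
#'   numeric vector together with `env`).
#' @param theta_field Fraction of the per-neuron peak rate used as the
#'   in-field threshold (default 0.2).
#' @param env Environment, required when `templates` is a bare vector.
#' @return A data.frame with one row per field: `neuron`, `start_bin`,
#'   `end_bin`, `size_m`, `mean_rate`.
#' @export
extract_fields <- function(templates, theta_field = 0.2, env = NULL) {
  if (theta_field <= 0 || theta_field >= 1)
    stop("'theta_field' must lie in (0, 1)", call. = FALSE)
  if (inherits(templates, "fc_ratemap")) {
    map <- templates$map
    env <- templates$env
  } else {
    map <- matrix(templates, nrow = 1L)
    if (is.null(env)) stop("'env' required for a bare rate-map row",
                           call. = FALSE)
  }
  out <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    row <- map[i, ]
    peak <- max(row)
    if (peak <= 0) next
    above <- row > theta_field * peak
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) next
    out[[i]] <- data.frame(
      neuron = i,
      start_bin = starts[keep],
      end_bin = ends[keep],
      size_m = r$lengths[keep] * env$bin_m,
      mean_rate = vapply(keep, function(k)
        mean(row[starts[k]:ends[k]]), numeric(1)))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(neuron = integer(0), start_bin = integer(0),
                      end_bin = integer(0), size_m = numeric(0),
                      mean_rate = numeric(0)))
  do.call(rbind, out)
}

#' Expected energy consumption of a code
#'
#' `C_eng = n_bins * mean in-field rate over all extracted fields`, a
#' proxy for the metabolic cost of maintaining the code's activity.
#'
#' @param templates An `fc_ratemap`.
#' @param theta_field Field-extraction threshold (see
#'   [extract_fields()]).
#' @return The scalar energy value; 0 (with a warning) when no fields
#'   are present.
#' @export
energy_consumption <- function(templates, theta_field = 0.2) {
  stopifnot(inherits(templates, "fc_ratemap"))
  fields <- extract_fields(templates, theta_field)
  if (nrow(fields) == 0L) {
    warning("no fields extracted; energy set to 0", call. = FALSE)
    return(0)
  }
  templates$env$n_bins * mean(fields$mean_rate)
}

## local maxima of a smoothed histogram with a minimum prominence
## (fraction of the global maximum)
find_hist_peaks <- function(counts, mids, prominence = 0.1) {
  if (length(counts) >= 3)
    counts <- stats::filter(counts, rep(1 / 3, 3), sides = 2) |>
      (\(x) { x[is.na(x)] <- counts[is.na(x)]; as.numeric(x) })()
  n <- length(counts)
  if (n == 1L) return(mids[counts > 0])
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1) counts[i - 1] else -Inf
    right <- if (i < n) counts[i + 1] else -Inf
    is_peak[i] <- counts[i] > left && counts[i] >= right &&
      counts[i] >= prominence * max(counts)
  }
  mids[is_peak]
}

#' Classify a spatial code as SSSF, SSMF or MSMF
#'
#' Single-scale single-field (SSSF): at most one field per neuron
#' (median).  Multi-field codes are split by the modality of the
#' population field-size distribution: the histogram (bin width = the
#' environment bin width) is lightly smoothed, local maxima with
#' prominence of at least 10% of the tallest bar are counted, and the
#' code is multi-scale (MSMF) when two peaks at least a factor of two
#' apart in size exist; otherwise single-scale multi-field (SSMF).
#'
#' @param fields A field table from [extract_fields()].
#' @param n_neurons Population size (silent neurons included).
#' @param bin_m Histogram bin width in meters.
#' @return A list with `label`, `peaks` (field sizes at peaks),
#'   per-neuron `field_counts`, and the summary statistics
#'   `median_size_mean` / `median_size_var` (medians over neurons of the
#'   per-neuron field-size mean and variance).
#' @export
classify_code <- function(fields, n_neurons, bin_m = 0.5) {
  if (nrow(fields) == 0L)
    stop("at least one field is required", call. = FALSE)
  counts <- tabulate(fields$neuron, nbins = n_neurons)
  per_mean <- tapply(fields$size_m, fields$neuron, mean)
  per_var <- tapply(fields$size_m, fields$neuron,
                    function(x) if (length(x) > 1) stats::var(x) else 0)
  stats <- list(median_size_mean = stats::median(per_mean),
                median_size_var = stats::median(per_var))
  if (stats::median(counts) <= 1) {
    label <- "SSSF"; peaks <- numeric(0)
  } else {
    breaks <- seq(0, max(fields$size_m) + bin_m, by = bin_m)
    h <- graphics::hist(fields$size_m, breaks = breaks, plot = FALSE)
    peaks <- find_hist_peaks(h$counts, h$mids)
    label <- if (length(peaks) >= 2 &&
                 max(peaks) / max(min(peaks), 1e-12) >= 2)
      "MSMF" else "SSMF"
  }
  c(list(label = label, peaks = peaks, field_counts = counts), stats)
}

#' Diagnostics of field-placement variation
#'
#' Four diagnostics of how a particular random field realization relates
#' to decodability: (a) the fraction of bins whose active-neuron
#' combination in the template is unique; (b) the mean per-step
#' false-positive and false-negative active-neuron counts of the decoded
#' bin's template versus the true bin's; (c) the mean distance from field
#' centers to the nearest bin center; (d) Kullback-Leibler divergences of
#' the realized field-size and field-location histograms from their
#' nominal distributions (gamma sizes / uniform locations where
#' applicable).
#'
#' @param model An `fc_model`.
#' @param templates An `fc_ratemap`.
#' @param decoding An `fc_decoding` from [positional_error()], or `NULL`
#'   to skip the false-positive/negative diagnostic.
#' @param simulation The decoded `fc_simulation` (for true positions).
#' @param theta_field Activity threshold defining "active" neurons.
#' @return A list with `unique_combination_fraction`,
#'   `mean_false_positive`, `mean_false_negative`,
#'   `mean_center_offset_m`, `kl_size`, `kl_location`.
#' @export
variation_diagnostics <- function(model, templates, decoding = NULL,
                                  simulation = NULL, theta_field = 0.2) {
  map <- templates$map
  env <- templates$env
  peaks <- apply(map, 1, max)
  thr <- theta_field * pmax(peaks, .Machine$double.eps)
  active <- map > thr                     # n_neurons x n_bins
  keys <- apply(active, 2, paste, collapse = "")
  uniq_frac <- sum(!(duplicated(keys) | duplicated(keys, fromLast = TRUE))) /
    env$n_bins

  fp <- fn <- NA_real_
  if (!is.null(decoding) && !is.null(simulation)) {
    true_bin <- position_to_bin(env, simulation$positions)
    dec_bin <- decoding$decoded_bin
    fp <- mean(colSums(active[, dec_bin, drop = FALSE] &
                         !active[, true_bin, drop = FALSE]))
    fn <- mean(colSums(!active[, dec_bin, drop = FALSE] &
                         active[, true_bin, drop = FALSE]))
  }

  ctr <- model$fields$center
  v <- (ctr / env$bin_m - 0.5) %% 1     # offset to nearest bin center
  off <- pmin(v, 1 - v) * env$bin_m

  kl <- function(p, q) {
    keep <- p > 0
    sum(p[keep] * log(p[keep] / pmax(q[keep], 1e-12)))
  }
  breaks_loc <- seq(0, env$length_m, length.out = 21)
  p_loc <- graphics::hist(pmin(ctr, env$length_m), breaks = breaks_loc,
                          plot = FALSE)$counts
  p_loc <- p_loc / sum(p_loc)
  kl_location <- kl(p_loc, rep(1 / 20, 20))

  kl_size <- NA_real_
  if (identical(model$family, "DMF")) {
    w <- model$fields$width
    breaks_w <- seq(0, max(w) * 1.001, length.out = 21)
    p_w <- graphics::hist(w, breaks = breaks_w, plot = FALSE)$counts
    p_w <- p_w / sum(p_w)
    q_w <- diff(stats::pgamma(breaks_w, shape = model$params$shape,
                              scale = model$params$scale))
    q_w <- q_w / sum(q_w)
    kl_size <- kl(p_w, q_w)
  }

  list(unique_combination_fraction = uniq_frac,
       mean_false_positive = fp,
       mean_false_negative = fn,
       mean_center_offset_m = if (length(off)) mean(off) else NA_real_,
       kl_size = kl_size,
       kl_location = kl_location)
}

#' Write a rate map to CSV
#'
#' @param templates An `fc_ratemap`.
#' @param path Output CSV path (neurons in rows, bins in columns).
#' @export
write_ratemap <- function(templates, path) {
  stopifnot(inherits(templates, "fc_ratemap"))
  utils::write.table(templates$map, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
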