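## Network construction for the four model families.
##
## A model is a list of class "fc_model":
##   family     "FMF" | "DMF" | "SSSF" | "GRID"
##   n_neurons  total neuron count (silent neurons included)
##   fields     data.frame(neuron, center, width, attractor) -- one row per
##              firing field; width is the length constant of the field's
##              input kernel in meters
##   W          dense symmetric recurrent weight matrix, or NULL when the
##              model has no lateral connections (W identically zero)
##   params     the full generating parameter set
##   env        the fc_environment the model was built for
##   lesioned   indices of dropped-out neurons (empty by default)

new_fc_model <- function(family, n_neurons, fields, W, params, env,
                         lesioned = integer(0), conn = NULL) {
  structure(
    list(family = family, n_neurons = as.integer(n_neurons),
         fields = fields, W = W, params = params, env = env,
         lesioned = lesioned, conn = conn),
    class = "fc_model")
}

empty_fields <- function() {
  data.frame(neuron = integer(0), center = numeric(0), width = numeric(0),
             attractor = character(0), stringsAsFactors = FALSE)
}

#' @export
print.fc_model <- function(x, ...) {
  nf <- n_fields_per_neuron(x)
  cat(sprintf("%s model: %d neurons, %d fields (mean %.2f/neuron)%s%s\n",
              x$family, x$n_neurons, nrow(x$fields), mean(nf),
              if (is.null(x$W)) ", no lateral connections" else
                ", with lateral connections",
              if (length(x$lesioned))
                sprintf(", %d lesioned", length(x$lesioned)) else ""))
  invisible(x)
}

#' Number of firing fields per neuron
#'
#' @param model An `fc_model`.
#' @return Integer vector of length `model$n_neurons`; silent neurons
#'   (no fields) count 0 and remain part of the population.
#' @export
n_fields_per_neuron <- function(model) {
  stopifnot(inherits(model, "fc_model"))
  tabulate(model$fields$neuron, nbins = model$n_neurons)
}

## symmetric excitatory kernel of a line attractor: contributions
## W_exc * exp(-|x_i - x_j| / L_int), accumulated into W[members, members].
add_attractor_kernel <- function(W, members, labels, l_int, w_exc) {
  D <- abs(outer(labels, labels, "-"))
  W[members, members] <- W[members, members] + w_exc * exp(-D / l_int)
  W
}

#' Build a fixed multi-field (F-MF) network
#'
#' Neurons are organized into hierarchical levels of line attractors.
#' Level `i` holds `n_attractors[i]` equal-width attractors that tile the
#' track contiguously; each neuron joins each attractor independently with
#' probability `p_att`.  An attractor's members receive positional labels
#' evenly spaced across its span (bin-centered), assigned in random order;
#' each membership contributes one firing field whose width equals the
#' attractor's interaction length, 5% of its span.  Recurrent weights
#' accumulate the excitatory kernel `w_exc * exp(-|x_i - x_j| / L_int)`
#' over every shared attractor, and a single global inhibition `w_inh` is
#' subtracted once per connected neuron pair.
#'
#' @param env An [make_environment()] object.
#' @param n_attractors Integer vector of attractor counts per level
#'   (default `c(5, 2, 1)`).
#' @param p_att Per-attractor membership probability.
#' @param n_neurons Total neuron pool size.
#' @param w_exc,w_inh Excitatory/inhibitory weight constants; both 0
#'   (the default) builds a model without lateral connections (`W = NULL`).
#' @return An `fc_model`.  Neurons that join no attractor are retained as
#'   silent neurons.
#' @export
build_fmf <- function(env, n_attractors = c(5, 2, 1), p_att = 0.3,
                      n_neurons = 50, w_exc = 0, w_inh = 0) {
  stopifnot(inherits(env, "fc_environment"))
  if (any(n_attractors < 0) || all(n_attractors == 0))
    stop("'n_attractors' must be non-negative with at least one level > 0",
         call. = FALSE)
  if (p_att < 0 || p_att > 1) stop("'p_att' must lie in [0, 1]", call. = FALSE)
  if (n_neurons < 1) stop("'n_neurons' must be >= 1", call. = FALSE)

  lateral <- (w_exc != 0 || w_inh != 0)
  W <- if (lateral) matrix(0, n_neurons, n_neurons) else NULL
  connected <- if (lateral) matrix(FALSE, n_neurons, n_neurons) else NULL

  neuron <- integer(0); center <- numeric(0); width <- numeric(0)
  attractor <- character(0)
  for (lev in seq_along(n_attractors)) {
    n_al <- n_attractors[lev]
    if (n_al == 0) next
    span_len <- env$length_m / n_al
    l_int <- 0.05 * span_len
    for (a in seq_len(n_al)) {
      members <- which(stats::runif(n_neurons) < p_att)
      if (length(members) == 0L) next
      m <- length(members)
      labels <- (a - 1) * span_len + (seq_len(m) - 0.5) * span_len / m
      members <- sample(members)  # random assignment order of labels
      neuron <- c(neuron, members)
      center <- c(center, labels)
      width <- c(width, rep(l_int, m))
      attractor <- c(attractor, rep(sprintf("L%d.A%d", lev - 1L, a), m))
      if (lateral) {
        W <- add_attractor_kernel(W, members, labels, l_int, w_exc)
        connected[members, members] <- TRUE
      }
    }
  }
  if (lateral) W <- W - w_inh * connected
  fields <- data.frame(neuron = neuron, center = center, width = width,
                       attractor = attractor, stringsAsFactors = FALSE)
  new_fc_model("FMF", n_neurons, fields, W,
               params = list(n_attractors = n_attractors, p_att = p_att,
                             n_neurons = n_neurons, w_exc = w_exc,
                             w_inh = w_inh),
               env = env)
}

#' Build a single-scale single-field (SSSF) line attractor
#'
#' One line attractor spans the whole track: each neuron has exactly one
#' field, centers evenly spaced (bin-centered, so neighboring centers are
#' `length_m / n_neurons` apart), and a single shared interaction length
#' of 5% of the track.
#'
#' @inheritParams build_fmf
#' @return An `fc_model`.
#' @export
build_sssf <- function(env, n_neurons = 50, w_exc = 0, w_inh = 0) {
  stopifnot(inherits(env, "fc_environment"))
  if (n_neurons < 1) stop("'n_neurons' must be >= 1", call. = FALSE)
  l_int <- 0.05 * env$length_m
  centers <- (seq_len(n_neurons) - 0.5) * env$length_m / n_neurons
  lateral <- (w_exc != 0 || w_inh != 0)
  W <- NULL
  if (lateral) {
    D <- abs(outer(centers, centers, "-"))
    W <- w_exc * exp(-D / l_int) - w_inh
  }
  fields <- data.frame(neuron = seq_len(n_neurons), center = centers,
                       width = rep(l_int, n_neurons),
                       attractor = rep("L0.A1", n_neurons),
                       stringsAsFactors = FALSE)
  new_fc_model("SSSF", n_neurons, fields, W,
               params = list(n_neurons = n_neurons, w_exc = w_exc,
                             w_inh = w_inh),
               env = env)
}

## field-size similarity gate: two fields connect when the ratio of the
## smaller to the larger size strictly exceeds th_fsr (ties never connect)
dmf_pair_qualifies <- function(fs0, fs1, th_fsr) {
  pmin(fs0, fs1) / pmax(fs0, fs1) > th_fsr
}

## draw gamma field widths for one neuron until the cumulative width first
## reaches sum_fs; the overshooting final field is kept.
draw_dmf_widths <- function(shape, scale, sum_fs) {
  widths <- numeric(0)
  total <- 0
  while (total < sum_fs) {
    k <- max(4L, ceiling((sum_fs - total) / (shape * scale)))
    w <- stats::rgamma(k, shape = shape, scale = scale)
    cs <- total + cumsum(w)
    hit <- which(cs >= sum_fs)
    if (length(hit)) {
      widths <- c(widths, w[seq_len(hit[1])])
      return(widths)
    }
    widths <- c(widths, w)
    total <- cs[k]
  }
  widths
}

#' Build a dynamic multi-field (D-MF) network
#'
#' Per neuron, field widths are drawn i.i.d. from a gamma distribution
#' (shape `shape`, scale `scale`) and centers uniformly on the track;
#' fields are appended until the cumulative width first reaches `sum_fs`
#' (the overshooting field is kept).  Lateral connectivity is gated by
#' field-size similarity: a cross-neuron field pair qualifies when the
#' ratio `min(fs0, fs1) / max(fs0, fs1)` strictly exceeds `th_fsr`
#' (ties do not connect).  Alternatively, `p_fc` connects each
#' cross-neuron field pair independently with that probability,
#' regardless of sizes; exactly one of `th_fsr` / `p_fc` may be given.
#' Each qualifying pair contributes
#' `w_exc * exp(-|c0 - c1| / L_pair)` with
#' `L_pair = 0.05 * (fs0 + fs1) / 2` (the 5% interaction-length rule
#' applied at the field scale), and `w_inh` is subtracted once per neuron
#' pair with at least one qualifying field pair.
#'
#' @inheritParams build_fmf
#' @param shape,scale Gamma shape/scale of field widths (meters).
#' @param sum_fs Target cumulative field width per neuron (meters).
#' @param th_fsr Field-size ratio threshold in `[0, 1]`, or `NULL`.
#' @param p_fc Field connection probability in `[0, 1]`, or `NULL`.
#' @param connectivity Build the connection graph even when
#'   `w_exc = w_inh = 0` (needed to count qualifying pairs); by default
#'   the graph is only built when weights are nonzero.
#' @return An `fc_model`; when the connection graph was built, element
#'   `conn` holds `n_field_pairs`, `n_connected_field_pairs`,
#'   `connection_fraction` and `n_connected_neuron_pairs`.
#' @export
build_dmf <- function(env, shape = 3.16, scale = 1.80, sum_fs = 30,
                      n_neurons = 50, th_fsr = NULL, p_fc = NULL,
                      w_exc = 0, w_inh = 0, connectivity = NULL) {
  stopifnot(inherits(env, "fc_environment"))
  if (!is.null(th_fsr) && !is.null(p_fc))
    stop("supply only one of 'th_fsr' and 'p_fc'", call. = FALSE)
  if (shape <= 0 || scale <= 0 || sum_fs <= 0)
    stop("'shape', 'scale' and 'sum_fs' must be positive", call. = FALSE)
  if (!is.null(th_fsr) && (th_fsr < 0 || th_fsr > 1))
    stop("'th_fsr' must lie in [0, 1]", call. = FALSE)
  if (!is.null(p_fc) && (p_fc < 0 || p_fc > 1))
    stop("'p_fc' must lie in [0, 1]", call. = FALSE)

  lateral <- (w_exc != 0 || w_inh != 0)
  if (is.null(connectivity)) connectivity <- lateral
  if (connectivity && is.null(th_fsr) && is.null(p_fc)) th_fsr <- 0.9

  neuron <- integer(0); center <- numeric(0); width <- numeric(0)
  for (i in seq_len(n_neurons)) {
    w <- draw_dmf_widths(shape, scale, sum_fs)
    neuron <- c(neuron, rep(i, length(w)))
    width <- c(width, w)
    center <- c(center, stats::runif(length(w), 0, env$length_m))
  }
  fields <- data.frame(neuron = neuron, center = center, width = width,
                       attractor = rep(NA_character_, length(neuron)),
                       stringsAsFactors = FALSE)

  W <- NULL; conn <- NULL
  if (connectivity) {
    W <- matrix(0, n_neurons, n_neurons)
    by_neuron <- split(seq_len(nrow(fields)), fields$neuron)
    n_pairs_total <- 0; n_pairs_conn <- 0; n_neuron_conn <- 0
    for (i in seq_len(n_neurons - 1L)) {
      fi <- by_neuron[[as.character(i)]]
      if (is.null(fi)) next
      for (j in seq.int(i + 1L, n_neurons)) {
        fj <- by_neuron[[as.character(j)]]
        if (is.null(fj)) next
        wi <- fields$width[fi]; wj <- fields$width[fj]
        n_pairs_total <- n_pairs_total + length(wi) * length(wj)
        if (!is.null(p_fc)) {
          mask <- matrix(stats::runif(length(wi) * length(wj)) < p_fc,
                         length(wi), length(wj))
        } else {
          mask <- outer(wi, wj, dmf_pair_qualifies, th_fsr = th_fsr)
        }
        if (!any(mask)) next
        n_pairs_conn <- n_pairs_conn + sum(mask)
        n_neuron_conn <- n_neuron_conn + 1L
        l_pair <- 0.05 * outer(wi, wj, "+") / 2
        dist <- abs(outer(fields$center[fi], fields$center[fj], "-"))
        wsum <- sum(w_exc * exp(-dist / l_pair) * mask)
        wij <- wsum - w_inh
        W[i, j] <- wij
        W[j, i] <- wij
      }
    }
    conn <- list(n_field_pairs = n_pairs_total,
                 n_connected_field_pairs = n_pairs_conn,
                 connection_fraction =
                   if (n_pairs_total > 0) n_pairs_conn / n_pairs_total else 0,
                 n_connected_neuron_pairs = n_neuron_conn)
    if (!lateral) W <- NULL
  }
  new_fc_model("DMF", n_neurons, fields, W,
               params = list(shape = shape, scale = scale, sum_fs = sum_fs,
                             n_neurons = n_neurons, th_fsr = th_fsr,
                             p_fc = p_fc, w_exc = w_exc, w_inh = w_inh),
               env = env, conn = conn)
}

#' Build a one-dimensional grid-code network
#'
#' `n_modules` modules of `n_per_module` neurons each.  Module `m`
#' (0-based) has population field spacing
#' `S_m = min_scale * scale_factor^m`; every neuron of the module repeats
#' its fields with period `P_m = S_m * n_per_module` and a phase offset
#' drawn uniformly on `[0, P_m)`, so that the module population jointly
#' tiles the track at spacing `S_m`.  Field width is `w_ratio * S_m`.
#' Grid models carry no lateral connections.
#'
#' @inheritParams build_fmf
#' @param n_modules Number of modules.
#' @param n_per_module Neurons per module.
#' @param scale_factor Multiplicative scale increment between modules.
#' @param min_scale Spacing of the finest module (meters).
#' @param w_ratio Field width as a fraction of the module spacing
#'   (default 1).
#' @return An `fc_model` with `n_modules * n_per_module` neurons.
#' @export
build_grid <- function(env, n_modules = 3, n_per_module = 9,
                       scale_factor = 1.6, min_scale = 0.5, w_ratio = 1) {
  stopifnot(inherits(env, "fc_environment"))
  if (n_modules < 1 || n_per_module < 1)
    stop("'n_modules' and 'n_per_module' must be >= 1", call. = FALSE)
  if (min_scale <= 0 || scale_factor <= 0)
    stop("'min_scale' and 'scale_factor' must be positive", call. = FALSE)
  n_neurons <- n_modules * n_per_module
  neuron <- integer(0); center <- numeric(0); width <- numeric(0)
  attractor <- character(0)
  id <- 0L
  for (m in seq_len(n_modules) - 1L) {
    s_m <- min_scale * scale_factor^m
    period <- s_m * n_per_module
    for (u in seq_len(n_per_module)) {
      id <- id + 1L
      phase <- stats::runif(1, 0, period)
      if (phase > env$length_m) next  # no field on the track
      k_max <- floor((env$length_m - phase) / period)
      pos <- phase + (0:k_max) * period
      neuron <- c(neuron, rep(id, length(pos)))
      center <- c(center, pos)
      width <- c(width, rep(w_ratio * s_m, length(pos)))
      attractor <- c(attractor, rep(sprintf("M%d", m), length(pos)))
    }
  }
  fields <- data.frame(neuron = neuron, center = center, width = width,
                       attractor = attractor, stringsAsFactors = FALSE)
  new_fc_model("GRID", n_neurons, fields, W = NULL,
               params = list(n_modules = n_modules,
                             n_per_module = n_per_module,
                             scale_factor = scale_factor,
                             min_scale = min_scale, w_ratio = w_ratio),
               env = env)
}

#' Expected fields per neuron of a grid model (closed form)
#'
#' With uniform random phases, a neuron of module `m` carries on average
#' `length_m / (n_per_module * min_scale * scale_factor^m)` fields on the
#' track; the population mean averages this over modules.
#'
#' @inheritParams build_grid
#' @return Expected mean number of fields per neuron.
#' @export
grid_expected_fields <- function(env, n_modules, n_per_module, scale_factor,
                                 min_scale) {
  m <- seq_len(n_modules) - 1L
  mean(env$length_m / (n_per_module * min_scale * scale_factor^m))
}

#' Lesion a model by random neuron drop-out
#'
#' Each neuron is independently lesioned with probability `p_dro`.
#' Lesioned neurons lose their fields (hence receive no positional input
#' and emit no activity), their weight rows/columns are zeroed, and their
#' all-zero decoding templates are inert in the population-vector decoder.
#' The population size is unchanged.
#'
#' @param model An `fc_model`.
#' @param p_dro Drop-out probability in `[0, 1]`.
#' @return The lesioned `fc_model` with element `lesioned` listing the
#'   removed neurons.
#' @export
apply_dropout <- function(model, p_dro) {
  stopifnot(inherits(model, "fc_model"))
  if (p_dro < 0 || p_dro > 1)
    stop("'p_dro' must lie in [0, 1]", call. = FALSE)
  if (p_dro == 0) return(model)
  lesioned <- which(stats::runif(model$n_neurons) < p_dro)
  if (length(lesioned) == 0L) return(model)
  model$fields <- model$fields[!(model$fields$neuron %in% lesioned), ,
                               drop = FALSE]
  if (!is.null(model$W)) {
    model$W[lesioned, ] <- 0
    model$W[, lesioned] <- 0
  }
  model$lesioned <- sort(unique(c(model$lesioned, lesioned)))
  model
}

#' Write a model to a plain-text archive
#'
#' The fields table is written as `<stem>_fields.csv`
#' (neuron, center, width, attractor), the recurrent weight matrix (if
#' any) as a dense CSV `<stem>_weights.csv`, and the generating
#' parameters as `<stem>_params.json`.
#'
#' @param model An `fc_model`.
#' @param stem Output path stem (directory must exist).
#' @return Invisibly, the paths written.
#' @export
write_model <- function(model, stem) {
  stopifnot(inherits(model, "fc_model"))
  paths <- character(0)
  fp <- paste0(stem, "_fields.csv")
  utils::write.csv(model$fields, fp, row.names = FALSE)
  paths <- fp
  if (!is.null(model$W)) {
    wp <- paste0(stem, "_weights.csv")
    utils::write.table(model$W, wp, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, wp)
  }
  pp <- paste0(stem, "_params.json")
  jsonlite::write_json(
    c(list(family = model$family, n_neurons = model$n_neurons,
           lesioned = model$lesioned),
      model$params),
    pp, auto_unbox = TRUE, null = "null")
  invisible(c(paths, pp))
}
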