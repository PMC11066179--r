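test_that("F-MF membership and field counts follow the attractor design", {
  env <- std_env()

  # full membership of a single attractor: one field each, evenly spaced
  set.seed(1)
  m <- build_fmf(env, n_attractors = c(1, 0, 0), p_att = 1, n_neurons = 4)
  expect_equal(n_fields_per_neuron(m), rep(1L, 4))
  expect_equal(sort(m$fields$center), c(25, 75, 125, 175))
  expect_equal(unique(m$fields$width), 0.05 * 200)

  # with full membership the field count is exactly the attractor total
  set.seed(2)
  m <- build_fmf(env, c(5, 2, 1), p_att = 1, n_neurons = 10)
  expect_equal(n_fields_per_neuron(m), rep(8L, 10))

  # empty membership: silent population, no lateral connections
  set.seed(3)
  m <- build_fmf(env, c(5, 2, 1), p_att = 0, n_neurons = 10,
                 w_exc = 0.2, w_inh = 0.05)
  expect_equal(nrow(m$fields), 0L)
  expect_true(all(m$W == 0))

  # field widths are 5% of the level's attractor span
  set.seed(4)
  m <- build_fmf(env, c(5, 2, 1), p_att = 1, n_neurons = 5)
  expect_setequal(unique(m$fields$width), 0.05 * c(40, 100, 200))
})

test_that("the original F-MF parameters give ~2.4 fields per neuron", {
  env <- std_env()
  med <- median(vapply(1:20, function(r) {
    set.seed(r)
    mean(n_fields_per_neuron(build_fmf(env, c(5, 2, 1), 0.30, 50)))
  }, numeric(1)))
  expect_equal(med, 2.4, tolerance = 0.15)
})

test_that("SSSF places evenly spaced single fields and a full kernel", {
  env <- std_env()
  m <- build_sssf(env, n_neurons = 50)
  expect_equal(n_fields_per_neuron(m), rep(1L, 50))
  expect_equal(unique(diff(sort(m$fields$center))), 4)
  expect_null(m$W)

  # single neuron with lateral connections: self-kernel at distance 0
  m1 <- build_sssf(env, n_neurons = 1, w_exc = 0.3, w_inh = 0.1)
  expect_equal(m1$W, matrix(0.3 - 0.1, 1, 1))
})

test_that("D-MF field widths accumulate to the coverage threshold", {
  env <- std_env()
  set.seed(5)
  m <- build_dmf(env, shape = 3.16, scale = 1.80, sum_fs = 30,
                 n_neurons = 30)
  for (i in seq_len(30)) {
    w <- m$fields$width[m$fields$neuron == i]
    expect_gte(sum(w), 30)
    expect_lt(sum(w) - w[length(w)], 30)  # dropping the last field undershoots
  }
  expect_true(all(m$fields$center >= 0 & m$fields$center <= 200))
  expect_error(build_dmf(env, th_fsr = 0.9, p_fc = 0.5), "only one")
})

test_that("sampled D-MF widths match the gamma mean", {
  set.seed(6)
  draws <- rgamma(1e5, shape = 3.16, scale = 1.80)
  expect_equal(mean(draws), 3.16 * 1.80, tolerance = 0.01)
  env <- std_env()
  set.seed(7)
  m <- build_dmf(env, 3.16, 1.80, sum_fs = 3000, n_neurons = 20)
  expect_equal(mean(m$fields$width), 5.688, tolerance = 0.05)
})

test_that("the field-size ratio gate is strict", {
  expect_false(fieldcode:::dmf_pair_qualifies(4, 5, 0.9))    # 0.8  < 0.9
  expect_true(fieldcode:::dmf_pair_qualifies(9.5, 10, 0.9))  # 0.95 > 0.9
  expect_false(fieldcode:::dmf_pair_qualifies(9, 10, 0.9))   # tie: no edge
  expect_true(fieldcode:::dmf_pair_qualifies(7, 7, 0.99))
})

test_that("threshold 0 and p_fc = 1 connect every cross-neuron field pair", {
  env <- small_env()
  set.seed(8)
  m_th <- build_dmf(env, 2, 1, sum_fs = 4, n_neurons = 8, th_fsr = 0,
                    connectivity = TRUE)
  set.seed(8)
  m_p <- build_dmf(env, 2, 1, sum_fs = 4, n_neurons = 8, p_fc = 1,
                   connectivity = TRUE)
  expect_equal(m_th$conn$connection_fraction, 1)
  expect_equal(m_p$conn$connection_fraction, 1)
  expect_equal(m_th$conn$n_field_pairs, m_p$conn$n_field_pairs)
})

test_that("grid modules tile the track at geometric scales", {
  env <- std_env()
  set.seed(9)
  m <- build_grid(env, n_modules = 3, n_per_module = 9,
                  scale_factor = 1.6, min_scale = 0.5)
  expect_equal(m$n_neurons, 27L)
  expect_null(m$W)
  # per-neuron fields are periodic with the module period
  for (i in unique(m$fields$neuron)) {
    ctr <- sort(m$fields$center[m$fields$neuron == i])
    mod <- m$fields$attractor[m$fields$neuron == i][1]
    s <- 0.5 * 1.6^as.integer(sub("M", "", mod))
    if (length(ctr) > 1)
      expect_equal(unique(round(diff(ctr), 9)), s * 9)
    expect_equal(unique(m$fields$width[m$fields$neuron == i]), s)
  }
})

test_that("grid field counts match closed form and per-realization oracle", {
  env <- std_env()
  cases <- list(c(3, 9, 1.6, 0.5), c(9, 19, 3.0, 0.5), c(3, 19, 1.8, 0.5))
  for (cs in cases) {
    expected <- grid_expected_fields(env, cs[1], cs[2], cs[3], cs[4])
    means <- vapply(1:30, function(r) {
      set.seed(r)
      m <- build_grid(env, cs[1], cs[2], cs[3], cs[4])
      counts <- n_fields_per_neuron(m)
      # oracle: recover each neuron's phase and count fields in closed form
      for (i in which(counts > 0)) {
        ctr <- m$fields$center[m$fields$neuron == i]
        mod <- as.integer(sub("M", "", m$fields$attractor[
          m$fields$neuron == i][1]))
        period <- cs[4] * cs[3]^mod * cs[2]
        phase <- min(ctr)
        expect_identical(counts[i],
                         as.integer(floor((env$length_m - phase) / period)) + 1L)
      }
      mean(counts)
    }, numeric(1))
    expect_equal(mean(means), expected, tolerance = 0.02)
  }
})

test_that("recurrent weight matrices are symmetric for every builder", {
  env <- std_env()
  for (seed in 1:3) {
    set.seed(seed)
    builders <- list(
      build_fmf(env, c(5, 2, 1), 0.5, 20, w_exc = 0.2, w_inh = 0.05),
      build_dmf(env, 3.16, 1.8, 30, 15, th_fsr = 0.9,
                w_exc = 0.2, w_inh = 0.05),
      build_sssf(env, 20, w_exc = 0.2, w_inh = 0.05))
    for (m in builders)
      expect_identical(max(abs(m$W - t(m$W))), 0)
  }
})

test_that("drop-out lesions silence neurons but keep the population", {
  env <- std_env()
  set.seed(10)
  m <- build_sssf(env, 50, w_exc = 0.2, w_inh = 0.05)

  expect_identical(apply_dropout(m, 0), m)

  set.seed(11)
  full <- apply_dropout(m, 1)
  expect_equal(nrow(full$fields), 0L)
  expect_equal(full$n_neurons, 50L)
  expect_true(all(full$W == 0))

  # all-silent population: decoder falls back to the first bin, and the
  # error is the mean distance of the trajectory to that bin's center
  traj <- make_trajectory(env)
  sim <- simulate_network(full, traj)
  tmpl <- build_templates(full, env, simulation = sim)
  dec <- positional_error(sim, tmpl)
  expect_true(all(dec$decoded_bin == 1L))
  expect_equal(dec$e_pos_mean, mean(abs(traj$positions - 0.25)))

  # surviving count lies in the binomial 99% interval
  set.seed(12)
  big <- fieldcode:::new_fc_model("SSSF", 1000L,
    data.frame(neuron = 1:1000, center = runif(1000, 0, 200),
               width = 1, attractor = NA_character_),
    NULL, list(), env)
  les <- apply_dropout(big, 0.5)
  surviving <- 1000 - length(les$lesioned)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(surviving, ci[1])
  expect_lte(surviving, ci[2])
})

test_that("models serialize to a plain-text archive", {
  env <- small_env()
  set.seed(13)
  m <- build_sssf(env, 5, w_exc = 0.2, w_inh = 0.05)
  stem <- file.path(withr::local_tempdir(), "model")
  paths <- write_model(m, stem)
  expect_true(all(file.exists(paths)))
  fields <- read.csv(paste0(stem, "_fields.csv"))
  expect_equal(fields$center, m$fields$center)
  W <- as.matrix(read.csv(paste0(stem, "_weights.csv"), header = FALSE))
  expect_equal(unname(W), m$W, tolerance = 1e-12)
})
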