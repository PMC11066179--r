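test_that("bundled presets reproduce the published parameter tables", {
  expected <- list(
    "F-Opt-1" = list(n_al_0 = 50, n_al_1 = 48, n_al_2 = 50, p_att = 0.95,
                     n_neurons = 50),
    "F-Opt-2" = list(n_al_0 = 50, n_al_1 = 22, n_al_2 = 40, p_att = 0.40,
                     n_neurons = 50),
    "F-Opt-3" = list(n_al_0 = 11, n_al_1 = 10, n_al_2 = 9, p_att = 0.40,
                     n_neurons = 50),
    "F-Org-1" = list(n_al_0 = 5, n_al_1 = 2, n_al_2 = 1, p_att = 0.30,
                     n_neurons = 4000),
    "F-Org-2" = list(n_al_0 = 5, n_al_1 = 2, n_al_2 = 1, p_att = 0.30,
                     n_neurons = 50),
    "D-Opt-1" = list(shape = 15.92, scale = 0.02, sum_fs = 36,
                     n_neurons = 50),
    "D-Org-1" = list(shape = 3.16, scale = 1.80, sum_fs = 30,
                     n_neurons = 50),
    "G-Opt-1" = list(n_modules = 3, n_per_module = 9, scale_factor = 1.6,
                     min_scale = 0.5),
    "G-Opt-2" = list(n_modules = 9, n_per_module = 19, scale_factor = 3.0,
                     min_scale = 0.5),
    "G-Opt-3" = list(n_modules = 9, n_per_module = 7, scale_factor = 3.0,
                     min_scale = 0.5),
    "G-Opt-4" = list(n_modules = 3, n_per_module = 19, scale_factor = 1.2,
                     min_scale = 0.5),
    "G-Opt-5" = list(n_modules = 3, n_per_module = 19, scale_factor = 1.8,
                     min_scale = 0.5))
  expect_true(all(names(expected) %in% list_presets()))
  for (nm in names(expected)) {
    p <- get_preset(nm)
    for (key in names(expected[[nm]]))
      expect_equal(p$params[[key]], expected[[nm]][[key]],
                   info = paste(nm, key))
  }
  expect_error(get_preset("no-such-model"), "unknown preset")
})

test_that("preset models build for every family and lateral mode", {
  env <- std_env()
  set.seed(1)
  g <- build_preset_model("G-Opt-1", env)
  expect_equal(g$family, "GRID")
  expect_equal(g$n_neurons, 27L)
  expect_null(g$W)

  set.seed(1)
  f <- build_preset_model("F-Org-2", env, lateral = TRUE)
  expect_false(is.null(f$W))
  expect_identical(max(abs(f$W - t(f$W))), 0)
  set.seed(1)
  f0 <- build_preset_model("F-Org-2", env, lateral = FALSE,
                           w_exc = 0.9, w_inh = 0.9)
  expect_null(f0$W)     # 'lateral' is authoritative over overrides

  set.seed(1)
  d <- build_preset_model("D-Org-1", env)
  expect_equal(d$family, "DMF")
})

test_that("batch evaluation is reproducible and run-indexed", {
  env <- std_env()
  b <- function() build_preset_model("G-Opt-1", env)
  r1 <- evaluate_batch(b, env, n_runs = 3, base_seed = 42)
  r2 <- evaluate_batch(b, env, n_runs = 3, base_seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$seed, 42:44)

  # a single run's summary equals that run
  s <- summarize_results(cbind(r1[1, ], preset = "G-Opt-1"))
  expect_equal(s$e_pos_median, r1$e_pos_mean[1])
  expect_equal(s$e_pos_min, s$e_pos_max)
})

test_that("baseline ablation covers the four lateral/background cells", {
  env <- std_env()
  res <- run_baseline("F-Org-2", env, n_runs = 2, base_seed = 1)
  expect_equal(nrow(res), 8L)
  expect_equal(sort(unique(paste(res$lateral, res$background))),
               c("FALSE FALSE", "FALSE TRUE", "TRUE FALSE", "TRUE TRUE"))
  # background input degrades the noiseless decoding
  s <- summarize_results(res)
  quiet <- s$e_pos_median[!s$lateral & !s$background]
  noisy <- s$e_pos_median[!s$lateral & s$background]
  expect_gt(noisy, quiet)
})

test_that("the dropout sweep rebuilds templates from the lesioned model", {
  env <- std_env()
  sw <- run_dropout_sweep("F-Opt-3", env, p_dro_grid = c(0, 0.5),
                          n_runs = 3, base_seed = 7)
  base <- evaluate_batch(function() build_preset_model("F-Opt-3", env),
                         env, n_runs = 3, base_seed = 7)
  # the p_dro = 0 point is the identity lesion
  expect_equal(sw$e_pos_mean[sw$p_dro == 0], base$e_pos_mean)
  expect_gte(median(sw$e_pos_mean[sw$p_dro == 0.5]),
             median(sw$e_pos_mean[sw$p_dro == 0]))
})

test_that("matched connection probability reproduces the gated density", {
  env <- std_env()
  p <- get_preset("D-Org-1")$params
  set.seed(11)
  gated <- build_dmf(env, p$shape, p$scale, p$sum_fs, p$n_neurons,
                     th_fsr = 0.9, connectivity = TRUE)
  p_fc <- gated$conn$connection_fraction
  set.seed(12)
  random <- build_dmf(env, p$shape, p$scale, p$sum_fs, p$n_neurons,
                      p_fc = p_fc, connectivity = TRUE)
  # connection count within the binomial 99% interval of the matched rate
  n <- random$conn$n_field_pairs
  ci <- qbinom(c(0.005, 0.995), n, p_fc)
  expect_gte(random$conn$n_connected_field_pairs, ci[1])
  expect_lte(random$conn$n_connected_field_pairs, ci[2])

  cm <- run_connection_mode("D-Org-1", env, n_runs = 2, n_calibration = 2,
                            base_seed = 1)
  expect_equal(sort(unique(cm$results$mode)), c("p_fc", "th_fsr"))
  expect_true(cm$p_fc_matched > 0 && cm$p_fc_matched < 1)
  expect_error(run_connection_mode("G-Opt-1", env), "D-MF")
})

test_that("lateral inhibition sharpens fields; zero weights change nothing", {
  env <- std_env()
  sh0 <- run_sharpening("S-Std-1", env, seed = 3, w_exc = 0, w_inh = 0)
  expect_identical(sh0$maps_off, sh0$maps_on)
  expect_equal(sh0$out_of_field_fraction_off, sh0$out_of_field_fraction_on)

  # purely inhibitory connections cannot raise out-of-field activity
  sh <- run_sharpening("S-Std-1", env, seed = 3, w_exc = 0, w_inh = 0.02)
  expect_lte(sh$out_of_field_fraction_on, sh$out_of_field_fraction_off)
  expect_true(all(sh$maps_on <= sh$maps_off + 1e-12))
})

test_that("the command-line interface writes a result table", {
  cli <- system.file("cli", "fieldcode.R", package = "fieldcode")
  expect_true(file.exists(cli))
  out_dir <- withr::local_tempdir()
  status <- system2("Rscript",
                    c(cli, "experiment", "baseline", "--preset", "G-Opt-1",
                      "--runs", "1", "--seed", "1", "--out", out_dir),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  csv <- file.path(out_dir, "baseline_G-Opt-1.csv")
  expect_true(file.exists(csv))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  res <- read.csv(csv)
  expect_true(all(c("e_pos_mean", "lateral", "background") %in% names(res)))
  # unknown preset: usage error with nonzero exit
  bad <- system2("Rscript", c(cli, "experiment", "baseline", "--preset",
                              "nope", "--out", out_dir),
                 stdout = FALSE, stderr = FALSE)
  expect_gt(bad, 0L)
})
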