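# Experiment drivers: reproducibility, manifests and scaled-down smokes.
# Full-scale population claims live in test-acceptance.R.

tiny_cfg <- function(steps = 60) {
  train_config(steps = steps, eval_every = Inf, batch_size = 32, probe_n = 80)
}

test_that("sweeps are reproducible end-to-end from config + seed", {
  s1 <- run_sweep(alphas = 0, n_models = 1, config = tiny_cfg(),
                  n_ranks = 128, probe_n = 80, seed = 3)
  s2 <- run_sweep(alphas = 0, n_models = 1, config = tiny_cfg(),
                  n_ranks = 128, probe_n = 80, seed = 3)
  expect_identical(s1$metrics, s2$metrics)
  expect_equal(sum(s1$class_shares$share), 1)
  expect_setequal(s1$class_shares$learner_class,
                  c("in_context", "in_weights", "double", "neither"))
})

test_that("run directories carry a manifest before any table", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "run1")
  run_sweep(alphas = 0, n_models = 1, config = tiny_cfg(), n_ranks = 128,
            probe_n = 80, seed = 4, out_dir = out)
  expect_true(file.exists(file.path(out, "config.yaml")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "metrics.csv")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_true(all(c("config_hash", "seed", "package_version", "r_version",
                    "timestamp", "wall_clock_s") %in% names(man)))
  # manifest written no later than the tables
  expect_lte(file.mtime(file.path(out, "manifest.json")),
             file.mtime(file.path(out, "metrics.csv")))
  cfg <- yaml::read_yaml(file.path(out, "config.yaml"))
  expect_equal(cfg$experiment, "sweep")
})

test_that("composite at P_c = 1 reduces to the uniform distribution", {
  expect_equal(zipflearn:::dist_pmf(composite_spec(1, 2, 2^14)),
               zipflearn:::dist_pmf(zipf_spec(0, 2^14)))
})

test_that("curriculum driver pairs conditions over shared seeds", {
  cr <- run_curriculum(curricula = "C2", alpha_s = 2, n_models = 2,
                       include_static = TRUE,
                       config = train_config(steps = 100, eval_every = 50,
                                             batch_size = 32, probe_n = 60),
                       n_ranks = 128, probe_n = 60, seed = 9)
  expect_setequal(unique(cr$metrics$condition), c("C2", "static"))
  expect_equal(nrow(cr$metrics), 4)
  expect_true(!is.null(cr$trajectories))
  expect_true(all(c("step", "acc_ic", "acc_iw", "condition") %in%
                    names(cr$trajectories)))
  g <- glance(cr)
  expect_true(all(c("condition", "mean_dli") %in% names(g)))
})

test_that("the transitive driver reports the binary-symbol metric suite", {
  tr <- run_transitive(alphas = 0, n_models = 1, n_envs = 64,
                       config = train_config(steps = 40, eval_every = Inf,
                                             batch_size = 16, probe_n = 50),
                       probe_n = 50, seed = 5)
  expect_equal(nrow(tr$metrics), 1)
  expect_equal(tr$metrics$chance, 0.5)
  expect_true(all(c("acc_ic", "acc_iw", "arb_p_ic", "arb_p_iw", "dli",
                    "learner_class") %in% names(tr$metrics)))
})

test_that("autoplot methods return ggplot objects", {
  fit <- smoke_fit(alpha = 0, steps = 100, K = 128, seed = 15,
                   eval_every = 50, probe_n = 50)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  sw <- run_sweep(alphas = 0, n_models = 1, config = tiny_cfg(), n_ranks = 128,
                  probe_n = 50, seed = 7)
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
  expect_s3_class(plot_distribution(zipf_spec(2, 150)), "ggplot")
})
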