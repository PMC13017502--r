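# End-to-end experiment drivers: the alpha sweep, the composite
# distribution, the curricula and the transitive-inference variant. Every
# driver can emit a run directory (config.yaml + manifest.json + CSV
# tables); the manifest is always written before any table.

.emit_run <- function(out_dir, config, tables, seed, t0) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    package = "zipflearn",
    package_version = as.character(utils::packageVersion("zipflearn")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  invisible(out_dir)
}

#' Share of learner classes in a population table
#'
#' @param metrics a metrics tibble with a `learner_class` column.
#' @return a tibble of class counts and shares (all four classes reported).
#' @export
summarise_classes <- function(metrics) {
  classes <- c("in_context", "in_weights", "double", "neither")
  counts <- vapply(classes, function(cl) sum(metrics$learner_class == cl), numeric(1))
  tibble(learner_class = classes, n = counts, share = counts / nrow(metrics))
}

#' Sweep the Zipfian exponent
#'
#' Trains `n_models` independent replicates per `alpha` and evaluates each
#' on the three probe types, pooling the population into one metrics table
#' with learner classes.
#'
#' @param alphas Zipf exponents to sweep.
#' @param n_models replicates per exponent (scaled default 10; the
#'   population-scale study used 30).
#' @param spec model specification.
#' @param config training configuration.
#' @param n_ranks Zipf support (and vocabulary size), default `2^14`.
#' @param probe_n probe trials per block for the final evaluation.
#' @param seed master seed.
#' @param out_dir optional run directory for config/manifest/CSV emission.
#' @param layout token layout.
#' @return an object of class `"icw_sweep"`: `metrics` (one row per model)
#'   and `class_shares`.
#' @export
run_sweep <- function(alphas = c(0, 1, 2, 4), n_models = 10,
                      spec = model_spec(), config = train_config(eval_every = Inf),
                      n_ranks = 2^14, probe_n = NULL, seed = 1, out_dir = NULL,
                      layout = "pair_adjacent") {
  if (length(alphas) == 0) abort("`alphas` is empty", class = "zipflearn_argument_error")
  t0 <- Sys.time()
  rows <- list()
  for (a in alphas) {
    pop <- run_replicates(spec, zipf_spec(a, n_ranks), config, n_models = n_models,
                          seed = derive_seed(seed, "sweep-alpha", round(1000 * a)),
                          probe_n = probe_n, layout = layout)
    rows[[length(rows) + 1L]] <- dplyr::mutate(pop$metrics, alpha = a, .before = 1)
  }
  metrics <- dplyr::bind_rows(rows)
  out <- structure(list(metrics = metrics, class_shares = summarise_classes(metrics),
                        alphas = alphas, n_models = n_models, seed = seed),
                   class = "icw_sweep")
  .emit_run(out_dir,
            list(experiment = "sweep", alphas = alphas, n_models = n_models,
                 steps = config$steps, batch_size = config$batch_size,
                 learning_rate = config$learning_rate, n_ranks = n_ranks,
                 seed = seed),
            list(metrics = metrics, class_shares = out$class_shares), seed, t0)
  out
}

#' @export
print.icw_sweep <- function(x, ...) {
  cat(sprintf("<icw_sweep> alphas {%s}, %d model(s) each\n",
              paste(x$alphas, collapse = ", "), x$n_models))
  print(x$class_shares)
  invisible(x)
}

#' Train a population on a composite distribution
#'
#' @param p_uniform mixing fraction of the uniform component.
#' @param alpha_s exponent of the skewed component.
#' @inheritParams run_sweep
#' @return an `"icw_sweep"`-like object with per-model double-learning
#'   indices and the double-learner share.
#' @export
run_composite <- function(p_uniform = 0.5, alpha_s = 2, n_models = 10,
                          spec = model_spec(), config = train_config(eval_every = Inf),
                          n_ranks = 2^14, probe_n = NULL, seed = 1, out_dir = NULL,
                          layout = "pair_adjacent") {
  t0 <- Sys.time()
  dist <- composite_spec(p_uniform, alpha_s, n_ranks)
  pop <- run_replicates(spec, dist, config, n_models = n_models,
                        seed = derive_seed(seed, "composite"), probe_n = probe_n,
                        layout = layout)
  metrics <- dplyr::mutate(pop$metrics, p_uniform = p_uniform, alpha_s = alpha_s,
                           .before = 1)
  out <- structure(list(metrics = metrics, class_shares = summarise_classes(metrics),
                        p_uniform = p_uniform, alpha_s = alpha_s,
                        n_models = n_models, seed = seed),
                   class = c("icw_composite", "icw_sweep"))
  .emit_run(out_dir,
            list(experiment = "composite", p_uniform = p_uniform, alpha_s = alpha_s,
                 n_models = n_models, steps = config$steps, n_ranks = n_ranks,
                 seed = seed),
            list(metrics = metrics, class_shares = out$class_shares), seed, t0)
  out
}

#' Train populations on curricula (and a static composite control)
#'
#' Each curriculum phases the uniform and skewed components of a composite
#' distribution over training instead of interleaving them; the static
#' control draws from the composite mixture throughout. Per-checkpoint
#' trajectories are recorded so the strategy hand-off (and its forgetting)
#' is visible across training.
#'
#' @param curricula curriculum names (see [curriculum_spec()]).
#' @param alpha_s skewed-phase exponent.
#' @param include_static also run the static composite control at
#'   `P_c = 0.5` with the same seeds.
#' @inheritParams run_sweep
#' @return a list with `metrics` (final evaluation incl. `dli` per model)
#'   and `trajectories` (checkpoint metrics per model).
#' @export
run_curriculum <- function(curricula = c("C1", "C2"), alpha_s = 2, n_models = 5,
                           include_static = TRUE, spec = model_spec(),
                           config = train_config(), n_ranks = 2^14,
                           probe_n = NULL, seed = 1, out_dir = NULL,
                           layout = "pair_adjacent") {
  t0 <- Sys.time()
  probe_n <- probe_n %||% config$probe_n
  conds <- curricula
  if (include_static) conds <- c(conds, "static")
  metrics <- list(); traj <- list()
  for (cond in conds) {
    dist <- if (cond == "static") {
      composite_spec(0.5, alpha_s, n_ranks)
    } else {
      curriculum_spec(cond, alpha_s = alpha_s, n_ranks = n_ranks,
                      total_steps = config$steps)
    }
    for (i in seq_len(n_models)) {
      fit <- train_model(spec, dist, config,
                         seed = derive_seed(seed, "curriculum", i), layout = layout)
      ev <- evaluate_model(fit, probe_n = probe_n)
      metrics[[length(metrics) + 1L]] <-
        dplyr::bind_cols(tibble(condition = cond, alpha_s = alpha_s, model = i), ev)
      if (!is.null(fit$history)) {
        traj[[length(traj) + 1L]] <-
          dplyr::mutate(fit$history, condition = cond, model = i, .before = 1)
      }
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  trajectories <- if (length(traj)) dplyr::bind_rows(traj) else NULL
  out <- structure(list(metrics = metrics, trajectories = trajectories,
                        curricula = curricula, alpha_s = alpha_s, seed = seed),
                   class = "icw_curriculum")
  .emit_run(out_dir,
            list(experiment = "curriculum", curricula = curricula,
                 alpha_s = alpha_s, n_models = n_models, steps = config$steps,
                 n_ranks = n_ranks, seed = seed),
            c(list(metrics = metrics),
              if (!is.null(trajectories)) list(trajectories = trajectories)),
            seed, t0)
  out
}

#' @export
print.icw_curriculum <- function(x, ...) {
  cat("<icw_curriculum>\n")
  print(dplyr::summarise(dplyr::group_by(x$metrics, .data$condition),
                         mean_dli = mean(.data$dli), .groups = "drop"))
  invisible(x)
}

#' Sweep the transitive-inference task
#'
#' Same metric suite as the main task, over ranked-environment contexts
#' with two relation symbols (chance 0.5; the learner-class threshold sits
#' midway between chance and 1).
#'
#' @param alphas Zipf exponents over environment frequency.
#' @param n_envs number of training environments.
#' @inheritParams run_sweep
#' @return an `"icw_sweep"` object.
#' @export
run_transitive <- function(alphas = c(0, 4), n_models = 3, n_envs = 1000,
                           spec = NULL, config = train_config(eval_every = Inf),
                           probe_n = NULL, seed = 1, out_dir = NULL) {
  t0 <- Sys.time()
  probe_n <- probe_n %||% config$probe_n
  rows <- list()
  for (a in alphas) {
    for (i in seq_len(n_models)) {
      mseed <- derive_seed(seed, sprintf("ti-a%s", format(a)), i)
      task <- ti_task(n_envs = n_envs, alpha = a, seed = derive_seed(mseed, "task"))
      sp <- spec %||% model_spec(n_outputs = 2, d_in = task$d_in, seq_len = task$seq_len)
      fit <- train_model(sp, task = task, config = config, seed = mseed)
      ev <- evaluate_model(fit, probe_n = probe_n, threshold = 0.75)
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble(alpha = a, model = i, seed = mseed), ev)
    }
  }
  metrics <- dplyr::bind_rows(rows)
  out <- structure(list(metrics = metrics, class_shares = summarise_classes(metrics),
                        alphas = alphas, n_models = n_models, seed = seed),
                   class = c("icw_transitive", "icw_sweep"))
  .emit_run(out_dir,
            list(experiment = "transitive", alphas = alphas, n_models = n_models,
                 n_envs = n_envs, steps = config$steps, seed = seed),
            list(metrics = metrics, class_shares = out$class_shares), seed, t0)
  out
}
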