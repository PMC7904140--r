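#' Experiment configuration
#'
#' Bundles everything needed to reproduce a run: model parameters, the kind
#' of experiment, its stopping condition, replicate count and seed. Defaults
#' are the package's concrete worked example (`a0 = a1 = 1`,
#' `lambda0 = 0.02`, `lambda1 = 0.04`, `u1 = 1e-6`, `nu = 1e-4`).
#' Configurations round-trip losslessly through YAML via [save_config()] /
#' [load_config()]. Seeds are mandatory for stochastic experiments — there
#' is no silent clock seeding.
#'
#' @param experiment one of `"exact"`, `"hybrid"`, `"random_fitness"`,
#'   `"driver_frequency"`, `"pd"`.
#' @param params a [two_type_params()] object.
#' @param fit a [fitness_distribution()] object (used by `random_fitness`).
#' @param t_end,n_end stopping conditions (time / population size).
#' @param M_target total size at observation for `driver_frequency`.
#' @param n_runs replicate count.
#' @param seed integer RNG seed.
#' @param f_min smallest materialized frequency for hybrid runs.
#' @param v0_mode `"sampled"` or `"mean"`.
#' @param alpha,n_atoms Poisson-Dirichlet settings for `experiment = "pd"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment = c("hybrid", "exact", "random_fitness",
                                      "driver_frequency", "pd"),
                       params = two_type_params(),
                       fit = fitness_distribution(),
                       t_end = NULL, n_end = NULL, M_target = NULL,
                       n_runs = 1L, seed = 1L, f_min = 0.001,
                       v0_mode = c("sampled", "mean"),
                       alpha = params$alpha, n_atoms = 100L) {
  experiment <- match.arg(experiment)
  v0_mode <- match.arg(v0_mode)
  stopifnot(inherits(params, "two_type_params"),
            inherits(fit, "fitness_distribution"))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("a finite numeric seed is required", call. = FALSE)
  }
  structure(
    list(experiment = experiment, params = params, fit = fit,
         t_end = t_end, n_end = n_end, M_target = M_target,
         n_runs = as.integer(n_runs), seed = as.integer(seed),
         f_min = f_min, v0_mode = v0_mode, alpha = alpha,
         n_atoms = as.integer(n_atoms)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: experiment = %s, n_runs = %d, seed = %d\n",
              x$experiment, x$n_runs, x$seed))
  print(x$params)
  invisible(x)
}

config_keys <- c("experiment", "params", "fit", "t_end", "n_end", "M_target",
                 "n_runs", "seed", "f_min", "v0_mode", "alpha", "n_atoms")
param_keys <- c("a0", "b0", "a1", "b1", "u1", "nu")

#' Save / load a run configuration as YAML
#'
#' The file stores primary quantities only (rates, not derived `lambda`s);
#' loading re-validates every invariant, so e.g. a file with
#' `lambda1 <= lambda0` is rejected with the field names in the message.
#' Unknown keys are rejected rather than ignored.
#'
#' @param config a [run_config()] object.
#' @param path file path.
#' @return `load_config` returns a validated `run_config`; `save_config`
#'   returns `path` invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- list(
    experiment = config$experiment,
    params = as.list(config$params[param_keys]),
    fit = list(m = config$fit$m, d = config$fit$d),
    t_end = config$t_end, n_end = config$n_end, M_target = config$M_target,
    n_runs = config$n_runs, seed = config$seed, f_min = config$f_min,
    v0_mode = config$v0_mode, alpha = config$alpha, n_atoms = config$n_atoms
  )
  obj <- obj[!vapply(obj, is.null, logical(1))]
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  unknown <- setdiff(names(obj), config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(obj$params)) {
    unknown_p <- setdiff(names(obj$params), param_keys)
    if (length(unknown_p) > 0) {
      stop("unknown params key(s): ", paste(unknown_p, collapse = ", "),
           call. = FALSE)
    }
  }
  params <- do.call(two_type_params, obj$params %||% list())
  fit <- do.call(fitness_distribution, obj$fit %||% list())
  run_config(experiment = obj$experiment %||% "hybrid", params = params,
             fit = fit, t_end = obj$t_end, n_end = obj$n_end,
             M_target = obj$M_target, n_runs = obj$n_runs %||% 1L,
             seed = obj$seed %||% 1L, f_min = obj$f_min %||% 0.001,
             v0_mode = obj$v0_mode %||% "sampled",
             alpha = obj$alpha %||% params$alpha,
             n_atoms = obj$n_atoms %||% 100L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate small seeded fixture datasets
#'
#' Writes the tab-separated fixtures used by the test suite (and available
#' for demos): regeneration with the same seed is byte-identical.
#'
#' * `small_exact` — one exact-simulator history (a few thousand cells):
#'   `mutations.tsv` plus `history.tsv` with the final state.
#' * `hybrid` — 20 hybrid runs at the illustrative high-mutation parameters
#'   (`nu = 0.02`, `u1 = 2e-4`): `families.tsv`, `mutations.tsv`.
#' * `pd` — Poisson-Dirichlet draws: `pd_atoms.tsv` with
#'   draw index, rank, fraction.
#' * `driver` — subclone frequencies at fixed final size: `driver_freq.tsv`.
#'
#' @param kind fixture family to generate.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(kind = c("small_exact", "hybrid", "pd", "driver"),
                          seed = 1L, dir = ".") {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- switch(kind,
    small_exact = {
      p <- two_type_params(b0 = 0.8, b1 = 0.6, u1 = 1e-3, nu = 0.05)
      h <- simulate_exact(p, n_end = 5000, seed = seed)
      c(tsv(h$mutations, "small_exact_mutations.tsv"),
        tsv(data.frame(t_end = h$t_end, z0 = h$z0, z1 = h$z1,
                       n_events = h$n_events, seed = seed),
            "small_exact_history.tsv"))
    },
    hybrid = {
      p <- two_type_params(u1 = 2e-4, nu = 0.02)
      h <- simulate_hybrid_type1(p, t_end = 400, n_runs = 20, seed = seed)
      c(tsv(h$families, "hybrid_families.tsv"),
        tsv(h$mutations, "hybrid_mutations.tsv"))
    },
    pd = {
      set.seed(seed)
      draws <- lapply(seq_len(50), function(i) {
        fr <- sample_pd(0.5)$fractions
        data.frame(draw_index = i, rank = seq_along(fr), fraction = fr)
      })
      tsv(do.call(rbind, draws), "pd_atoms.tsv")
    },
    driver = {
      p <- two_type_params(b1 = 0.965, u1 = 1e-5)
      f <- simulate_driver_frequency(p, M_target = 1e8, n_runs = 50,
                                     seed = seed)
      tsv(data.frame(run = seq_along(f), f_sub = f), "driver_freq.tsv")
    }
  )
  invisible(files)
}
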