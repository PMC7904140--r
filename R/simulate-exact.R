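#' Exact Gillespie simulation of the two-type model
#'
#' Simulates the continuous-time two-type birth-death process exactly, with
#' infinite-sites mutations: type-0 cells divide at rate `a0`, die at `b0`
#' and mutate to type 1 at rate `u1`; type-1 cells divide at `a1` and die at
#' `b1`; every cell acquires neutral mutations continuously at rate `nu`,
#' each mutation being new and inherited by all descendants. Intended for
#' populations up to about a million cells; use [simulate_hybrid_type1()]
#' beyond that.
#'
#' @param params a [two_type_params()] object.
#' @param t_end stop at this model time (`NULL` for no time limit).
#' @param n_end stop when the total population reaches this size (`NULL` for
#'   no size limit). At least one of `t_end`, `n_end` must be given.
#' @param seed optional integer seed.
#' @param cell_cap memory guard: the run aborts (with partial history and
#'   `aborted = TRUE`) if the population exceeds this many cells.
#' @param record_every record a `(time, Z0, Z1)` trajectory point every this
#'   many events (0 = no trajectory).
#' @return An object of class `population_history`: final `z0`, `z1`,
#'   `t_end`, `n_events`, `aborted`, a `mutations` data.frame (`id`,
#'   `class` in `type0`/`type1A`/`type1`, `origin_time`, `carriers`) and an
#'   optional `trajectory` data.frame.
#' @examples
#' h <- simulate_exact(two_type_params(u1 = 0, nu = 0.5), n_end = 200,
#'                     seed = 1)
#' h$z0
#' @export
simulate_exact <- function(params, t_end = NULL, n_end = NULL, seed = NULL,
                           cell_cap = 2e6, record_every = 0L) {
  stopifnot(inherits(params, "two_type_params"))
  if (is.null(t_end) && is.null(n_end)) {
    stop("give at least one stopping condition (t_end or n_end)",
         call. = FALSE)
  }
  if (!is.null(t_end) && t_end <= 0) stop("t_end must be positive",
                                          call. = FALSE)
  if (!is.null(n_end) && n_end <= 0) stop("n_end must be positive",
                                          call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  raw <- gillespie_two_type(params$a0, params$b0, params$a1, params$b1,
                            params$u1, params$nu,
                            if (is.null(t_end)) -1 else t_end,
                            if (is.null(n_end)) -1 else n_end,
                            cell_cap, as.integer(record_every))
  class_labels <- c("type0", "type1A", "type1")
  mutations <- data.frame(
    id = raw$mut_id,
    class = factor(class_labels[raw$mut_class + 1L], levels = class_labels),
    origin_time = raw$mut_time,
    carriers = raw$mut_carriers
  )
  trajectory <- if (record_every > 0) {
    data.frame(time = raw$traj_t, z0 = raw$traj_z0, z1 = raw$traj_z1)
  } else NULL
  structure(
    list(t_end = raw$t_end, z0 = raw$z0, z1 = raw$z1,
         n_events = raw$n_events, aborted = raw$aborted,
         mutations = mutations, trajectory = trajectory,
         params = params, seed = seed),
    class = "population_history"
  )
}

#' @export
print.population_history <- function(x, ...) {
  cat(sprintf(
    "population_history: t = %.3f, Z0 = %d, Z1 = %d, %d mutations (%s)%s\n",
    x$t_end, as.integer(x$z0), as.integer(x$z1), nrow(x$mutations),
    paste(sprintf("%s: %d", levels(x$mutations$class),
                  tabulate(x$mutations$class, 3L)), collapse = ", "),
    if (x$aborted) " [ABORTED at cell cap]" else ""))
  invisible(x)
}

#' Mutation frequencies from an exact simulation
#'
#' Extracts carrier frequencies of the recorded mutations, relative to a
#' chosen reference population. For spectra within the type-1 population
#' (the convention for the driver and type-1 neutral classes) use
#' `denominator = "type1"`; for whole-tumor subclone frequencies use
#' `"total"`.
#'
#' @param history a `population_history` from [simulate_exact()].
#' @param classes which mutation classes to keep (default all).
#' @param denominator reference population size for the frequency.
#' @param drop_zero drop mutations with no surviving carriers (default TRUE).
#' @return A data.frame with columns `id`, `class`, `origin_time`,
#'   `carriers`, `frequency`.
#' @export
mutation_frequencies <- function(history,
                                 classes = c("type0", "type1A", "type1"),
                                 denominator = c("total", "type1", "type0"),
                                 drop_zero = TRUE) {
  stopifnot(inherits(history, "population_history"))
  denominator <- match.arg(denominator)
  denom <- switch(denominator,
                  total = history$z0 + history$z1,
                  type1 = history$z1,
                  type0 = history$z0)
  m <- history$mutations
  m <- m[m$class %in% classes, , drop = FALSE]
  if (drop_zero) m <- m[m$carriers > 0, , drop = FALSE]
  m$frequency <- if (denom > 0) m$carriers / denom else NA_real_
  m
}
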