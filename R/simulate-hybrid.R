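# Hybrid simulators for large populations.
#
# The type-0 population is represented by its surviving-process limit
# Z0(t) = V0 * exp(lambda0 * t); successful driver families arrive as an
# inhomogeneous Poisson process thinned by the survival probability, and each
# family grows deterministically as W * exp(lambda * (t - s)) around its
# exponential limit W. Neutral mutations are laid down from their known
# within-family 1/f law. This reproduces the large-time composition of the
# type-1 population at a cost that does not grow with the number of cells.

# mean of min(max(L, 0), a1) for L ~ Normal(m, d): the expected per-candidate
# success weight (success probability of a family with growth rate L is
# min(max(L, 0), a1) / a1)
success_weight_mean <- function(m, d, a1) {
  if (d == 0) return(min(max(m, 0), a1))
  normal_partial_expectation(0, a1, m, d) + a1 * (1 - stats::pnorm(a1, m, d))
}

# sample n growth rates of *successful* families: density proportional to
# min(max(l, 0), a1) * dnorm(l, m, d).  Rejection from N(m + d^2/m, d) with
# envelope l <= m * exp((l - m)/m) (log-concavity of log at l = m); the
# acceptance probability is ~ exp(-d^2/(2 m^2)), essentially 1 for d << m.
sample_success_rates <- function(n, m, d, a1) {
  if (n == 0) return(numeric(0))
  if (d == 0) return(rep(m, n))
  out <- numeric(n)
  todo <- n
  while (todo > 0) {
    prop <- stats::rnorm(todo, mean = m + d^2 / m, sd = d)
    acc_p <- pmin(pmax(prop, 0), a1) / (m * exp((prop - m) / m))
    keep <- stats::runif(todo) < acc_p
    k <- sum(keep)
    if (k > 0) out[(n - todo + 1):(n - todo + k)] <- prop[keep]
    todo <- todo - k
  }
  out
}

# founder times of successful families on [0, t_end]: inhomogeneous Poisson
# with rate proportional to exp(lambda0 * s); `mean_total` is the expected
# number over the whole window
sample_founder_times <- function(mean_total, lambda0, t_end) {
  n <- stats::rpois(1, mean_total)
  if (n == 0) return(numeric(0))
  u <- stats::runif(n)
  sort(log1p(u * expm1(lambda0 * t_end)) / lambda0)
}

# one run of the family-level engine; returns families + v0
hybrid_one_run <- function(params, fit, t_end, v0_mode) {
  v0 <- if (v0_mode == "sampled") {
    stats::rexp(1, rate = params$lambda0 / params$a0)
  } else {
    params$a0 / params$lambda0
  }
  pbar <- success_weight_mean(fit$m, fit$d, params$a1) / params$a1
  mean_total <- params$u1 * pbar * v0 * expm1(params$lambda0 * t_end) /
    params$lambda0
  s <- sample_founder_times(mean_total, params$lambda0, t_end)
  n <- length(s)
  lambda <- sample_success_rates(n, fit$m, fit$d, params$a1)
  w <- if (n > 0) stats::rexp(n, rate = lambda / params$a1) else numeric(0)
  list(v0 = v0,
       families = data.frame(s = s, lambda1 = lambda, W = w,
                             size = w * exp(lambda * (t_end - s))))
}

# neutral + driver + founder-passenger mutations of one run, as frequencies
# within the type-1 population; only frequencies >= f_min are materialized
# (for every class -- sub-threshold families still count toward the total
# size and still draw their passenger counts, so the RNG stream does not
# depend on f_min beyond the neutral placements)
hybrid_mutations <- function(fam, nu, f_min) {
  n <- nrow(fam)
  empty <- list(mutations = data.frame(
    family = integer(0),
    class = factor(character(0), levels = c("type0", "type1A", "type1")),
    frequency = numeric(0)), n_pass = integer(0))
  if (n == 0) return(empty)
  z1 <- sum(fam$size)
  q <- fam$size / z1                       # family frequencies
  keep <- q >= f_min
  # driver (1A) mutations: one per family, at the family's frequency
  fidx <- which(keep)
  cls <- rep("type1A", sum(keep))
  freq <- q[keep]
  # founder passengers: Poisson(nu * s) type-0 mutations riding at the
  # family's frequency (private to each founder; shared type-0 ancestry
  # between founders is ignored -- see the methods vignette)
  n_pass <- stats::rpois(n, nu * fam$s)
  npk <- n_pass * keep
  if (sum(npk) > 0) {
    fidx <- c(fidx, rep.int(seq_len(n), npk))
    cls <- c(cls, rep("type0", sum(npk)))
    freq <- c(freq, rep(q, npk))
  }
  # within-family neutral mutations: homogeneous Poisson of rate nu/lambda
  # on the inverse-frequency axis u in [1, K_i], i.e. the within-family
  # cumulative spectrum (nu/lambda) / f; only mutations whose frequency in
  # the whole type-1 population reaches f_min can arise (u_max < 1 below
  # threshold)
  u_max <- pmin(fam$size, fam$size / (z1 * f_min))
  len <- pmax(u_max - 1, 0)
  n_neut <- stats::rpois(n, nu / fam$lambda1 * len)
  tot <- sum(n_neut)
  if (tot > 0) {
    fam_idx <- rep.int(seq_len(n), n_neut)
    u <- stats::runif(tot, min = 1, max = rep.int(u_max, n_neut))
    fidx <- c(fidx, fam_idx)
    cls <- c(cls, rep("type1", tot))
    freq <- c(freq, fam$size[fam_idx] / (u * z1))
  }
  list(mutations = data.frame(
    family = fidx,
    class = factor(cls, levels = c("type0", "type1A", "type1")),
    frequency = freq), n_pass = as.integer(n_pass))
}

#' Hybrid simulation with random fitness increases
#'
#' Simulates the type-1 side of the two-type model at the family level, with
#' each successful family drawing its own growth rate from
#' Normal(`fit$m`, `fit$d`). Per run: the type-0 population is
#' `V0 * exp(lambda0 * t)` with `V0` exponential (rate `lambda0/a0`) or fixed
#' at its mean; successful founders arrive as an inhomogeneous Poisson
#' process with rate `u1 * Z0(t) * E[success weight]`; each family gets a
#' growth rate from the success-size-biased normal (negative draws are never
#' successful), an exponential amplitude `W` (rate `lambda/a1`), founder
#' passengers `Poisson(nu * s)`, and within-family neutral mutations from the
#' 1/f law at rate `nu/lambda`. Frequencies are reported within the type-1
#' population.
#'
#' @param params a [two_type_params()] object (`a1`, `b1` enter only through
#'   `lambda1`, which is superseded by `fit` here).
#' @param fit a [fitness_distribution()] object; `fit$m` should exceed
#'   `params$lambda0`.
#' @param t_end end time of each run.
#' @param n_runs number of independent runs.
#' @param seed optional integer seed.
#' @param v0_mode `"sampled"` (exponential `V0`) or `"mean"` (`V0 = a0/lambda0`).
#' @param f_min smallest type-1-population frequency at which mutations are
#'   materialized in the output table (the 1/f law makes smaller ones
#'   arbitrarily numerous; they never enter spectra above `f_min`).
#'   Sub-threshold families still count toward the type-1 total.
#' @param keep_families keep the per-family table (set `FALSE` for large
#'   parameter sweeps where only the mutation spectrum is needed).
#' @return An object of class `hybrid_result`: data.frames `families`
#'   (`run`, `s`, `lambda1`, `W`, `size`, `n_founder_passengers`) and
#'   `mutations` (`run`, `class`, `frequency`), the per-run `v0`, and the
#'   call settings.
#' @seealso [simulate_hybrid_type1()] for the constant-fitness case.
#' @export
simulate_random_fitness <- function(params, fit, t_end, n_runs = 1L,
                                    seed = NULL, v0_mode = c("sampled", "mean"),
                                    f_min = 0.001, keep_families = TRUE) {
  stopifnot(inherits(params, "two_type_params"),
            inherits(fit, "fitness_distribution"))
  v0_mode <- match.arg(v0_mode)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (fit$d < 0) stop("d must be nonnegative", call. = FALSE)
  if (fit$m <= 0) stop("mean growth rate m must be positive", call. = FALSE)
  if (f_min <= 0 || f_min >= 1) stop("f_min must lie in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fam_list <- vector("list", n_runs)
  mut_list <- vector("list", n_runs)
  v0s <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    run <- hybrid_one_run(params, fit, t_end, v0_mode)
    v0s[r] <- run$v0
    mm <- hybrid_mutations(run$families, params$nu, f_min)
    if (keep_families) {
      fam <- run$families
      fam$n_founder_passengers <- mm$n_pass
      fam_list[[r]] <- if (nrow(fam) > 0) cbind(run = r, fam) else NULL
    }
    mut_list[[r]] <- if (nrow(mm$mutations) > 0) {
      cbind(run = r, mm$mutations)
    } else NULL
  }
  structure(
    list(families = if (keep_families) do.call(rbind, fam_list) else NULL,
         mutations = do.call(rbind, mut_list),
         v0 = v0s, params = params, fit = fit, t_end = t_end,
         v0_mode = v0_mode, f_min = f_min, n_runs = n_runs, seed = seed),
    class = "hybrid_result"
  )
}

#' Hybrid simulation of the type-1 population (constant fitness)
#'
#' The family-level simulator for the standard two-type model: identical to
#' [simulate_random_fitness()] with the degenerate fitness distribution
#' `Normal(lambda1, 0)` (and is implemented as exactly that call, so the two
#' agree draw-for-draw at `d = 0`).
#'
#' @inheritParams simulate_random_fitness
#' @return A `hybrid_result`; see [simulate_random_fitness()].
#' @examples
#' p <- two_type_params(u1 = 2e-4, nu = 0.02)
#' h <- simulate_hybrid_type1(p, t_end = 300, n_runs = 2, seed = 1)
#' head(h$families)
#' @export
simulate_hybrid_type1 <- function(params, t_end, n_runs = 1L, seed = NULL,
                                  v0_mode = c("sampled", "mean"),
                                  f_min = 0.001, keep_families = TRUE) {
  simulate_random_fitness(params,
                          fitness_distribution(m = params$lambda1, d = 0),
                          t_end = t_end, n_runs = n_runs, seed = seed,
                          v0_mode = match.arg(v0_mode), f_min = f_min,
                          keep_families = keep_families)
}

#' @export
print.hybrid_result <- function(x, ...) {
  nf <- if (is.null(x$families)) 0L else nrow(x$families)
  nm <- if (is.null(x$mutations)) 0L else nrow(x$mutations)
  cat(sprintf(
    "hybrid_result: %d run(s) to t = %g; %d successful families, %d mutations (f >= %g)\n",
    x$n_runs, x$t_end, nf, nm, x$f_min))
  if (x$fit$d > 0) {
    cat(sprintf("  random fitness: Normal(%g, %g)\n", x$fit$m, x$fit$d))
  }
  invisible(x)
}

#' Type-1 population size of a hybrid run at an arbitrary time
#'
#' Sums `W * exp(lambda * (t - s))` over the families of one run that were
#' founded by time `t`; useful for checking the subclone-ratio growth law
#' `Z1/Z0 ~ exp((lambda1 - lambda0) s)`.
#'
#' @param result a `hybrid_result`.
#' @param t evaluation time(s), each in `[0, t_end]`.
#' @param run which run to evaluate.
#' @return Numeric vector of type-1 sizes, one per `t`.
#' @export
hybrid_type1_size <- function(result, t, run = 1L) {
  stopifnot(inherits(result, "hybrid_result"))
  fam <- result$families
  fam <- fam[fam$run == run, , drop = FALSE]
  vapply(t, function(tt) {
    keep <- fam$s <= tt
    sum(fam$W[keep] * exp(fam$lambda1[keep] * (tt - fam$s[keep])))
  }, numeric(1))
}

#' Subclone frequency at a fixed total tumor size
#'
#' Grows the tumor to a fixed total size `M_target` and records the fraction
#' `f_sub` of type-1 cells, replicating the design of the subclonal-driver
#' detectability analysis. In `single_1A` mode only the first successful
#' driver family exists (the classical one-driver assumption); in
#' `multiple_1A` mode all successful families founded before the stopping
#' time contribute. Runs where no successful family has arisen when the
#' tumor reaches `M_target` record `f_sub = 0`.
#'
#' @param params a [two_type_params()] object.
#' @param M_target total population size at observation (cells), much
#'   greater than 1.
#' @param n_runs number of replicates.
#' @param mode `"single_1A"` or `"multiple_1A"`.
#' @param seed optional integer seed.
#' @param v0_mode `"sampled"` or `"mean"` type-0 amplitude.
#' @return Numeric vector of `n_runs` subclone frequencies in \[0, 1).
#' @examples
#' p <- two_type_params(b1 = 0.965, u1 = 1e-5) # lambda1 = 0.035
#' f <- simulate_driver_frequency(p, M_target = 1e9, n_runs = 20, seed = 1)
#' mean(f > 0.2)
#' @export
simulate_driver_frequency <- function(params, M_target, n_runs = 1L,
                                      mode = c("multiple_1A", "single_1A"),
                                      seed = NULL,
                                      v0_mode = c("sampled", "mean")) {
  stopifnot(inherits(params, "two_type_params"))
  mode <- match.arg(mode)
  v0_mode <- match.arg(v0_mode)
  if (M_target <= 1) stop("M_target must exceed 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rate_success <- params$u1 * params$lambda1 / params$a1
  f_sub <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    v0 <- if (v0_mode == "sampled") {
      stats::rexp(1, rate = params$lambda0 / params$a0)
    } else {
      params$a0 / params$lambda0
    }
    # time at which type 0 alone reaches M: upper bound for the stop time
    t_hi <- log(M_target / v0) / params$lambda0
    if (t_hi <= 0) { f_sub[r] <- 0; next }     # V0 already >= M
    if (mode == "single_1A") {
      # first-success time from the inhomogeneous exponential clock
      e1 <- stats::rexp(1)
      grow <- 1 + e1 * params$lambda0 / (rate_success * v0)
      s <- log(grow) / params$lambda0
      if (s >= t_hi) { f_sub[r] <- 0; next }
      lam <- params$lambda1
      w <- stats::rexp(1, rate = lam / params$a1)
      fam <- data.frame(s = s, lambda1 = lam, W = w)
    } else {
      mean_total <- rate_success * v0 * expm1(params$lambda0 * t_hi) /
        params$lambda0
      s <- sample_founder_times(mean_total, params$lambda0, t_hi)
      if (length(s) == 0) { f_sub[r] <- 0; next }
      fam <- data.frame(s = s, lambda1 = params$lambda1,
                        W = stats::rexp(length(s),
                                        rate = params$lambda1 / params$a1))
    }
    y_at <- function(tt) {
      keep <- fam$s <= tt
      sum(fam$W[keep] * exp(fam$lambda1[keep] * (tt - fam$s[keep])))
    }
    z_at <- function(tt) v0 * exp(params$lambda0 * tt) + y_at(tt)
    # first time total size reaches M: bisection (Z is increasing with
    # upward jumps at founding times, so bisection is exact here)
    lo <- 0; hi <- t_hi
    if (z_at(0) >= M_target) { f_sub[r] <- y_at(0) / z_at(0); next }
    while ((hi - lo) > 1e-6 * max(hi, 1)) {
      mid <- (lo + hi) / 2
      if (z_at(mid) >= M_target) hi <- mid else lo <- mid
    }
    f_sub[r] <- y_at(hi) / z_at(hi)
  }
  f_sub
}
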