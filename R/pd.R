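#' Ranked relative family sizes
#'
#' Light container for one draw of the ranked relative sizes of the driver
#' (1A) families: a finite descending sequence of fractions of the type-1
#' population, plus a bound on the relative mass of the omitted tail.
#'
#' @param fractions descending positive fractions summing to at most 1.
#' @param truncation_mass upper bound on the omitted relative tail mass.
#' @param points optional raw (unnormalized) point sizes, descending.
#' @return An object of class `family_size_atoms`.
#' @keywords internal
family_size_atoms <- function(fractions, truncation_mass, points = NULL) {
  stopifnot(all(fractions > 0), all(diff(fractions) <= 0),
            sum(fractions) <= 1 + 1e-12)
  structure(list(fractions = fractions, truncation_mass = truncation_mass,
                 points = points),
            class = "family_size_atoms")
}

#' @export
print.family_size_atoms <- function(x, ...) {
  cat(sprintf("family_size_atoms: %d ranked fractions, largest %.4f, ",
              length(x$fractions), x$fractions[1]))
  cat(sprintf("sum %.4f (omitted tail mass <= %.2e)\n",
              sum(x$fractions), x$truncation_mass))
  invisible(x)
}

#' Sample relative family sizes from the Poisson-Dirichlet PD(alpha, 0)
#'
#' Draws the `n_atoms` largest fractions of a Poisson-Dirichlet PD(alpha, 0)
#' vector — the limiting ranked relative sizes of the driver families in the
#' type-1 population, with `alpha = lambda0/lambda1`. Sampling uses the
#' GEM(alpha, 0) stick-breaking representation: residual fractions
#' `Beta(1 - alpha, i * alpha)` in size-biased order, then sorted descending.
#' The unbroken remainder of the stick bounds the omitted tail mass.
#'
#' @param alpha Poisson-Dirichlet parameter in (0, 1).
#' @param n_atoms number of stick-breaking atoms to generate (default 100;
#'   the omitted atoms are then far below any frequency of interest for
#'   moderate `alpha`).
#' @param seed optional integer seed for reproducibility.
#' @return A `family_size_atoms` object.
#' @examples
#' a <- sample_pd(0.5, seed = 1)
#' head(a$fractions)
#' @export
sample_pd <- function(alpha, n_atoms = 100L, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (n_atoms < 1) stop("n_atoms must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  i <- seq_len(n_atoms)
  breaks <- stats::rbeta(n_atoms, shape1 = 1 - alpha, shape2 = i * alpha)
  remain <- cumprod(1 - breaks)
  sticks <- breaks * c(1, remain[-n_atoms])
  family_size_atoms(sort(sticks, decreasing = TRUE),
                    truncation_mass = remain[n_atoms])
}

#' Sample family sizes from the limiting Poisson point process
#'
#' Independent construction of the same ranked fractions: simulate the points
#' of a Poisson process whose mean measure has tail
#' `C * v0 * x^(-alpha)`, then normalize by their sum. Points are generated
#' in decreasing order via `x_k = (Gamma_k / (C * v0))^(-1/alpha)` with
#' `Gamma_k` the arrival times of a unit-rate Poisson process, stopping once
#' the expected omitted mass below the current level is under `truncation`
#' times the realized sum. Dividing the points by their sum yields a
#' PD(alpha, 0) vector, so this acts as a mutual oracle for [sample_pd()].
#'
#' @param alpha tail exponent in (0, 1).
#' @param intensity_constant the constant `C` multiplying `v0 * x^(-alpha)`
#'   (see [limit_intensity_constant()]).
#' @param v0 amplitude multiplying the measure; positive.
#' @param truncation bound on the omitted relative tail mass, in (0, 1).
#' @param seed optional integer seed.
#' @return A `family_size_atoms` object (fractions normalized by the realized
#'   sum, so they total 1; `truncation_mass` reports the achieved bound; the
#'   raw point sizes are kept in `$points`).
#' @examples
#' a <- sample_poisson_atoms(0.5, 0.1772, v0 = 1, seed = 1)
#' sum(a$fractions) # 1
#' @export
sample_poisson_atoms <- function(alpha, intensity_constant = 0.1772, v0 = 1,
                                 truncation = 1e-4, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (truncation <= 0 || truncation >= 1) {
    stop("truncation must lie in (0, 1)", call. = FALSE)
  }
  if (intensity_constant <= 0 || v0 <= 0) {
    stop("intensity_constant and v0 must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cv <- intensity_constant * v0
  chunk <- 64L
  gam <- cumsum(stats::rexp(chunk))
  pts <- (gam / cv)^(-1 / alpha)
  repeat {
    # expected mass below the smallest generated point:
    # int_0^x t dLambda(t) = cv * alpha/(1-alpha) * x^(1-alpha)
    x_low <- pts[length(pts)]
    omitted <- cv * alpha / (1 - alpha) * x_low^(1 - alpha)
    if (omitted < truncation * sum(pts)) break
    gam_new <- gam[length(gam)] + cumsum(stats::rexp(chunk))
    gam <- c(gam, gam_new)
    pts <- c(pts, (gam_new / cv)^(-1 / alpha))
  }
  s <- sum(pts)
  family_size_atoms(pts / s, truncation_mass = omitted / s, points = pts)
}

#' Tail probability of the combined top-i family fractions
#'
#' Monte-Carlo estimate of the probability that the `i` largest driver
#' families jointly exceed a fraction `x` of the type-1 population, under
#' PD(alpha, 0).
#'
#' @param alpha Poisson-Dirichlet parameter in (0, 1).
#' @param i number of top families combined; `i >= 1`.
#' @param x fraction threshold in (0, 1); vector allowed.
#' @param n_draws Monte-Carlo replicates.
#' @param seed optional integer seed.
#' @param n_atoms atoms per draw (passed to [sample_pd()]).
#' @return A data.frame with columns `x`, `prob`, `se` (binomial standard
#'   error).
#' @examples
#' top_i_tail(0.5, i = 1, x = 0.5, n_draws = 500, seed = 1)
#' @export
top_i_tail <- function(alpha, i, x, n_draws = 2000L, seed = NULL,
                       n_atoms = 100L) {
  if (i < 1) stop("i must be at least 1", call. = FALSE)
  if (any(x <= 0) || any(x >= 1)) stop("x must lie in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  topsums <- vapply(seq_len(n_draws), function(k) {
    fr <- sample_pd(alpha, n_atoms = n_atoms)$fractions
    sum(fr[seq_len(min(i, length(fr)))])
  }, numeric(1))
  prob <- vapply(x, function(xx) mean(topsums > xx), numeric(1))
  data.frame(x = x, prob = prob, se = sqrt(prob * (1 - prob) / n_draws))
}
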