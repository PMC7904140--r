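#' Median time of the first successful driver mutation
#'
#' In the surviving-process representation the type-0 population grows as
#' `V0 * exp(lambda0 * t)` and successful type-1 founders (those whose family
#' escapes extinction) arrive at rate `u1 * (lambda1/a1) * Z0(t)`. The time
#' of the first successful driver has median
#' `(1/lambda0) * log(lambda0^2 * a1 / (a0 * u1 * lambda1))`.
#'
#' @param params a [two_type_params()] object.
#' @return The median first-success time, in model time units.
#' @examples
#' median_first_success_time(two_type_params()) # 460.517
#' @export
median_first_success_time <- function(params) {
  stopifnot(inherits(params, "two_type_params"))
  if (params$u1 <= 0) stop("u1 must be positive", call. = FALSE)
  arg <- params$lambda0^2 * params$a1 / (params$a0 * params$u1 * params$lambda1)
  if (arg < 1) {
    stop("lambda0^2*a1/(a0*u1*lambda1) < 1: u1 too large for the ",
         "asymptotic regime; median would be negative", call. = FALSE)
  }
  log(arg) / params$lambda0
}

#' Constant of the limiting Poisson intensity of family sizes
#'
#' Rescaled around the median first-success time, the sizes of the successful
#' type-1 families are the points of a Poisson process whose mean measure has
#' tail `C * V0 * x^(-alpha)` with `alpha = lambda0/lambda1`. This returns
#' the constant `C = lambda0 * gamma(alpha) / lambda1^alpha` (the mutation
#' rate drops out of the rescaled measure). At the default parameters
#' (`alpha = 1/2`) the constant is 0.17725.
#'
#' @param params a [two_type_params()] object (only `lambda0`, `lambda1`
#'   enter).
#' @return The positive constant `C`.
#' @examples
#' limit_intensity_constant(two_type_params()) # 0.1772
#' @export
limit_intensity_constant <- function(params) {
  stopifnot(inherits(params, "two_type_params"))
  alpha <- params$alpha
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha = lambda0/lambda1 must lie strictly in (0, 1)", call. = FALSE)
  }
  params$lambda0 * gamma(alpha) / params$lambda1^alpha
}

#' Expected cumulative spectrum of driver (1A) mutations
#'
#' The expected number of driver mutations carried by at least a fraction `f`
#' of the type-1 population, in the large-time limit:
#' `sin(pi*alpha)/(pi*alpha) * (1/f - 1)^alpha`. This is the mean number of
#' atoms of a Poisson-Dirichlet PD(alpha, 0) vector that exceed `f`. At
#' `alpha = 1/2` the leading constant is `2/pi = 0.6366`.
#'
#' @param f frequency (or vector of frequencies) in (0, 1).
#' @param alpha power-law exponent `lambda0/lambda1`, in (0, 1).
#' @return Expected count(s), decreasing in `f`, vanishing as `f -> 1`.
#' @examples
#' sfs_1a(0.5, 0.5) # 2/pi
#' @export
sfs_1a <- function(f, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (any(f <= 0) || any(f >= 1)) stop("f must lie in (0, 1)", call. = FALSE)
  sin(pi * alpha) / (pi * alpha) * (1 / f - 1)^alpha
}

#' Neutral 1/f cumulative site frequency spectrum
#'
#' Expected number of neutral mutations with frequency at least `f` in an
#' exponentially growing population. With mutations acquired once at birth
#' (rate `rate` per birth) the count is `rate / f`, independent of the growth
#' rate; with mutations accumulating continuously over a cell's lifetime at
#' rate `rate`, it is `rate / (growth * f)`. Applied with `growth = lambda1`,
#' the continuous mode gives the spectrum of neutral mutations within the
#' type-1 population.
#'
#' @param f frequency (vector allowed) in (0, 1].
#' @param rate mutation rate (per birth for `at_birth`, per unit lifetime for
#'   `continuous`); nonnegative.
#' @param growth net exponential growth rate; must be positive (used only in
#'   `continuous` mode).
#' @param mode `"at_birth"` or `"continuous"`.
#' @return Expected count(s) of mutations with frequency `>= f`.
#' @examples
#' neutral_sfs(0.5, rate = 0.02, growth = 0.04, mode = "continuous") # 1
#' @export
neutral_sfs <- function(f, rate, growth = NULL,
                        mode = c("at_birth", "continuous")) {
  mode <- match.arg(mode)
  if (any(f <= 0) || any(f > 1)) stop("f must lie in (0, 1]", call. = FALSE)
  if (rate < 0) stop("rate must be nonnegative", call. = FALSE)
  if (mode == "at_birth") {
    rate / f
  } else {
    if (is.null(growth) || growth <= 0) {
      stop("continuous mode needs growth > 0", call. = FALSE)
    }
    rate / (growth * f)
  }
}

# Partial expectation of a Normal(m, d) over [lo, hi]:
# integral of x*phi(x) dx = m*(Phi(hi)-Phi(lo)) + d^2*(phi(lo)-phi(hi)).
normal_partial_expectation <- function(lo, hi, m, d) {
  m * (stats::pnorm(hi, m, d) - stats::pnorm(lo, m, d)) +
    d^2 * (stats::dnorm(lo, m, d) - stats::dnorm(hi, m, d))
}

#' Expected number of large random-fitness families
#'
#' Under random fitness increases, each successful family founded at time `s`
#' with growth rate `lambda` reaches size of order `exp(lambda * (t_end - s))`
#' by time `t_end`. The expected number of successful families with
#' `lambda_i * (t_end - s_i) > x` is the integral
#' \deqn{u_1 \int_0^{t_{end}} v_0 e^{\lambda_0 s}
#'   \left[m(1 - \Phi(x/(t_{end}-s))) + d^2 \phi(x/(t_{end}-s))\right] ds,}
#' where `phi`/`Phi` are the Normal(`m`, `d`) density and cdf and the bracket
#' is the partial expectation `int_{x/(t-s)}^Inf lambda*phi(lambda) dlambda`
#' (each candidate founder with growth rate `lambda` succeeds with
#' probability `lambda/a1`; with `a1 = 1` this contributes the `lambda`
#' weight).
#'
#' @param x threshold for the log-size proxy `lambda_i * (t_end - s_i)`;
#'   nonnegative (vector allowed).
#' @param params a [two_type_params()] object (supplies `u1`, `lambda0`,
#'   `a1`).
#' @param fit a [fitness_distribution()] object.
#' @param t_end end time of the experiment; positive.
#' @param v0 amplitude of the type-0 population `Z0(t) = v0 * exp(lambda0 t)`;
#'   default the mean `a0/lambda0` of its exponential limit (50 at the
#'   default rates).
#' @return Expected count(s), nonincreasing in `x`.
#' @examples
#' p <- two_type_params()
#' fd <- fitness_distribution(0.04, 0.005)
#' random_fitness_family_tail(0, p, fd, t_end = 1000)
#' @export
random_fitness_family_tail <- function(x, params, fit, t_end,
                                       v0 = params$a0 / params$lambda0) {
  stopifnot(inherits(params, "two_type_params"),
            inherits(fit, "fitness_distribution"))
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (v0 <= 0) stop("v0 must be positive", call. = FALSE)
  if (any(x < 0)) stop("x must be nonnegative", call. = FALSE)
  m <- fit$m; d <- fit$d
  if (d == 0) {
    # degenerate fitness: all families grow at rate m, the tail indicator
    # cuts the founder-time integral at t_end - x/m
    weight <- min(max(m, 0), params$a1)
    t_cut <- pmax(0, t_end - ifelse(x > 0, x / m, 0))
    return(params$u1 * weight / params$a1 * v0 *
             expm1(params$lambda0 * t_cut) / params$lambda0)
  }
  vapply(x, function(xi) {
    integrand <- function(s) {
      thr <- ifelse(s < t_end, xi / (t_end - s), Inf)
      tail_pe <- m * (1 - stats::pnorm(thr, m, d)) +
        d^2 * stats::dnorm(thr, m, d)
      v0 * exp(params$lambda0 * s) * tail_pe / params$a1
    }
    params$u1 * stats::integrate(integrand, 0, t_end, abs.tol = 1e-10,
                                 rel.tol = 1e-8,
                                 subdivisions = 500L)$value
  }, numeric(1))
}

#' Distribution function of the subclone frequency at fixed tumor size
#'
#' Probability that the subclone founded by the first successful driver makes
#' up at most a fraction `y` of the tumor when the total size reaches `M`
#' cells. The type-0 population at the driver's appearance is
#' `X0 ~ Exponential(u*c/b1)` (restricted to `X0 <= M`) and the subclone
#' grows as `W1 * exp(r1 * t)` with `W1 ~ Exponential(c*r/b1)`, giving
#' \deqn{P(f_{sub} \le y) = \int_0^M (uc/b_1) e^{-ucx_0/b_1}
#'   \left[1 - \exp\left(-\frac{cr}{b_1} \frac{y}{(1-y)^{c}}
#'   x_0^{c} M^{1-c}\right)\right] dx_0.}
#' The inner exponent follows from `Y_t <= (y/(1-y)) X_t` with
#' `X_t = (1-y) M` at the boundary, so `(1-y)` enters with power `-c`.
#'
#' @param y frequency in (0, 1); vector allowed.
#' @param p a [bozic_params()] object.
#' @param method `"quadrature"` (adaptive, absolute tolerance 1e-10) or
#'   `"riemann"` (fixed midpoint sum on the `x0` axis, step `dx`).
#' @param dx Riemann step size (cells), used only for `method = "riemann"`.
#' @return Probability/ies in \[0, 1\], nondecreasing in `y`; tends to
#'   `1 - exp(-u*c*M/b1)` (the chance any driver arises before size `M`) as
#'   `y -> 1`.
#' @examples
#' bp <- bozic_params(b = 0.14, d = 0.13, b1 = 0.14, d1 = 0.127,
#'                    u = 1e-5, M = 1e9)
#' bozic_subclonal_cdf(c(0.2, 0.8), bp)
#' @export
bozic_subclonal_cdf <- function(y, p, method = c("quadrature", "riemann"),
                                dx = 500) {
  stopifnot(inherits(p, "bozic_params"))
  method <- match.arg(method)
  if (any(y <= 0) || any(y >= 1)) stop("y must lie in (0, 1)", call. = FALSE)
  scale <- p$u * p$c / p$b1              # rate of the X0 exponential
  vapply(y, function(yy) {
    # inner bracket as a function of x0
    bracket <- function(x0) {
      expo <- (p$c * p$r / p$b1) * yy * (1 - yy)^(-p$c) * x0^p$c * p$M^(1 - p$c)
      -expm1(-expo)
    }
    val <- if (method == "quadrature") {
      # substitute z = scale * x0 so the exponential weight is O(1)
      f <- function(z) exp(-z) * bracket(z / scale)
      upper <- min(scale * p$M, 60)      # exp(-60) ~ 9e-27: negligible tail
      stats::integrate(f, 0, upper, abs.tol = 1e-10, rel.tol = 1e-10,
                       subdivisions = 1000L)$value
    } else {
      x0 <- seq(dx / 2, p$M, by = dx)    # midpoint rule, step dx cells
      sum(scale * exp(-scale * x0) * bracket(x0)) * dx
    }
    min(max(val, 0), 1)                  # clamp fp noise into [0, 1]
  }, numeric(1))
}

#' Probability a subclonal driver is at detectable frequency
#'
#' Probability that the subclone frequency at total size `M` lies in
#' `[lo, hi]`, by default the detectable-but-not-fixed window \[0.2, 0.8\].
#'
#' @param p a [bozic_params()] object.
#' @param lo,hi window bounds, `0 < lo < hi < 1`.
#' @inheritParams bozic_subclonal_cdf
#' @return A probability in \[0, 1\].
#' @export
detectable_driver_probability <- function(p, lo = 0.2, hi = 0.8,
                                          method = c("quadrature", "riemann"),
                                          dx = 500) {
  if (lo < 0 || hi <= 0 || lo > hi || hi >= 1) {
    stop("need 0 < lo <= hi < 1", call. = FALSE)
  }
  if (lo == hi) return(0)
  method <- match.arg(method)
  val <- bozic_subclonal_cdf(hi, p, method = method, dx = dx) -
    bozic_subclonal_cdf(lo, p, method = method, dx = dx)
  min(max(val, 0), 1)
}

#' Duration of the subclone coexistence window
#'
#' The type-1 : type-0 ratio grows as `exp((lambda1 - lambda0) * s)`, so the
#' time for it to traverse `[ratio_lo, ratio_hi]` — e.g. for the subclone
#' frequency to pass from 20% to 80% of the tumor — is
#' `log(ratio_hi/ratio_lo) / (lambda1 - lambda0)`, independent of the
#' mutation rates and the initial sizes.
#'
#' @param params a [two_type_params()] object.
#' @param ratio_lo,ratio_hi ratio window; defaults 1/4 and 4 correspond to
#'   frequencies 0.2 and 0.8.
#' @return Window duration in model time units (ln(16)/0.015 = 184.8 at
#'   `lambda1 - lambda0 = 0.015`).
#' @export
subclone_ratio_window <- function(params, ratio_lo = 1 / 4, ratio_hi = 4) {
  stopifnot(inherits(params, "two_type_params"))
  if (ratio_lo <= 0 || ratio_hi < ratio_lo) {
    stop("need ratio_hi >= ratio_lo > 0", call. = FALSE)
  }
  log(ratio_hi / ratio_lo) / (params$lambda1 - params$lambda0)
}

#' Probability a later family overtakes the first
#'
#' Two successful families founded `delta_s` apart reach sizes
#' `W0 * exp(lambda1 * t)` and `W1 * exp(lambda1 * (t - delta_s))` with
#' `W0`, `W1` i.i.d. exponential. Since `P(W0/W1 <= x) = x/(x+1)`, the later
#' family ends up larger with probability `1 / (exp(lambda1 * delta_s) + 1)`
#' — e.g. 0.018 when `lambda1 * delta_s = 4`, which is why the important
#' driver families all arise within a few multiples of `1/lambda1` of the
#' first success and hence carry roughly the same number of hitchhiking
#' passengers.
#'
#' @param delta_s founding-time gap, nonnegative (vector allowed).
#' @param lambda1 growth rate of the families; positive.
#' @return Probability/ies in (0, 1/2\].
#' @examples
#' second_family_dominance_prob(100, 0.04) # 1/(exp(4)+1)
#' @export
second_family_dominance_prob <- function(delta_s, lambda1) {
  if (any(delta_s < 0)) stop("delta_s must be nonnegative", call. = FALSE)
  if (lambda1 <= 0) stop("lambda1 must be positive", call. = FALSE)
  1 / (exp(lambda1 * delta_s) + 1)
}
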