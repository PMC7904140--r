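#' Two-type branching-process parameters
#'
#' Container for the rates of the two-type model of clonal expansion: a
#' resident type-0 population (birth rate `a0`, death rate `b0`, net growth
#' `lambda0 = a0 - b0`) produces, at rate `u1` per cell per unit time, founders
#' of fitter type-1 families (birth `a1`, death `b1`, net growth
#' `lambda1 = a1 - b1 > lambda0`). Neutral mutations accumulate continuously
#' over a cell's lifetime at rate `nu` under the infinite-sites model.
#'
#' The derived quantity `alpha = lambda0 / lambda1` (in (0, 1)) is the
#' power-law exponent of the driver-mutation site frequency spectrum and the
#' parameter of the Poisson-Dirichlet distribution governing relative family
#' sizes.
#'
#' Defaults are the concrete worked example used throughout the package:
#' `a0 = a1 = 1`, `lambda0 = 0.02`, `lambda1 = 0.04` (so `b0 = 0.98`,
#' `b1 = 0.96`), `u1 = 1e-6`, `nu = 1e-4`.
#'
#' @param a0,b0 type-0 birth and death rates (per cell per unit time).
#' @param a1,b1 type-1 birth and death rates.
#' @param u1 driver mutation rate (type 0 to type 1, per cell per unit time).
#' @param nu neutral mutation rate (per cell per unit time, continuous in
#'   lifetime).
#'
#' @return An object of class `two_type_params`: a list with the primary rates
#'   plus derived `lambda0`, `lambda1`, `alpha`.
#' @examples
#' p <- two_type_params()
#' p$alpha # 0.5
#' @export
two_type_params <- function(a0 = 1, b0 = 0.98, a1 = 1, b1 = 0.96,
                            u1 = 1e-6, nu = 1e-4) {
  rates <- c(a0 = a0, b0 = b0, a1 = a1, b1 = b1, u1 = u1, nu = nu)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates must be finite and nonnegative", call. = FALSE)
  }
  lambda0 <- a0 - b0
  lambda1 <- a1 - b1
  if (lambda0 <= 0) {
    stop("lambda0 = a0 - b0 must be positive (supercritical type 0)",
         call. = FALSE)
  }
  if (lambda1 <= lambda0) {
    stop("lambda1 = a1 - b1 must exceed lambda0 (alpha = lambda0/lambda1 ",
         "must lie in (0, 1))", call. = FALSE)
  }
  structure(
    list(a0 = a0, b0 = b0, a1 = a1, b1 = b1, u1 = u1, nu = nu,
         lambda0 = lambda0, lambda1 = lambda1, alpha = lambda0 / lambda1),
    class = "two_type_params"
  )
}

#' @export
print.two_type_params <- function(x, ...) {
  cat("Two-type branching-process parameters\n")
  cat(sprintf("  type 0: birth a0 = %g, death b0 = %g, growth lambda0 = %g\n",
              x$a0, x$b0, x$lambda0))
  cat(sprintf("  type 1: birth a1 = %g, death b1 = %g, growth lambda1 = %g\n",
              x$a1, x$b1, x$lambda1))
  cat(sprintf("  driver rate u1 = %g, neutral rate nu = %g\n", x$u1, x$nu))
  cat(sprintf("  alpha = lambda0/lambda1 = %g\n", x$alpha))
  invisible(x)
}

#' Normal distribution of type-1 growth rates
#'
#' Describes random fitness increases: each type-1 family draws its net growth
#' rate from Normal(`m`, `d`). `d = 0` degenerates to constant fitness
#' `lambda1 = m`.
#'
#' @param m mean growth rate of type-1 families (per unit time).
#' @param d standard deviation of the growth rate; `d >= 0`.
#' @return An object of class `fitness_distribution` with fields `m`, `d` and
#'   functions `phi` (density) and `Phi` (distribution function).
#' @examples
#' fd <- fitness_distribution(m = 0.04, d = 0.005)
#' fd$Phi(0.04) # 0.5
#' @export
fitness_distribution <- function(m = 0.04, d = 0.005) {
  if (!is.finite(m) || !is.finite(d) || d < 0) {
    stop("need finite m and d >= 0", call. = FALSE)
  }
  force(m); force(d)
  phi <- if (d == 0) {
    function(x) ifelse(x == m, Inf, 0)
  } else {
    function(x) stats::dnorm(x, mean = m, sd = d)
  }
  Phi <- if (d == 0) {
    function(x) as.numeric(x >= m)
  } else {
    function(x) stats::pnorm(x, mean = m, sd = d)
  }
  structure(list(m = m, d = d, phi = phi, Phi = Phi),
            class = "fitness_distribution")
}

#' @export
print.fitness_distribution <- function(x, ...) {
  cat(sprintf("Type-1 growth-rate distribution: Normal(m = %g, d = %g)%s\n",
              x$m, x$d,
              if (x$d == 0) " [degenerate: constant fitness]" else ""))
  invisible(x)
}

#' Fixed-final-size parameterization of the two-type model
#'
#' The alternative notation used for the subclonal-driver detectability
#' analysis: type-0 birth `b`, death `d`, net growth `r = b - d`; the single
#' subclone has birth `b1`, death `d1`, net growth `r1 = d1 - b1`... see
#' fields. The selection coefficient is expressed through `c = r1 / r > 1`
#' and `g = c - 1`; the tumor is observed when its total size reaches `M`
#' cells. The mapping onto [two_type_params()] is `a0 = b`, `b0 = d`,
#' `lambda0 = r`, `a1 = b1`, `b1 = d1`, `lambda1 = r1`, `u1 = u`.
#'
#' @param b,d type-0 birth and death rates; `r = b - d > 0`.
#' @param b1,d1 subclone birth and death rates; `r1 = b1 - d1 > r`.
#' @param u driver mutation rate per cell per unit time.
#' @param M total tumor size (cell count) at observation.
#' @return An object of class `bozic_params` with derived `r`, `r1`, `c`, `g`.
#' @examples
#' # moderately growing tumor with a 30% fitter subclone
#' bp <- bozic_params(b = 0.14, d = 0.13, b1 = 0.14, d1 = 0.127,
#'                    u = 1e-5, M = 1e9)
#' bp$g # 0.3
#' @export
bozic_params <- function(b, d, b1, d1, u, M) {
  vals <- c(b = b, d = d, b1 = b1, d1 = d1, u = u, M = M)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all parameters must be finite and nonnegative", call. = FALSE)
  }
  r <- b - d
  r1 <- b1 - d1
  if (r <= 0) stop("need r = b - d > 0", call. = FALSE)
  cc <- r1 / r
  if (cc <= 1) stop("need c = r1/r > 1 (the subclone must be fitter)",
                    call. = FALSE)
  if (M <= 0) stop("need M > 0", call. = FALSE)
  structure(
    list(b = b, d = d, r = r, b1 = b1, d1 = d1, r1 = r1, u = u,
         c = cc, g = cc - 1, M = M),
    class = "bozic_params"
  )
}

#' @export
print.bozic_params <- function(x, ...) {
  cat("Fixed-final-size two-type parameters\n")
  cat(sprintf("  type 0: b = %g, d = %g, r = %g\n", x$b, x$d, x$r))
  cat(sprintf("  subclone: b1 = %g, d1 = %g, r1 = %g (c = %g, g = %g)\n",
              x$b1, x$d1, x$r1, x$c, x$g))
  cat(sprintf("  driver rate u = %g, final size M = %g\n", x$u, x$M))
  invisible(x)
}

#' Convert fixed-final-size parameters to two-type rates
#'
#' @param p a [bozic_params()] object.
#' @param nu neutral mutation rate to attach (the fixed-final-size analysis
#'   does not use one; default 0).
#' @return A [two_type_params()] object.
#' @export
as_two_type_params <- function(p, nu = 0) {
  stopifnot(inherits(p, "bozic_params"))
  two_type_params(a0 = p$b, b0 = p$d, a1 = p$b1, b1 = p$d1, u1 = p$u, nu = nu)
}
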