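#' Logarithmic frequency grid for cumulative spectra
#'
#' @param f_min,f_max grid endpoints, `0 < f_min < f_max <= 1`.
#' @param n number of grid points (default 200, logarithmically spaced).
#' @return Strictly increasing numeric vector of frequencies.
#' @export
sfs_grid <- function(f_min = 0.01, f_max = 1, n = 200L) {
  if (f_min <= 0 || f_max > 1 || f_min >= f_max) {
    stop("need 0 < f_min < f_max <= 1", call. = FALSE)
  }
  exp(seq(log(f_min), log(f_max), length.out = n))
}

#' Empirical cumulative site frequency spectrum
#'
#' Builds the cumulative spectrum `M(f)` = number of mutations with frequency
#' at least `f`, evaluated on a grid. When a `runs` vector is supplied,
#' counts are averaged across runs (mean `M(f)` per grid point), matching the
#' averaged spectra used for the simulation figures. When `classes` is
#' supplied, per-class columns `M_<class>` are added alongside the total.
#'
#' @param frequencies mutation frequencies, each in (0, 1].
#' @param grid strictly increasing frequency grid (default [sfs_grid()]).
#' @param runs optional run labels (same length as `frequencies`): `M(f)` is
#'   then the per-run average. Runs that produced zero mutations still count
#'   toward the average if included in `n_runs`.
#' @param classes optional class labels (same length as `frequencies`).
#' @param n_runs total number of runs for the average (defaults to the
#'   number of distinct values in `runs`; supply explicitly when some runs
#'   yielded no mutations).
#' @return An object of classes `sfs_table` and `data.frame` with columns
#'   `f`, `M` (and `M_<class>` if requested); `M` is nonincreasing in `f`.
#' @examples
#' empirical_sfs(c(0.5, 0.5, 0.25), grid = c(0.25, 0.5, 0.75))
#' @export
empirical_sfs <- function(frequencies, grid = sfs_grid(), runs = NULL,
                          classes = NULL, n_runs = NULL) {
  if (any(frequencies <= 0) || any(frequencies > 1)) {
    stop("frequencies must lie in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  if (is.null(n_runs)) {
    n_runs <- if (is.null(runs)) 1L else length(unique(runs))
  }
  count_geq <- function(x) {
    # M(f) = #(x >= f) for each grid point, via one sort
    length(x) - findInterval(grid, sort(x), left.open = TRUE)
  }
  out <- data.frame(f = grid, M = count_geq(frequencies) / n_runs)
  if (!is.null(classes)) {
    for (cl in unique(as.character(classes))) {
      out[[paste0("M_", cl)]] <-
        count_geq(frequencies[classes == cl]) / n_runs
    }
  }
  structure(out, class = c("sfs_table", "data.frame"), n_runs = n_runs)
}

#' Evaluate a closed-form spectrum on a grid as an `sfs_table`
#'
#' Convenience wrapper turning a vectorized function `f -> M(f)` into the
#' same tabular form as [empirical_sfs()], for plotting or fitting theory
#' curves.
#'
#' @param fun vectorized function of frequency.
#' @param grid frequency grid.
#' @return An `sfs_table`.
#' @examples
#' theory_sfs(function(f) sfs_1a(f, 0.5), grid = sfs_grid(0.05, 0.9))
#' @export
theory_sfs <- function(fun, grid = sfs_grid()) {
  structure(data.frame(f = grid, M = fun(grid)),
            class = c("sfs_table", "data.frame"), n_runs = NA_integer_)
}

window_rows <- function(table, f_min, f_max) {
  stopifnot(is.data.frame(table), all(c("f", "M") %in% names(table)))
  which(table$f >= f_min & table$f <= f_max)
}

new_fit_result <- function(model, slope, intercept, r_squared, f_min, f_max,
                           n_points) {
  structure(list(model = model, slope = slope, intercept = intercept,
                 r_squared = r_squared, f_min = f_min, f_max = f_max,
                 n_points = n_points),
            class = "sfs_fit")
}

#' @export
print.sfs_fit <- function(x, ...) {
  if (x$model == "inverse_f") {
    cat(sprintf(
      "Neutral 1/f fit on [%g, %g] (%d points): M(f) = %.4g / f + %.4g, R^2 = %.4f\n",
      x$f_min, x$f_max, x$n_points, x$slope, x$intercept, x$r_squared))
  } else {
    cat(sprintf(
      "Power-law fit on [%g, %g] (%d points): M(f) = %.4g / f^%.4f, R^2 = %.4f\n",
      x$f_min, x$f_max, x$n_points, exp(x$intercept), x$slope, x$r_squared))
  }
  invisible(x)
}

#' Fit the neutral linear-in-1/f spectrum
#'
#' Ordinary least squares of `M(f)` against `1/f` over a frequency window.
#' Under neutral growth the cumulative spectrum is `mu/f` (mutation at
#' birth) or `nu/(lambda f)` (continuous mutation), so the slope estimates
#' the (scaled) mutation rate and `R^2` near 1 indicates the neutral shape.
#'
#' @param table an `sfs_table`.
#' @param f_min,f_max fitting window (defaults 0.05 and 0.5: below 0.05 the
#'   counts are detection-limited, above 0.5 the `(1-f)^alpha` roll-off of
#'   the selective shape distorts both fits).
#' @return An `sfs_fit` with `model = "inverse_f"`, the `slope` (rate
#'   estimate), `intercept` and `r_squared`.
#' @examples
#' tab <- theory_sfs(function(f) 0.5 / f)
#' fit_inverse_f(tab)$slope # 0.5
#' @export
fit_inverse_f <- function(table, f_min = 0.05, f_max = 0.5) {
  rows <- window_rows(table, f_min, f_max)
  if (length(rows) < 3) {
    stop("need at least 3 grid points in the fitting window", call. = FALSE)
  }
  x <- 1 / table$f[rows]
  y <- table$M[rows]
  fit <- stats::lm(y ~ x)
  # suppressed: summary.lm warns on the "essentially perfect" fits that
  # arise when the table holds an exact closed form
  r2 <- if (stats::var(y) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  new_fit_result("inverse_f", unname(stats::coef(fit)[2]),
                 unname(stats::coef(fit)[1]), r2, f_min, f_max, length(rows))
}

#' Fit the power-law spectrum C/f^beta
#'
#' Ordinary least squares of `log M(f)` against `log f` over a frequency
#' window; returns `beta = -slope` and `C = exp(intercept)`. Under the
#' two-type model the driver-mutation spectrum has `beta = alpha =
#' lambda0/lambda1 < 1`, against `beta = 1` for neutral growth — the
#' package's headline discriminator. Grid points with `M(f) = 0` cannot
#' enter the log fit; they are dropped with a warning.
#'
#' @inheritParams fit_inverse_f
#' @return An `sfs_fit` with `model = "power_law"`; `slope` holds `beta`.
#' @examples
#' tab <- theory_sfs(function(f) 2 / f)
#' fit_power_law(tab)$slope # 1
#' @export
fit_power_law <- function(table, f_min = 0.05, f_max = 0.5) {
  rows <- window_rows(table, f_min, f_max)
  zero <- table$M[rows] <= 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " grid points with M(f) = 0 from the ",
            "log-log fit", call. = FALSE)
    rows <- rows[!zero]
  }
  if (length(rows) < 3) {
    stop("need at least 3 grid points with positive counts in the window",
         call. = FALSE)
  }
  x <- log(table$f[rows])
  y <- log(table$M[rows])
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  new_fit_result("power_law", -unname(stats::coef(fit)[2]),
                 unname(stats::coef(fit)[1]), r2, f_min, f_max, length(rows))
}

#' Read and write cumulative spectra and frequency tables
#'
#' Spectra are stored as two-column tab-separated text (`f`, `M`, header
#' line, '.' decimal); variant-allele-frequency tables as two columns
#' (`id`, `frequency`).
#'
#' @param table an `sfs_table` (for writing).
#' @param path file path.
#' @return `read_sfs_table` returns an `sfs_table`; `read_vaf_table` a
#'   data.frame with `id` and `frequency`; the writers return the path,
#'   invisibly.
#' @export
write_sfs_table <- function(table, path) {
  stopifnot(inherits(table, "sfs_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sfs_table
#' @export
read_sfs_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("f", "M") %in% names(d))) {
    stop("expected columns 'f' and 'M' in ", path, call. = FALSE)
  }
  structure(d, class = c("sfs_table", "data.frame"), n_runs = NA_integer_)
}

#' @rdname write_sfs_table
#' @export
read_vaf_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("id", "frequency") %in% names(d))) {
    stop("expected columns 'id' and 'frequency' in ", path, call. = FALSE)
  }
  if (any(d$frequency <= 0) || any(d$frequency > 1)) {
    stop("frequencies must lie in (0, 1]", call. = FALSE)
  }
  d
}
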