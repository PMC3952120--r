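#' Agreement statistics between experimental and predicted binding energies
#'
#' `pearson_r()` is the product-moment correlation between the known (`x`)
#' and predicted (`y`) values; `standard_error()` is the regression-style
#' standard error of the predictions,
#' `SE = sqrt((1 - r^2) * sum((y - mean(y))^2) / (n - 2))`;
#' `fit_regression()` is the ordinary least-squares line of `y` on `x`
#' (optionally forced through the origin); `evaluate_predictions()` bundles
#' all of them.
#'
#' @param data A data frame of paired observations.
#' @param x,y Columns (tidy-eval) holding the experimental and predicted
#'   values; default `x` and `y`.
#' @param form For `standard_error()`: `"moment"` evaluates the centred
#'   form above; `"sums"` evaluates the algebraically identical
#'   raw-sums form (both are exposed so they can be checked against each
#'   other).
#' @param through_origin For `fit_regression()`: force a zero intercept.
#' @return `pearson_r()` and `standard_error()`: a scalar.
#'   `fit_regression()`: named vector `c(slope, intercept)`.
#'   `evaluate_predictions()`: an `fb_eval` with fields `r`, `se`, `slope`,
#'   `intercept`, `n` (see [glance()]).
#' @export
#' @examples
#' d <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 4))
#' pearson_r(d)
#' standard_error(d)
#' fit_regression(d)
pearson_r <- function(data, x = x, y = y) {
  v <- eval_pair(data, enquo(x), enquo(y))
  if (v$n < 3) abort("need at least 3 pairs for a correlation")
  if (stats::var(v$x) == 0 || stats::var(v$y) == 0) {
    abort("zero variance in x or y; correlation undefined")
  }
  stats::cor(v$x, v$y)
}

#' @rdname pearson_r
#' @export
standard_error <- function(data, x = x, y = y,
                           form = c("moment", "sums")) {
  form <- match.arg(form)
  v <- eval_pair(data, enquo(x), enquo(y))
  n <- v$n
  if (n < 3) abort("need at least 3 pairs for a standard error")
  if (form == "moment") {
    r <- stats::cor(v$x, v$y)
    syy <- sum((v$y - mean(v$y))^2)
    sqrt((1 - r^2) * syy / (n - 2))
  } else {
    sx <- sum(v$x); sy <- sum(v$y)
    sxx <- sum(v$x^2); syy <- sum(v$y^2); sxy <- sum(v$x * v$y)
    inner <- n * syy - sy^2 - (n * sxy - sx * sy)^2 / (n * sxx - sx^2)
    sqrt(inner / (n * (n - 2)))
  }
}

#' @rdname pearson_r
#' @export
fit_regression <- function(data, x = x, y = y, through_origin = FALSE) {
  v <- eval_pair(data, enquo(x), enquo(y))
  if (v$n < 2) abort("need at least 2 pairs to fit a line")
  if (stats::var(v$x) == 0) abort("degenerate x: zero variance")
  if (through_origin) {
    fit <- lm(y ~ x + 0, data = v)
    c(slope = unname(coef(fit)[1]), intercept = 0)
  } else {
    fit <- lm(y ~ x, data = v)
    c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  }
}

#' @rdname pearson_r
#' @export
evaluate_predictions <- function(data, x = x, y = y,
                                 through_origin = FALSE) {
  v <- eval_pair(data, enquo(x), enquo(y))
  v <- tibble(x = v$x, y = v$y)
  line <- fit_regression(v, through_origin = through_origin)
  structure(list(r = pearson_r(v), se = standard_error(v),
                 slope = unname(line["slope"]),
                 intercept = unname(line["intercept"]), n = nrow(v)),
            class = "fb_eval")
}

eval_pair <- function(data, xq, yq) {
  if (!is.data.frame(data)) abort("data must be a data frame of pairs")
  x <- eval_tidy(xq, data)
  y <- eval_tidy(yq, data)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("paired observations must be finite")
  }
  list(x = x, y = y, n = length(x))
}

#' @export
print.fb_eval <- function(x, ...) {
  cat(sprintf("n = %d pairs\nr = %.2f\nSE = %.2f (units of y)\n",
              x$n, x$r, x$se))
  cat(sprintf("fitted line: y = %.2fx %+.2f\n", x$slope, x$intercept))
  invisible(x)
}

#' @rdname tidy.fb_potential
#' @method tidy fb_eval
#' @export
tidy.fb_eval <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' @rdname tidy.fb_potential
#' @method glance fb_eval
#' @export
glance.fb_eval <- function(x, ...) {
  tibble(r = x$r, se = x$se, slope = x$slope, intercept = x$intercept,
         n = x$n)
}

#' Published 10-complex benchmark table
#'
#' The head-to-head benchmark set of ten protein-ligand complexes with
#' experimental `pk_d` values, the competing empirical scoring function's
#' predicted `pk_d`, the experimental binding free energy (from `pk_d` via
#' the 0.592 kcal/mol conversion) and the four-body model's predicted
#' binding free energy.
#'
#' @return A tibble with columns `pdb`, `pkd_exp`, `pkd_xscore`, `dg_exp`,
#'   `dg_model`.
#' @export
load_benchmark_complexes <- function() {
  path <- system.file("extdata", "xscore_benchmark_10.tsv",
                      package = "fourbody", mustWork = TRUE)
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
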