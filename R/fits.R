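#' Titration datasets
#'
#' A titration table (concentration `x`, normalized signal `y`, optional
#' per-point `sd`, optional `replicate`) with the concentration unit and
#' basis (monomer or hexamer) recorded explicitly, since published fits mix
#' both conventions.
#'
#' @param x Concentrations (>= 0).
#' @param y Normalized anisotropy or fraction bound.
#' @param sd Optional per-point standard deviations.
#' @param replicate Optional replicate index.
#' @param unit Concentration unit (e.g. `"uM"`, `"nM"`).
#' @param basis `"monomer"` or `"hexamer"`.
#' @return A tibble of class `titration_data` with `unit`/`basis` attrs.
#' @export
titration_data <- function(x, y, sd = NULL, replicate = NULL,
                           unit = "uM", basis = c("monomer", "hexamer")) {
  basis <- match.arg(basis)
  if (any(x < 0)) abort("concentrations must be >= 0")
  if (!all(is.finite(y))) abort("signal values must be finite")
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(sd)) out$sd <- as.numeric(sd)
  if (!is.null(replicate)) out$replicate <- replicate
  out <- dplyr::arrange(out, .data$x)
  structure(out, class = c("titration_data", class(out)),
            unit = unit, basis = basis)
}

# --- fitted-model container ---------------------------------------------

new_binding_fit <- function(fit, model, data, extra = list(),
                            unit = NULL, basis = NULL) {
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    rep(NA_real_, length(est))
  })
  z <- qnorm(0.975)
  coefs <- tibble::tibble(term = names(est), estimate = unname(est),
                          std_error = unname(se),
                          conf_low = unname(est - z * se),
                          conf_high = unname(est + z * se))
  structure(list(fit = fit, model = model, coefs = coefs, data = data,
                 extra = extra, unit = unit, basis = basis,
                 rss = sum(stats::residuals(fit)^2)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit: ", x$model, ">\n", sep = "")
  print(as.data.frame(x$coefs), row.names = FALSE, digits = 4)
  if (length(x$extra) > 0) {
    for (nm in names(x$extra)) {
      if (is.numeric(x$extra[[nm]]) && length(x$extra[[nm]]) == 1) {
        cat("  ", nm, " = ", format(x$extra[[nm]], digits = 4), "\n", sep = "")
      }
    }
  }
  invisible(x)
}

#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) x$coefs

#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, n = nrow(x$data),
                 sigma = sqrt(x$rss / max(1, nrow(x$data) - nrow(x$coefs))),
                 converged = isTRUE(x$fit$convInfo$isConv %||% TRUE))
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  stats::predict(object$fit, newdata = newdata)
}

coef_of <- function(fit, term) {
  fit$coefs$estimate[fit$coefs$term == term]
}

# Trust-region NLS with a coarse multi-start fallback.
nls_multistart <- function(formula, data, start, grids = NULL) {
  first <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (!inherits(first, "error")) return(first)
  if (!is.null(grids)) {
    combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    for (i in seq_len(nrow(combos))) {
      st <- utils::modifyList(start, as.list(combos[i, , drop = FALSE]))
      alt <- tryCatch(
        minpack.lm::nlsLM(formula, data = data, start = st,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL
      )
      if (!is.null(alt)) return(alt)
    }
  }
  abort(paste0("nonlinear fit failed to converge: ",
               conditionMessage(first)))
}

check_curvature <- function(y) {
  if (diff(range(y)) < 1e-8 * max(1, abs(mean(y)))) {
    abort("no curvature in the data (signal is constant); refusing to fit")
  }
}

# --- fitters -------------------------------------------------------------

#' Single-site binding isotherm fit
#'
#' Fits the hyperbolic isotherm `y = Ka x / (1 + Ka x)` by nonlinear least
#' squares and reports the association constant Ka and the dissociation
#' constant Kd = 1/Ka (standard error by the delta method), in the
#' dataset's concentration unit and basis.
#'
#' @param data Data frame with columns `x` (concentration) and `y`
#'   (normalized signal); a [titration_data()] carries its unit/basis
#'   through to the fit.
#' @return A `binding_fit` with terms `Ka` and `Kd`.
#' @export
fit_single_site <- function(data) {
  d <- tibble::as_tibble(data)[, c("x", "y")]
  if (nrow(d) < 5) abort("need at least 5 titration points")
  check_curvature(d$y)
  half <- d$x[which.min(abs(d$y - 0.5 * max(d$y)))]
  ka0 <- 1 / max(half, min(d$x[d$x > 0], na.rm = TRUE))
  fit <- nls_multistart(y ~ Ka * x / (1 + Ka * x), d, list(Ka = ka0),
                        grids = list(Ka = 10^seq(-4, 4)))
  out <- new_binding_fit(fit, "single_site", d,
                         unit = attr(data, "unit"),
                         basis = attr(data, "basis"))
  ka <- coef_of(out, "Ka")
  se_ka <- out$coefs$std_error[out$coefs$term == "Ka"]
  z <- qnorm(0.975)
  kd <- 1 / ka
  se_kd <- se_ka / ka^2
  out$coefs <- dplyr::bind_rows(
    out$coefs,
    tibble::tibble(term = "Kd", estimate = kd, std_error = se_kd,
                   conf_low = kd - z * se_kd, conf_high = kd + z * se_kd)
  )
  out
}

#' Hill binding fit
#'
#' Fits `y = x^n / (Kd^n + x^n)`; the signal is half-maximal at `x = Kd`
#' for any Hill coefficient n. With `fix_n = 1` this reduces exactly to
#' the single-site isotherm with `Ka = 1/Kd`.
#'
#' @inheritParams fit_single_site
#' @param fix_n Optional fixed Hill coefficient; default `NULL` fits n.
#' @return A `binding_fit` with terms `Kd` and `n`.
#' @export
fit_hill <- function(data, fix_n = NULL) {
  d <- tibble::as_tibble(data)[, c("x", "y")]
  if (nrow(d) < 5) abort("need at least 5 titration points")
  check_curvature(d$y)
  kd0 <- max(d$x[which.min(abs(d$y - 0.5 * max(d$y)))],
             min(d$x[d$x > 0], na.rm = TRUE))
  if (is.null(fix_n)) {
    fit <- nls_multistart(y ~ x^n / (Kd^n + x^n), d,
                          list(Kd = kd0, n = 1),
                          grids = list(Kd = kd0 * 10^seq(-2, 2),
                                       n = c(0.5, 1, 2)))
    out <- new_binding_fit(fit, "hill", d, unit = attr(data, "unit"),
                           basis = attr(data, "basis"))
  } else {
    n_fixed <- fix_n
    fit <- nls_multistart(y ~ x^n_fixed / (Kd^n_fixed + x^n_fixed), d,
                          list(Kd = kd0),
                          grids = list(Kd = kd0 * 10^seq(-2, 2)))
    out <- new_binding_fit(fit, "hill", d,
                           extra = list(fix_n = n_fixed),
                           unit = attr(data, "unit"),
                           basis = attr(data, "basis"))
    out$coefs <- dplyr::bind_rows(
      out$coefs,
      tibble::tibble(term = "n", estimate = n_fixed, std_error = 0,
                     conf_low = n_fixed, conf_high = n_fixed)
    )
  }
  out
}

#' Competition (IC50) fit
#'
#' Fits the displacement curve
#' `y = minY + (maxY - minY) / (1 + (x / IC50)^n)`: signal decreases from
#' `maxY` toward `minY` as competitor displaces the probe, with midpoint at
#' `x = IC50`. Monotonically increasing data are rejected.
#'
#' @inheritParams fit_single_site
#' @return A `binding_fit` with terms `IC50`, `n`, `minY`, `maxY`.
#' @export
fit_ic50 <- function(data) {
  d <- tibble::as_tibble(data)[, c("x", "y")]
  if (nrow(d) < 5) abort("need at least 5 competition points")
  check_curvature(d$y)
  d <- dplyr::arrange(d, .data$x)
  lo <- mean(head(d$y, 2))
  hi <- mean(utils::tail(d$y, 2))
  if (hi > lo) {
    abort("signal increases with competitor; competition must decrease toward minY")
  }
  mid <- (max(d$y) + min(d$y)) / 2
  ic0 <- max(d$x[which.min(abs(d$y - mid))],
             min(d$x[d$x > 0], na.rm = TRUE))
  fit <- nls_multistart(
    y ~ minY + (maxY - minY) / (1 + (x / IC50)^n), d,
    list(minY = min(d$y), maxY = max(d$y), IC50 = ic0, n = 1),
    grids = list(IC50 = ic0 * 10^seq(-2, 2), n = c(0.5, 1, 2))
  )
  new_binding_fit(fit, "ic50", d, unit = attr(data, "unit"),
                  basis = attr(data, "basis"))
}

#' Exponential progress-curve fit
#'
#' Fits annealing progress curves to a single-exponential
#' `y = A (1 - exp(-k t)) + c` or double-exponential rate equation. For a
#' double fit the dominant (larger-amplitude) rate is reported as `k_obs`.
#'
#' @param curve Data frame with columns `t` (seconds) and `y` (signal).
#' @param order `"single"` or `"double"`.
#' @return A `binding_fit`; `$extra$k_obs` holds the observed rate.
#' @export
fit_exponential <- function(curve, order = c("single", "double")) {
  order <- match.arg(order)
  d <- tibble::as_tibble(curve)
  if ("time" %in% names(d) && !"t" %in% names(d)) names(d)[names(d) == "time"] <- "t"
  d <- d[, c("t", "y")]
  if (nrow(d) < 10) abort("need at least 10 time points")
  check_curvature(d$y)
  c0 <- d$y[1]
  a0 <- d$y[nrow(d)] - c0
  t63 <- d$t[which.min(abs((d$y - c0) - 0.632 * a0))]
  k0 <- 1 / max(t63, min(d$t[d$t > 0]))
  if (order == "single") {
    fit <- nls_multistart(y ~ A * (1 - exp(-k * t)) + c, d,
                          list(A = a0, k = k0, c = c0),
                          grids = list(k = k0 * 10^seq(-2, 2)))
    out <- new_binding_fit(fit, "exponential_single", d)
    out$extra$k_obs <- coef_of(out, "k")
  } else {
    fit <- nls_multistart(
      y ~ A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t)) + c, d,
      list(A1 = 0.7 * a0, k1 = k0, A2 = 0.3 * a0, k2 = k0 / 10, c = c0),
      grids = list(k1 = k0 * 10^seq(-1, 1), k2 = k0 * 10^seq(-3, 0))
    )
    out <- new_binding_fit(fit, "exponential_double", d)
    a <- abs(c(coef_of(out, "A1"), coef_of(out, "A2")))
    k <- c(coef_of(out, "k1"), coef_of(out, "k2"))
    out$extra$k_obs <- k[which.max(a)]
  }
  if (out$extra$k_obs <= 0) abort("fitted rate is not positive")
  out
}

#' Ordinary least-squares line with adjusted R-squared
#'
#' Simple linear regression `y = slope x + intercept`, reporting the
#' adjusted R-squared `1 - (1 - R^2)(n - 1)/(n - 2)` and the two-sided
#' t-test p-value of the slope — the summary used to relate per-residue
#' interaction energies to measured binding free energies.
#'
#' @param data Data frame with columns `x` and `y` (n >= 3; `x` must vary).
#' @return One-row tibble: `slope`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `p_value`, `n`.
#' @export
linear_fit <- function(data) {
  d <- tibble::as_tibble(data)[, c("x", "y")]
  if (nrow(d) < 3) abort("need at least 3 points")
  if (stats::var(d$x) == 0) abort("x has zero variance")
  fit <- lm(y ~ x, data = d)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(coef(fit)["x"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    p_value = sm$coefficients["x", "Pr(>|t|)"],
    n = nrow(d)
  )
}
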