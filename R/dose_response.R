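#' Four-parameter logistic dose-response fitting
#'
#' Fits the standard 4PL inhibition curve
#' \deqn{f(d) = lower + \frac{upper - lower}{1 + (d/EC_{50})^{hill}}}
#' to normalized single-agent responses (vehicle = 1) by least squares, with
#' multi-start initialization: the EC50 grid visits every tested non-zero
#' dose, hill starts at 0.5, 1 and 2, and the asymptotes start at the response
#' extrema. Each start is refined by bounded Levenberg-Marquardt (asymptotes
#' in [0, 1.5] — supra-vehicle responses are permitted — and hill > 0); the
#' lowest residual sum of squares wins, ties broken by the smallest |hill|.
#'
#' A response vector that is constant across doses yields a flat fit
#' (`lower = upper = mean`, `hill = NA`, `rss` of the constant model) which
#' downstream IC computations report as `not_reached`.
#'
#' @param doses dose vector in micromolar (zero allowed; at least 4 distinct
#'   non-zero doses required).
#' @param responses normalized responses, same length as `doses`.
#' @return An object of class `dose_response_fit`: list with `lower`, `upper`,
#'   `log10_ec50`, `hill`, `rss`, `converged`, and the data.
#' @export
fit_4pl <- function(doses, responses) {
  if (length(doses) != length(responses)) abort("doses/responses length mismatch")
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  nz <- sort(unique(doses[doses > 0]))
  if (length(nz) < 4) abort("need at least 4 distinct non-zero doses")

  if (diff(range(responses)) < 1e-12) {
    m <- mean(responses)
    return(structure(list(lower = m, upper = m, log10_ec50 = NA_real_,
                          hill = NA_real_, rss = sum((responses - m)^2),
                          converged = TRUE, doses = doses,
                          responses = responses),
                     class = "dose_response_fit"))
  }

  upper0 <- min(max(responses), 1.5)
  lower0 <- max(min(responses), 0)
  starts <- expand.grid(le = log10(nz), hill = c(0.5, 1, 2))
  lb <- c(lower = 0, upper = 0, le = log10(min(nz)) - 3, hill = 0.05)
  ub <- c(lower = 1.5, upper = 1.5, le = log10(max(nz)) + 3, hill = 10)

  resid_fun <- function(par) {
    responses - (par[1] + (par[2] - par[1]) /
                   (1 + (doses / 10^par[3])^par[4]))
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(lower = lower0, upper = upper0,
                le = starts$le[s], hill = starts$hill[s]),
        lower = lb, upper = ub, fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    cf <- fit$par
    better <- is.null(best) ||
      rss < best$rss - 1e-15 ||
      (abs(rss - best$rss) <= 1e-15 && abs(cf[["hill"]]) < abs(best$hill))
    if (better) {
      best <- list(lower = cf[["lower"]], upper = cf[["upper"]],
                   le = cf[["le"]], hill = cf[["hill"]], rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(lower = NA_real_, upper = NA_real_,
                          log10_ec50 = NA_real_, hill = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          doses = doses, responses = responses),
                     class = "dose_response_fit"))
  }
  structure(list(lower = best$lower, upper = best$upper,
                 log10_ec50 = best$le, hill = best$hill, rss = best$rss,
                 converged = TRUE, doses = doses, responses = responses),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> lower=%.4g upper=%.4g log10(EC50)=%.4g hill=%.4g rss=%.3g%s\n",
    x$lower, x$upper, x$log10_ec50, x$hill, x$rss,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Predict normalized response from a fitted 4PL curve
#'
#' @param object a `dose_response_fit`.
#' @param doses doses in micromolar.
#' @param ... unused.
#' @return Numeric vector of fitted responses.
#' @export
predict.dose_response_fit <- function(object, doses, ...) {
  if (is.na(object$hill)) return(rep(object$upper, length(doses)))
  ec50 <- 10^object$log10_ec50
  object$lower + (object$upper - object$lower) /
    (1 + (doses / ec50)^object$hill)
}

#' Inhibitory concentration at a given level, censored to the tested range
#'
#' Solves the fitted 4PL analytically for the dose at which the response
#' equals `1 - level` (e.g. IC20 = dose where relative viability is 0.8).
#' The result is censored to the tested dose range: doses below it are
#' reported as `below_range`, above it as `above_range`, and when the curve
#' never crosses the target level (target outside the open asymptote interval)
#' the status is `not_reached` — the screen's "no IC20 could be calculated".
#'
#' @param fit a converged `dose_response_fit`.
#' @param level inhibition fraction in (0, 1); 0.2 for IC20.
#' @param dose_range tested dose range in micromolar (default 0.01-20).
#' @return An object of class `censored_ic`: list with `status` (one of
#'   `"value"`, `"below_range"`, `"above_range"`, `"not_reached"`), `dose`
#'   (micromolar, `NA` unless status is `"value"`) and `level`.
#' @export
ic_level <- function(fit, level = 0.2, dose_range = c(0.01, 20)) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!fit$converged) abort("fit did not converge")
  if (!(level > 0 && level < 1)) abort("level must be in (0, 1)")
  mk <- function(status, dose = NA_real_) {
    structure(list(status = status, dose = dose, level = level),
              class = "censored_ic")
  }
  target <- 1 - level
  if (is.na(fit$hill) ||
      !(target > fit$lower && target < fit$upper)) {
    return(mk("not_reached"))
  }
  ratio <- (fit$upper - target) / (target - fit$lower)
  dose <- 10^fit$log10_ec50 * ratio^(1 / fit$hill)
  if (dose < dose_range[1]) return(mk("below_range"))
  if (dose > dose_range[2]) return(mk("above_range"))
  mk("value", dose)
}

#' @export
print.censored_ic <- function(x, ...) {
  lab <- switch(x$status, value = sprintf("%.4g uM", x$dose),
                below_range = "< dose range", above_range = "> dose range",
                not_reached = "NA (level not reached)")
  cat(sprintf("IC%d: %s\n", round(x$level * 100), lab))
  invisible(x)
}

#' Normalized area under a fitted dose-response curve
#'
#' Mean fitted response over a uniform grid in log10 dose across the tested
#' range (trapezoid rule on 201 points, divided by the log-range width).
#' The result is unit-free and bounded: 1 for a drug with no effect,
#' approaching the lower asymptote for a maximally effective drug, so AUC is
#' comparable across drugs with different potencies.
#'
#' @param fit a converged `dose_response_fit`.
#' @param dose_range tested dose range in micromolar.
#' @param n_grid number of grid points (odd values give an exact midpoint).
#' @return Numeric scalar, the mean-viability AUC.
#' @export
auc <- function(fit, dose_range = c(0.01, 20), n_grid = 201) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!fit$converged) abort("fit did not converge")
  if (dose_range[1] <= 0 || dose_range[2] <= dose_range[1]) {
    abort("degenerate dose range")
  }
  lg <- seq(log10(dose_range[1]), log10(dose_range[2]), length.out = n_grid)
  f <- predict(fit, 10^lg)
  dx <- lg[2] - lg[1]
  trap <- sum((f[-1] + f[-n_grid]) / 2) * dx
  trap / (lg[n_grid] - lg[1])
}

#' Fit dose-response summaries for every single-agent curve in a screen
#'
#' Groups vehicle-normalized single-agent wells (one drug, the other slot
#' empty) by cell line, culture format, drug and readout; fits a 4PL to each
#' group and reports the censored IC at `level` and the log-dose AUC.
#'
#' @param normalized tibble from [normalize_dataset()].
#' @param readout readout to summarise (default `"viability"`).
#' @param level inhibition fraction for the censored IC (default 0.2).
#' @param dose_range tested dose range in micromolar.
#' @return Tibble, one row per (cell_line, culture_format, drug, readout):
#'   4PL parameters, `rss`, `converged`, `ic_status`, `ic_dose`, `auc`.
#' @export
summarize_dose_response <- function(normalized, readout = "viability",
                                    level = 0.2, dose_range = c(0.01, 20)) {
  ro <- readout
  sa <- filter(normalized, .data$readout == ro, .data$role == "treatment",
               .data$drug_b == "", .data$drug_a != "")
  if (nrow(sa) == 0) abort(sprintf("no single-agent wells for readout '%s'", ro))
  sa |>
    group_by(.data$cell_line, .data$culture_format, .data$drug_a,
             .data$readout) |>
    summarise(.fit = list(fit_4pl(.data$dose_a, .data$value_norm)),
              .groups = "drop") |>
    mutate(
      lower = vapply(.data$.fit, `[[`, double(1), "lower"),
      upper = vapply(.data$.fit, `[[`, double(1), "upper"),
      log10_ec50 = vapply(.data$.fit, `[[`, double(1), "log10_ec50"),
      hill = vapply(.data$.fit, `[[`, double(1), "hill"),
      rss = vapply(.data$.fit, `[[`, double(1), "rss"),
      converged = vapply(.data$.fit, `[[`, logical(1), "converged"),
      .ic = purrr::map(.data$.fit, ic_level, level = level,
                       dose_range = dose_range),
      ic_level = level,
      ic_status = vapply(.data$.ic, `[[`, character(1), "status"),
      ic_dose = vapply(.data$.ic, `[[`, double(1), "dose"),
      auc = vapply(.data$.fit, auc, double(1), dose_range = dose_range)
    ) |>
    select(-".fit", -".ic") |>
    rename(drug = "drug_a")
}
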