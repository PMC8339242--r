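#' Construct an abundance time series
#'
#' Validated container for one strain's abundance trajectory under one culture
#' condition: strictly increasing sampling times (hours) and positive
#' abundances (qPCR scale or any positive unit). At least six time points are
#' required so that even the four-parameter Richards fit has residual degrees
#' of freedom.
#'
#' @param time sampling times in hours, strictly increasing.
#' @param abundance positive abundance values, same length.
#' @param strain_id,condition,pair_id series metadata; `condition` must be
#'   `"monoculture"` or `"coculture"` when supplied.
#' @return A data frame of class `abundance_series` with columns `time` and
#'   `abundance` and the metadata stored as attributes.
#' @export
abundance_series <- function(time, abundance, strain_id = NA_character_,
                             condition = NA_character_,
                             pair_id = NA_character_) {
  if (length(time) != length(abundance)) stop("time and abundance lengths differ", call. = FALSE)
  if (length(time) < 6L) stop("need at least 6 time points", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(abundance)) || any(abundance <= 0)) {
    stop("abundances must be finite and strictly positive", call. = FALSE)
  }
  if (!is.na(condition) && !condition %in% c("monoculture", "coculture")) {
    stop("condition must be 'monoculture' or 'coculture'", call. = FALSE)
  }
  structure(data.frame(time = as.numeric(time), abundance = as.numeric(abundance)),
            strain_id = strain_id, condition = condition, pair_id = pair_id,
            class = c("abundance_series", "data.frame"))
}

#' Evaluate a Zwietering-parameterized sigmoid growth curve
#'
#' The three classical growth equations in the reparameterization whose
#' parameters are directly interpretable: asymptote `A` (abundance units),
#' maximum specific growth rate `mu_m` (abundance per hour, the slope at the
#' inflection tangent) and lag time `lam` (hours, the intercept of that
#' tangent with the baseline). Richards adds a shape `nu`; `nu = 1` recovers
#' the logistic exactly and `nu -> 0` the Gompertz.
#'
#' @param t times (hours).
#' @param model `"gompertz"`, `"logistic"` or `"richards"`.
#' @param A,mu_m,lam curve parameters (see Description).
#' @param nu Richards shape (ignored by the other models).
#' @return Curve values at `t`.
#' @export
growth_curve <- function(t, model = c("logistic", "gompertz", "richards"),
                         A, mu_m, lam, nu = 1) {
  model <- match.arg(model)
  switch(model,
    logistic = A / (1 + exp(4 * mu_m / A * (lam - t) + 2)),
    gompertz = A * exp(-exp(mu_m * exp(1) / A * (lam - t) + 1)),
    richards = {
      k <- mu_m / A * (1 + nu)^(1 + 1 / nu)
      A * (1 + nu * exp(1 + nu) * exp(k * (lam - t)))^(-1 / nu)
    })
}

.n_params <- c(logistic = 3L, gompertz = 3L, richards = 4L)

## deterministic multi-start multipliers applied to (mu_m, lam) inits
.restart_grid <- rbind(c(1, 1), c(0.5, 1), c(2, 1), c(1, 0.5),
                       c(1, 1.5), c(0.6, 1.4))

.init_growth <- function(time, value) {
  A0 <- max(value)
  slopes <- diff(value) / diff(time)
  i <- which.max(slopes)
  mu0 <- max(slopes[i], 1e-6)
  tm <- (time[i] + time[i + 1]) / 2
  vm <- (value[i] + value[i + 1]) / 2
  lam0 <- max(tm - vm / mu0, 0)
  list(A = A0, mu_m = mu0, lam = lam0)
}

#' Fit a sigmoid growth model to an abundance series
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of one Zwietering-form growth equation, with a
#' deterministic multi-start: a tangent-based initial guess plus five fixed
#' rescalings of the rate and lag guesses; the converged fit with the lowest
#' residual sum of squares wins. Fitting is on the raw abundance scale by
#' default; set `log_scale = TRUE` to fit `log(abundance)` against the log of
#' the curve.
#'
#' @param series an [abundance_series] (or data frame with `time` and
#'   `abundance` columns).
#' @param model `"logistic"`, `"gompertz"` or `"richards"`.
#' @param log_scale fit on the log-abundance scale.
#' @return Object of class `growth_fit`: list with `model`, `A`, `mu_m`,
#'   `lam`, `nu` (NA unless Richards), `rss`, `n`, `data`, `log_scale` and
#'   `convergence` information. Errors (class `hawkdove_fit_error`) on
#'   degenerate input or non-convergence of every start.
#' @examples
#' t <- c(seq(0, 24, 2), seq(28, 36, 4))
#' y <- growth_curve(t, "logistic", A = 1, mu_m = 0.2, lam = 4)
#' fit_growth(abundance_series(t, pmax(y, 1e-9)), "logistic")
#' @export
fit_growth <- function(series, model = c("logistic", "gompertz", "richards"),
                       log_scale = FALSE) {
  model <- match.arg(model)
  if (!is.data.frame(series) || !all(c("time", "abundance") %in% names(series))) {
    stop("series must have 'time' and 'abundance' columns", call. = FALSE)
  }
  time <- series$time; value <- series$abundance
  p <- .n_params[[model]]
  if (length(time) <= p) {
    stop("fewer time points (", length(time), ") than needed for a ", model,
         " fit", call. = FALSE)
  }
  if (stats::sd(value) < 1e-12 * max(abs(value))) {
    stop(errorCondition(
      "degenerate series: abundance is constant, no growth signal to fit",
      class = c("hawkdove_fit_error", "error", "condition")))
  }
  init <- .init_growth(time, value)
  obs <- if (log_scale) log(value) else value
  pred_fun <- function(par) {
    f <- growth_curve(time, model, A = par[["A"]], mu_m = par[["mu_m"]],
                      lam = par[["lam"]],
                      nu = if (model == "richards") par[["nu"]] else 1)
    if (log_scale) log(pmax(f, 1e-300)) else f
  }
  lower <- c(A = 1e-12, mu_m = 1e-12, lam = 0)
  upper <- c(A = 100 * max(value), mu_m = Inf, lam = max(time))
  if (model == "richards") {
    lower <- c(lower, nu = 0.02); upper <- c(upper, nu = 50)
  }
  best <- NULL
  for (r in seq_len(nrow(.restart_grid))) {
    start <- c(A = init$A, mu_m = init$mu_m * .restart_grid[r, 1],
               lam = min(max(init$lam * .restart_grid[r, 2], 0), max(time)))
    if (model == "richards") start <- c(start, nu = 1)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start,
                         fn = function(par) obs - pred_fun(par),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(par = fit$par, rss = rss)
    }
  }
  if (is.null(best)) {
    stop(errorCondition(
      paste0("growth fit failed to converge for model '", model,
             "' after multi-start"),
      class = c("hawkdove_fit_error", "error", "condition")))
  }
  par <- best$par
  structure(list(model = model,
                 A = par[["A"]], mu_m = par[["mu_m"]], lam = par[["lam"]],
                 nu = if (model == "richards") par[["nu"]] else NA_real_,
                 rss = best$rss, n = length(time),
                 log_scale = log_scale,
                 data = data.frame(time = time, abundance = value),
                 strain_id = attr(series, "strain_id"),
                 condition = attr(series, "condition"),
                 pair_id = attr(series, "pair_id")),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("%s growth fit (n = %d): A = %.4g, mu_m = %.4g /h, lam = %.4g h%s, rss = %.4g\n",
              x$model, x$n, x$A, x$mu_m, x$lam,
              if (!is.na(x$nu)) sprintf(", nu = %.3g", x$nu) else "", x$rss))
  invisible(x)
}

#' @export
fitted.growth_fit <- function(object, times = object$data$time, ...) {
  growth_curve(times, object$model, A = object$A, mu_m = object$mu_m,
               lam = object$lam, nu = if (is.na(object$nu)) 1 else object$nu)
}

.aicc <- function(fit) {
  k <- .n_params[[fit$model]] + 1  # + residual variance
  n <- fit$n
  n * log(fit$rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Select the best growth model among fitted candidates
#'
#' Follows the classical two-stage reasoning: the two three-parameter models
#' (logistic, Gompertz) are non-nested and compared by small-sample AIC
#' (AICc); the winner is then compared to the four-parameter Richards fit --
#' of which both are limiting cases -- with an extra-sum-of-squares F-test at
#' level `alpha`. Richards is retained only when it improves the fit
#' significantly; exact ties in RSS go to the model with fewer parameters.
#'
#' @param fits list of [growth_fit] objects for the same data (any non-empty
#'   subset of the three models).
#' @param alpha significance level of the nested F-test (default 0.05).
#' @return The winning `growth_fit`, with attributes `selection_criterion`
#'   (human-readable record of the comparison) and `f_p_value` when the
#'   F-test was applied.
#' @export
select_model <- function(fits, alpha = 0.05) {
  fits <- Filter(function(f) inherits(f, "growth_fit"), fits)
  if (length(fits) == 0L) {
    stop(errorCondition("no successful growth fits to select from",
                        class = c("hawkdove_fit_error", "error", "condition")))
  }
  names(fits) <- vapply(fits, `[[`, "", "model")
  three <- fits[names(fits) %in% c("logistic", "gompertz")]
  crit <- character(0)
  if (length(three) >= 2L) {
    aic <- vapply(three, .aicc, 0)
    base <- three[[which.min(aic)]]
    crit <- c(crit, sprintf("AICc %s=%.3f %s=%.3f -> %s",
                            names(aic)[1], aic[1], names(aic)[2], aic[2],
                            base$model))
  } else if (length(three) == 1L) {
    base <- three[[1L]]
  } else {
    base <- NULL
  }
  rich <- fits[["richards"]]
  winner <- base
  f_p <- NA_real_
  if (!is.null(rich) && !is.null(base)) {
    n <- base$n
    df2 <- n - .n_params[["richards"]]
    if (rich$rss < base$rss && df2 > 0) {
      f_stat <- ((base$rss - rich$rss) / 1) / (rich$rss / df2)
      f_p <- stats::pf(f_stat, 1, df2, lower.tail = FALSE)
      if (f_p < alpha) winner <- rich
      crit <- c(crit, sprintf("F-test vs richards: F = %.3f, p = %.3g -> %s",
                              f_stat, f_p, winner$model))
    } else {
      crit <- c(crit, "richards did not reduce RSS; simpler model kept")
    }
  } else if (is.null(base)) {
    winner <- rich
    crit <- c(crit, "only richards converged")
  }
  attr(winner, "selection_criterion") <- paste(crit, collapse = "; ")
  attr(winner, "f_p_value") <- f_p
  winner
}

#' Fit all growth models and select the best
#'
#' Convenience wrapper: fits whichever of the three models converge and passes
#' them to [select_model()].
#'
#' @inheritParams fit_growth
#' @param models candidate models.
#' @param alpha F-test level for [select_model()].
#' @return The selected [growth_fit].
#' @export
fit_growth_auto <- function(series, models = c("logistic", "gompertz", "richards"),
                            alpha = 0.05, log_scale = FALSE) {
  fits <- lapply(models, function(m) {
    tryCatch(fit_growth(series, m, log_scale = log_scale),
             error = function(e) NULL)
  })
  select_model(Filter(Negate(is.null), fits), alpha = alpha)
}

#' Partition a fitted growth curve into lag, linear and asymptotic phases
#'
#' The lag phase runs from the start of observation to the fitted lag time
#' `lam`; the linear (exponential-slope) phase from `lam` to the time `t95` at
#' which the fitted curve reaches a fraction `p` (default 95%) of the
#' asymptote `A`; the asymptotic phase beyond `t95`. `t95` is computed by the
#' closed-form inverse of each sigmoid. Every observation time receives
#' exactly one label.
#'
#' @param fit a [growth_fit].
#' @param times times to label (defaults to the fitted data's times).
#' @param p asymptote fraction defining the linear/asymptotic boundary.
#' @return List with `lag_end` (= `lam`), `linear_end` (= `t95`) and `labels`,
#'   a factor over `times` with levels `lag`, `linear`, `asymptotic`. Warns if
#'   the curve does not reach `p * A` inside the observation window (empty
#'   asymptotic phase).
#' @export
partition_phases <- function(fit, times = fit$data$time, p = 0.95) {
  stopifnot(inherits(fit, "growth_fit"), p > 0, p < 1)
  A <- fit$A; mu <- fit$mu_m; lam <- fit$lam
  t95 <- switch(fit$model,
    logistic = lam + A / (4 * mu) * (2 + log(p / (1 - p))),
    gompertz = lam + A / (mu * exp(1)) * (1 - log(-log(p))),
    richards = {
      nu <- fit$nu
      k <- mu / A * (1 + nu)^(1 + 1 / nu)
      lam + log(nu * exp(1 + nu) / (p^(-nu) - 1)) / k
    })
  if (t95 < lam) t95 <- lam  # pathological fits only
  if (t95 > max(times)) {
    warning("fitted curve reaches ", 100 * p,
            "% of the asymptote only beyond the observation window; ",
            "asymptotic phase is empty", call. = FALSE)
  }
  labels <- factor(ifelse(times <= lam, "lag",
                          ifelse(times <= t95, "linear", "asymptotic")),
                   levels = c("lag", "linear", "asymptotic"))
  list(lag_end = lam, linear_end = t95, labels = labels)
}
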