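#' Empirical interaction strengths from co-culture vs monoculture abundances
#'
#' For one pair of strains measured on a shared time grid in both conditions,
#' computes the per-time empirical strengths, with `x(t), y(t)` the co-culture
#' abundances of the more and less abundant strain and `x0(t), y0(t)` the
#' matching monoculture abundances:
#' \itemize{
#'   \item mutualism `Mu(t) = (x/x0 + y/y0)/2` -- above 1 both partners gained
#'     from socialization (cooperation region), below 1 they lost
#'     (competition region);
#'   \item aggression `Ag(t) = (x/y) / (x0/y0)` -- the relative gain of the
#'     dominant strain from socialization;
#'   \item altruism `Al(t) = (y/y0) / (x/x0) = 1/Ag(t)` -- the relative gain
#'     of the subordinate strain.
#' }
#' Which strain plays X is decided by co-culture abundance, per time point by
#' default (`ordering = "per_time"`) or once per pair by mean co-culture
#' abundance (`"per_pair"`); the monoculture never decides.
#'
#' @param abund long-format data frame with columns `pair_id`, `strain_id`,
#'   `condition` (`"monoculture"`/`"coculture"`), `time`, `abundance`,
#'   containing exactly two strains for one pair (filter with `pair`).
#' @param pair optional pair id to select from `abund`.
#' @param ordering `"per_time"` or `"per_pair"` (see Description).
#' @return Data frame of class `strength_series`: `pair_id`, `time`, `x`, `y`,
#'   `x0`, `y0`, `x_id`, `Mu`, `Ag`, `Al`, `region`
#'   (`competition`/`cooperation`/`neutral`).
#' @export
empirical_strengths <- function(abund, pair = NULL,
                                ordering = c("per_time", "per_pair")) {
  ordering <- match.arg(ordering)
  abund <- .validate_abundances(abund)
  if (!is.null(pair)) abund <- abund[abund$pair_id == pair, , drop = FALSE]
  if (length(unique(abund$pair_id)) != 1L) {
    stop("abund must contain exactly one pair (use the 'pair' argument)", call. = FALSE)
  }
  strains <- sort(unique(abund$strain_id))
  if (length(strains) != 2L) stop("a pair needs exactly two strains", call. = FALSE)
  series <- lapply(c("coculture", "monoculture"), function(cond) {
    lapply(strains, function(s) {
      d <- abund[abund$condition == cond & abund$strain_id == s, , drop = FALSE]
      d[order(d$time), , drop = FALSE]
    })
  })
  co <- series[[1L]]; mono <- series[[2L]]
  grids <- lapply(c(co, mono), `[[`, "time")
  if (any(vapply(grids, length, 0L) == 0L)) {
    stop("missing strain x condition series for this pair", call. = FALSE)
  }
  if (!all(vapply(grids[-1], function(g) identical(g, grids[[1L]]), TRUE))) {
    stop("alignment error: the four strain x condition series are not on a shared time grid",
         call. = FALSE)
  }
  tt <- grids[[1L]]
  a_co <- co[[1L]]$abundance; b_co <- co[[2L]]$abundance
  a_mo <- mono[[1L]]$abundance; b_mo <- mono[[2L]]$abundance
  a_is_x <- if (ordering == "per_pair") {
    rep(mean(a_co) >= mean(b_co), length(tt))
  } else {
    a_co >= b_co
  }
  x  <- ifelse(a_is_x, a_co, b_co); y  <- ifelse(a_is_x, b_co, a_co)
  x0 <- ifelse(a_is_x, a_mo, b_mo); y0 <- ifelse(a_is_x, b_mo, a_mo)
  Mu <- (x / x0 + y / y0) / 2
  Ag <- (x / y) / (x0 / y0)
  Al <- (y / y0) / (x / x0)
  structure(data.frame(pair_id = abund$pair_id[1L], time = tt,
                       x = x, y = y, x0 = x0, y0 = y0,
                       x_id = ifelse(a_is_x, strains[1L], strains[2L]),
                       Mu = Mu, Ag = Ag, Al = Al,
                       region = ifelse(Mu > 1, "cooperation",
                                       ifelse(Mu < 1, "competition", "neutral")),
                       stringsAsFactors = FALSE),
            class = c("strength_series", "data.frame"))
}

.validate_abundances <- function(abund) {
  need <- c("pair_id", "strain_id", "condition", "time", "abundance")
  if (!is.data.frame(abund) || !all(need %in% names(abund))) {
    stop("abundance table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(abund$abundance)) || any(abund$abundance <= 0)) {
    stop("abundances must be finite and strictly positive", call. = FALSE)
  }
  if (!all(abund$condition %in% c("monoculture", "coculture"))) {
    stop("condition must be 'monoculture' or 'coculture'", call. = FALSE)
  }
  abund
}

#' Correlate mathematical descriptors with empirical strengths by growth phase
#'
#' Pools all pairs and time points within each growth phase and computes the
#' correlation between each size-based descriptor and its empirical
#' counterpart: `z_mu` vs `Mu`, `z_ag` vs `Ag`, `z_al` vs `Al`.
#'
#' @param data data frame with columns `phase` (factor/character with values
#'   `lag`, `linear`, `asymptotic`), the descriptors `z_mu`, `z_ag`, `z_al`
#'   and the strengths `Mu`, `Ag`, `Al` (e.g. the `$data` component of
#'   [coculture_validation()]).
#' @param method `"pearson"` (default, what the validation reports) or
#'   `"spearman"`.
#' @return Data frame with one row per phase x descriptor: `phase`,
#'   `descriptor`, `strength`, `r`, `p`, `n`. Phase/descriptor cells with
#'   fewer than 3 points or zero variance are skipped with a warning.
#' @export
strength_correlations <- function(data, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pairs <- list(c("z_mu", "Mu"), c("z_ag", "Ag"), c("z_al", "Al"))
  phases <- c("lag", "linear", "asymptotic")
  out <- list()
  for (ph in phases) {
    d <- data[data$phase == ph, , drop = FALSE]
    for (pr in pairs) {
      v1 <- d[[pr[1L]]]; v2 <- d[[pr[2L]]]
      ok <- is.finite(v1) & is.finite(v2)
      v1 <- v1[ok]; v2 <- v2[ok]
      if (length(v1) < 3L) {
        warning("phase '", ph, "', ", pr[1L], " vs ", pr[2L],
                ": fewer than 3 points, skipped", call. = FALSE)
        next
      }
      if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
        warning("phase '", ph, "', ", pr[1L], " vs ", pr[2L],
                ": zero variance, correlation undefined, skipped", call. = FALSE)
        next
      }
      ct <- suppressWarnings(stats::cor.test(v1, v2, method = method))
      out[[length(out) + 1L]] <- data.frame(
        phase = ph, descriptor = pr[1L], strength = pr[2L],
        r = unname(ct$estimate), p = ct$p.value, n = length(v1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Full co-culture validation of the interaction descriptors
#'
#' Runs the validation arm end-to-end for a long-format abundance table of
#' many strain pairs: per pair it (i) computes the empirical strengths `Mu`,
#' `Ag`, `Al` ([empirical_strengths()]); (ii) evaluates the size-based
#' descriptors `z_mu`, `z_ag`, `z_al` from the co-culture abundances
#' `x(t), y(t)` at each shared time point; (iii) fits a growth model to the
#' dominant strain's co-culture trajectory and partitions it into lag, linear
#' and asymptotic phases ([fit_growth_auto()], [partition_phases()]); then
#' pools everything and correlates descriptor against strength within each
#' phase ([strength_correlations()]).
#'
#' Time points where the two co-culture abundances are degenerate (relative
#' difference below `eps`, so the descriptors are undefined) are dropped.
#'
#' @param abund long-format abundance table (see [empirical_strengths()]) with
#'   one or more pairs.
#' @param model growth model for phase partitioning: `"auto"` (model
#'   selection) or one of the three model names.
#' @param method correlation method, see [strength_correlations()].
#' @param ordering X/Y assignment rule, see [empirical_strengths()].
#' @param phase_p asymptote fraction for the linear/asymptotic boundary.
#' @param eps relative degeneracy guard for descriptor evaluation.
#' @return List with `data` (pooled per-pair, per-time table including
#'   `phase`, descriptors and strengths), `correlations` (per-phase
#'   correlation table) and `fits` (named list of per-pair growth fits).
#' @export
coculture_validation <- function(abund, model = "auto",
                                 method = c("pearson", "spearman"),
                                 ordering = c("per_time", "per_pair"),
                                 phase_p = 0.95, eps = 1e-9) {
  method <- match.arg(method)
  ordering <- match.arg(ordering)
  abund <- .validate_abundances(abund)
  pair_ids <- unique(abund$pair_id)
  rows <- list(); fits <- list()
  for (pid in pair_ids) {
    st <- empirical_strengths(abund, pair = pid, ordering = ordering)
    ## descriptors from co-culture abundances at each time point
    keep <- (st$x - st$y) / st$x >= eps
    st <- st[keep, , drop = FALSE]
    if (nrow(st) < 6L) next
    st$z_mu <- .z_mu(st$x, st$y)
    st$z_ag <- .z_ag(st$x, st$y)
    st$z_al <- .z_al(st$x, st$y)
    ## phases from the dominant strain's co-culture trajectory
    dom <- names(which.max(table(st$x_id)))
    d <- abund[abund$pair_id == pid & abund$condition == "coculture" &
                 abund$strain_id == dom, , drop = FALSE]
    d <- d[order(d$time), , drop = FALSE]
    ser <- abundance_series(d$time, d$abundance, strain_id = dom,
                            condition = "coculture", pair_id = pid)
    fit <- tryCatch(
      if (model == "auto") fit_growth_auto(ser) else fit_growth(ser, model),
      error = function(e) NULL)
    if (is.null(fit)) next
    ph <- suppressWarnings(partition_phases(fit, times = st$time, p = phase_p))
    st$phase <- as.character(ph$labels)
    fits[[pid]] <- fit
    rows[[pid]] <- st
  }
  if (length(rows) == 0L) stop("no pair could be processed", call. = FALSE)
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(data = data,
       correlations = strength_correlations(data, method = method),
       fits = fits)
}
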