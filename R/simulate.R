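#' Default co-culture sampling schedule
#'
#' Sampling every 2 hours through the first 24 hours, then every 4 hours to
#' 36 hours -- the measurement schedule the validation design uses.
#'
#' @return Numeric vector of sampling times (hours).
#' @export
default_schedule <- function() c(seq(0, 24, by = 2), seq(28, 36, by = 4))

#' Generate a synthetic trait cohort
#'
#' Draws a cohort of positive, distinct body masses from a log-normal
#' distribution (the shape adult fish mass data typically show), optionally
#' planting a tier structure: tier 1 (top) is drawn tightly around the cohort
#' median and each lower tier's members are placed at a target ratio, drawn
#' uniformly from `bands[[k]]`, of the tier above's mean trait. Planting is
#' rejection-sampled until the realized mean cross-tier dyad ratio of every
#' adjacent tier pair lands inside its band and all cross-tier ratios are
#' below 1; infeasible bands error out.
#'
#' @param n cohort size (ignored when `tiers` is given, where
#'   `n = sum(tiers$sizes)`); default 71, a typical full-sib mapping family.
#' @param meanlog,sdlog log-normal parameters of the trait (default median
#'   500 units, log-sd 0.35).
#' @param tiers optional list with `sizes` (integer vector, top tier first)
#'   and `bands` (list of length `length(sizes) - 1` of `c(lo, hi)` ratio
#'   bands for each adjacent tier pair).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return Data frame with columns `id`, `trait` and `tier` (`NA` without
#'   planted structure; otherwise `"tier1"`, `"tier2"`, ...).
#' @examples
#' cohort <- generate_cohort(n = 71, seed = 1)
#' planted <- generate_cohort(tiers = list(sizes = c(5, 15),
#'                                         bands = list(c(0.70, 0.80))),
#'                            seed = 1)
#' @export
generate_cohort <- function(n = 71, meanlog = log(500), sdlog = 0.35,
                            tiers = NULL, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    if (is.null(tiers)) {
      trait <- stats::rlnorm(n, meanlog, sdlog)
      while (anyDuplicated(trait)) trait <- stats::rlnorm(n, meanlog, sdlog)
      return(data.frame(id = sprintf("ind%02d", seq_len(n)), trait = trait,
                        tier = NA_character_, stringsAsFactors = FALSE))
    }
    sizes <- tiers$sizes; bands <- tiers$bands
    if (length(bands) != length(sizes) - 1L) {
      stop("need one ratio band per adjacent tier pair", call. = FALSE)
    }
    for (b in bands) {
      if (b[1L] >= b[2L] || b[1L] <= 0 || b[2L] >= 1) {
        stop("infeasible tier band: bands must satisfy 0 < lo < hi < 1", call. = FALSE)
      }
    }
    for (attempt in seq_len(500L)) {
      traits <- vector("list", length(sizes))
      ## top tier: tight spread so that cross-tier ratios track the band
      traits[[1L]] <- stats::rlnorm(sizes[1L], meanlog, 0.05)
      ok <- TRUE
      for (k in seq_along(bands)) {
        r <- stats::runif(sizes[k + 1L], bands[[k]][1L], bands[[k]][2L])
        traits[[k + 1L]] <- r * mean(traits[[k]])
        ratios <- as.vector(outer(traits[[k + 1L]], traits[[k]], "/"))
        m <- mean(ratios)
        if (any(ratios >= 1) || m < bands[[k]][1L] || m > bands[[k]][2L]) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        trait <- unlist(traits)
        if (anyDuplicated(trait)) next
        return(data.frame(
          id = sprintf("ind%02d", seq_along(trait)),
          trait = trait,
          tier = rep(paste0("tier", seq_along(sizes)), sizes),
          stringsAsFactors = FALSE))
      }
    }
    stop("could not realize the requested tier bands in 500 attempts; ",
         "bands may be infeasible", call. = FALSE)
  })
}

#' Generate synthetic co-culture and monoculture growth trajectories
#'
#' Simulates, per strain pair, coupled logistic dynamics
#' \deqn{dN_x/dt = r_x N_x (1 - N_x/A_x + a_{xy} N_y/A_y)}
#' (and symmetrically for Y), integrated with \pkg{deSolve}; the monoculture
#' is the exact zero-coupling limit (closed-form logistic with the same
#' parameters). Multiplicative log-normal measurement noise is applied at the
#' sampling times. Positive symmetric coupling inflates both strains'
#' co-culture trajectories, so the empirical mutualism strength `Mu` exceeds
#' 1 past the lag phase; the sign of the coupling is recorded as a
#' ground-truth label.
#'
#' @param n_pairs number of strain pairs (default 100, the validation
#'   experiments' size).
#' @param coupling interaction coefficients: a single value, a vector of
#'   length `n_pairs`, or a length-2 range graded linearly over pairs;
#'   applied symmetrically unless `coupling_yx` is also given.
#' @param coupling_yx optional separate coupling felt by strain Y (same
#'   recycling rules); default equal to `coupling`.
#' @param noise_sd standard deviation of log-normal measurement noise
#'   (default 0.05, i.e. ~5% multiplicative error).
#' @param schedule sampling times in hours (default [default_schedule()]).
#' @param A_x,A_y,r_range ranges (length-2) from which each pair's carrying
#'   capacities and per-capita growth rates are drawn uniformly; X is the
#'   dominant strain by construction (`A_x` above `A_y`).
#' @param n0_frac initial abundance as a fraction of the carrying capacity
#'   (controls the effective lag).
#' @param seed integer seed.
#' @return Long-format data frame with columns `pair_id`, `strain_id`,
#'   `condition`, `time`, `abundance`, with a `truth` attribute (data frame
#'   of per-pair parameters, couplings and interaction label
#'   `mutualistic`/`antagonistic`/`neutral`/`mixed`).
#' @examples
#' cc <- generate_coculture(n_pairs = 3, coupling = 0.3, noise_sd = 0, seed = 1)
#' head(attr(cc, "truth"))
#' @export
generate_coculture <- function(n_pairs = 100, coupling = c(-0.4, 0.6),
                               coupling_yx = NULL, noise_sd = 0.05,
                               schedule = default_schedule(),
                               A_x = c(0.8, 1.5), A_y = c(0.3, 0.6),
                               r_range = c(0.3, 0.4), n0_frac = 0.02, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  a_xy <- .expand_coupling(coupling, n_pairs)
  a_yx <- if (is.null(coupling_yx)) a_xy else .expand_coupling(coupling_yx, n_pairs)
  if (any(a_xy >= 1) || any(a_yx >= 1)) {
    stop("couplings must be below 1 (mutual facilitation >= 1 diverges)", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    rows <- vector("list", n_pairs)
    truth <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      pid <- sprintf("pair%03d", i)
      Ax <- stats::runif(1, A_x[1L], A_x[2L])
      Ay <- stats::runif(1, A_y[1L], A_y[2L])
      rx <- stats::runif(1, r_range[1L], r_range[2L])
      ry <- stats::runif(1, r_range[1L], r_range[2L])
      co <- .integrate_pair(schedule, Ax, Ay, rx, ry, a_xy[i], a_yx[i], n0_frac)
      if (any(co <= 0)) {
        stop("co-culture dynamics produced non-positive abundance for ", pid,
             " (a_xy = ", a_xy[i], ", a_yx = ", a_yx[i], ")", call. = FALSE)
      }
      mono_x <- .logistic_closed(schedule, Ax, rx, n0_frac * Ax)
      mono_y <- .logistic_closed(schedule, Ay, ry, n0_frac * Ay)
      vals <- cbind(co, mono_x, mono_y)
      if (noise_sd > 0) {
        vals <- vals * exp(matrix(stats::rnorm(length(vals), 0, noise_sd),
                                  nrow = nrow(vals)))
      }
      nt <- length(schedule)
      rows[[i]] <- data.frame(
        pair_id = pid,
        strain_id = rep(paste0(pid, c("_X", "_Y", "_X", "_Y")), each = nt),
        condition = rep(c("coculture", "coculture",
                          "monoculture", "monoculture"), each = nt),
        time = rep(schedule, 4L),
        abundance = c(vals[, 1L], vals[, 2L], vals[, 3L], vals[, 4L]),
        stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        pair_id = pid, A_x = Ax, A_y = Ay, r_x = rx, r_y = ry,
        a_xy = a_xy[i], a_yx = a_yx[i],
        label = if (a_xy[i] > 0 && a_yx[i] > 0) "mutualistic"
                else if (a_xy[i] < 0 && a_yx[i] < 0) "antagonistic"
                else if (a_xy[i] == 0 && a_yx[i] == 0) "neutral" else "mixed",
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- do.call(rbind, truth)
    out
  })
}

.expand_coupling <- function(a, n_pairs) {
  if (length(a) == n_pairs) return(a)
  if (length(a) == 1L) return(rep(a, n_pairs))
  if (length(a) == 2L) return(seq(a[1L], a[2L], length.out = n_pairs))
  stop("coupling must have length 1, 2 (range) or n_pairs", call. = FALSE)
}

.integrate_pair <- function(times, Ax, Ay, rx, ry, axy, ayx, n0_frac) {
  deriv <- function(t, state, parms) {
    nx <- state[1L]; ny <- state[2L]
    list(c(rx * nx * (1 - nx / Ax + axy * ny / Ay),
           ry * ny * (1 - ny / Ay + ayx * nx / Ax)))
  }
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::ode(y = c(nx = n0_frac * Ax, ny = n0_frac * Ay),
                      times = tt, func = deriv, parms = NULL)
  sol[match(times, sol[, "time"]), c("nx", "ny"), drop = FALSE]
}

.logistic_closed <- function(t, A, r, n0) {
  A / (1 + (A / n0 - 1) * exp(-r * t))
}

#' Generate a full-sib genotype matrix by Mendelian segregation
#'
#' Per SNP, a segregating parental cross type is drawn (both parents
#' heterozygous `AB x AB`, or one heterozygous parent `AB x AA` / `AA x AB`),
#' and each offspring receives one allele from each parent independently.
#' Genotypes are coded 0/1/2 counting one parental allele, so `AB x AB` SNPs
#' segregate 1:2:1 and single-heterozygote SNPs 1:1 (codes 0/1).
#'
#' @param n number of full sibs.
#' @param m_snps number of SNPs.
#' @param seed integer seed.
#' @param cross_probs probabilities of the three cross types, in the order
#'   `ABxAB`, `ABxAA`, `AAxAB`.
#' @return Integer matrix `n x m_snps` with rownames `sib...` and colnames
#'   `snp...`; attribute `"cross"` records each SNP's cross type.
#' @examples
#' g <- generate_fullsib_genotypes(10, 100, seed = 1)
#' table(attr(g, "cross"))
#' @export
generate_fullsib_genotypes <- function(n, m_snps, seed,
                                       cross_probs = c(ABxAB = 0.5,
                                                       ABxAA = 0.25,
                                                       AAxAB = 0.25)) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n >= 2, m_snps >= 1)
  cross_probs <- cross_probs / sum(cross_probs)
  withr::with_seed(as.integer(seed), {
    cross <- sample(c("ABxAB", "ABxAA", "AAxAB"), m_snps, replace = TRUE,
                    prob = cross_probs)
    g <- matrix(0L, nrow = n, ncol = m_snps,
                dimnames = list(sprintf("sib%03d", seq_len(n)),
                                sprintf("snp%05d", seq_len(m_snps))))
    for (j in seq_len(m_snps)) {
      ## allele contribution of each parent: heterozygous parent transmits
      ## the counted allele with probability 1/2, homozygous AA transmits 0
      p1 <- if (cross[j] %in% c("ABxAB", "ABxAA")) stats::rbinom(n, 1L, 0.5) else 0L
      p2 <- if (cross[j] %in% c("ABxAB", "AAxAB")) stats::rbinom(n, 1L, 0.5) else 0L
      g[, j] <- p1 + p2
    }
    attr(g, "cross") <- cross
    g
  })
}
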