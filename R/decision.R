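#' Break-even size of a smaller dove facing a larger player
#'
#' Solves the break-even between the larger player's dove payoff `x^2 y^2` and
#' hawk payoff `x^2 (x - y)` against a dove opponent, i.e. the positive root of
#' `y^2 + y - x = 0`. At the normalization `x = 1` this is the golden section
#' `phi = (sqrt(5) - 1)/2 = 0.618...`: a larger player does better by
#' exploiting a dove smaller than 62% of its size and by cooperating with one
#' above it.
#'
#' @param x trait value of the larger player (positive; the model normalizes
#'   decisions to `x = 1`, in which units the return value is the critical
#'   size ratio).
#' @return The positive root `(-1 + sqrt(1 + 4 x))/2`.
#' @examples
#' breakeven_larger_vs_dove(1)   # 0.618..., the golden-section threshold
#' breakeven_larger_vs_dove(6)   # 2, exact
#' @export
breakeven_larger_vs_dove <- function(x) {
  .check_positive_x(x)
  (-1 + sqrt(1 + 4 * x)) / 2
}

#' Break-even size of a smaller hawk facing a larger player
#'
#' Solves the break-even between the larger player's dove payoff
#' `y (x - y)^2` and hawk payoff 1 against a hawk opponent: the unique real
#' root of `y (x - y)^2 = 1` with `y > x`. At `x = 1` the root is 1.7549...,
#' i.e. the "smaller" hawk must reversely surpass the larger player by about
#' 75% before non-aggression breaks even -- within the admissible range
#' `0 < y < x` the larger player always meets a hawk with aggression.
#'
#' @param x trait value of the larger player (positive).
#' @param tol absolute convergence tolerance for the bracketed root search.
#' @return The break-even `y > x`.
#' @examples
#' breakeven_larger_vs_hawk(1)  # 1.7549...
#' @export
breakeven_larger_vs_hawk <- function(x, tol = 1e-12) {
  .check_positive_x(x)
  f <- function(y) y * (x - y)^2 - 1
  ## f(x) = -1 < 0 and f is strictly increasing for y > x; expand the upper
  ## bracket until a sign change, then refine with uniroot (Brent).
  lo <- x
  hi <- x + 1
  while (f(hi) < 0) hi <- hi * 2
  r <- stats::uniroot(f, c(lo, hi), tol = tol)
  if (abs(r$estim.prec) > 1e-6) {
    stop("root finding for y*(x - y)^2 = 1 did not converge (x = ", x,
         ", precision ", r$estim.prec, ")", call. = FALSE)
  }
  r$root
}

#' Break-even size of a smaller player facing a larger dove
#'
#' Solves the break-even between the smaller player's cooperate payoff
#' `x^2 y^2` and cheat payoff `y (x - y)^2`, which reduces to the quadratic
#' `y^2 - (x^2 + 2 x) y + x^2 = 0`; the non-extraneous root is the one lying
#' in `(0, x)`. At `x = 1` this is `1 - phi = 0.382...`, the Fibonacci
#' retracement mark.
#'
#' @param x trait value of the larger player (positive).
#' @return The root in `(0, x)`.
#' @examples
#' breakeven_smaller_vs_dove(1)  # 0.3819..., equals 1 - breakeven_larger_vs_dove(1)
#' @export
breakeven_smaller_vs_dove <- function(x) {
  .check_positive_x(x)
  b <- x^2 + 2 * x
  ## smaller root of y^2 - b y + x^2 = 0 is the one in (0, x)
  (b - sqrt(b^2 - 4 * x^2)) / 2
}

#' Break-even size of a smaller player facing a larger hawk
#'
#' Solves the break-even between the smaller player's surrender payoff
#' `x^2 (x - y)` and resistance payoff 1, i.e. `x^2 (x - y) = 1`, giving
#' `y = x - 1/x^2`. At `x = 1` the solution is exactly 0: every smaller player
#' in `(0, 1)` gains more from resisting a hawk than from surrendering.
#'
#' @param x trait value of the larger player (positive).
#' @return `x - 1/x^2` (may be negative for small `x`; at `x = 1` exactly 0).
#' @examples
#' breakeven_smaller_vs_hawk(1)  # 0
#' breakeven_smaller_vs_hawk(2)  # 1.75
#' @export
breakeven_smaller_vs_hawk <- function(x) {
  .check_positive_x(x)
  x - 1 / x^2
}

.check_positive_x <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("x must be a single positive finite number", call. = FALSE)
  }
  invisible(x)
}

#' The four hypothesis thresholds of the conflict model
#'
#' Returns the analytic constants governing the four behavioural hypotheses at
#' the normalization `x = 1`:
#' \describe{
#'   \item{`phi`}{golden-section threshold `(sqrt(5) - 1)/2 = 0.618...`, the
#'     size ratio at which a larger player's best response to a dove switches
#'     from aggression to cooperation. (The model calls this "the golden
#'     ratio"; it is the reciprocal `1/1.618...` of the usual convention.)}
#'   \item{`hawk_shift`}{root of `y (1 - y)^2 = 1`, about 1.7549: a hawk must
#'     reversely outgrow the larger player by about 75% before the latter's
#'     aggression stops paying.}
#'   \item{`fib_mark`}{Fibonacci retracement mark `1 - phi = 0.382...`, the
#'     switch point of the smaller player's best response to a dove.}
#'   \item{`surrender_point`}{0: against a hawk, a smaller player's resistance
#'     payoff dominates surrender over the whole ratio range `(0, 1)`.}
#' }
#'
#' @return Named list with `phi`, `hawk_shift`, `fib_mark`, `surrender_point`.
#' @examples
#' unlist(conflict_thresholds())
#' @export
conflict_thresholds <- function() {
  list(phi = (sqrt(5) - 1) / 2,
       hawk_shift = breakeven_larger_vs_hawk(1),
       fib_mark = (3 - sqrt(5)) / 2,
       surrender_point = 0)
}

#' Predict a player's optimal strategy in a size dyad
#'
#' Applies the reward-matrix argmax at the normalized ratio `rho = y/x`
#' (decisions depend only on relative size, so both traits are rescaled to
#' `x = 1` before comparing payoffs):
#' \itemize{
#'   \item larger vs dove: cooperate (`rho^2`) vs aggress (`1 - rho`);
#'     cooperation wins above the golden-section threshold `phi`.
#'   \item larger vs hawk: cooperate (`rho (1 - rho)^2`) vs aggress (1);
#'     aggression wins for every `rho` in (0, 1).
#'   \item smaller vs dove: cooperate (`rho^2`) vs cheat (`rho (1 - rho)^2`);
#'     the payoffs cross at the Fibonacci mark `1 - phi`, cooperation paying
#'     more above it.
#'   \item smaller vs hawk: surrender (`1 - rho`) vs resist (1); resistance
#'     wins for every `rho` in (0, 1) (surrender is dominated).
#' }
#' Exact payoff ties resolve to the non-aggressive branch.
#'
#' @param pair a [size_pair], or a single numeric ratio `y/x` in (0, 1).
#' @param focal_role `"larger"` or `"smaller"`: which player is deciding.
#' @param opponent_type `"dove"` or `"hawk"`: the opponent's fixed strategy.
#' @return Object of class `strategy_decision`: list with `focal_role`,
#'   `opponent_type`, `ratio`, `decision` (`"cooperate"`, `"aggress"`,
#'   `"cheat"`, `"resist"` or `"surrender"`), `payoff_chosen`,
#'   `payoff_rejected`, and `threshold` (the break-even ratio applied).
#' @examples
#' predict_strategy(size_pair(1, 0.5), "larger", "dove")$decision  # "aggress"
#' predict_strategy(0.7, "larger", "dove")$decision                # "cooperate"
#' @export
predict_strategy <- function(pair, focal_role = c("larger", "smaller"),
                             opponent_type = c("dove", "hawk")) {
  focal_role <- match.arg(focal_role)
  opponent_type <- match.arg(opponent_type)
  if (inherits(pair, "size_pair")) {
    rho <- pair$y / pair$x
  } else if (is.numeric(pair) && length(pair) == 1L && is.finite(pair)) {
    if (pair <= 0 || pair >= 1) {
      stop("ratio y/x must lie strictly between 0 and 1", call. = FALSE)
    }
    rho <- pair
  } else {
    stop("pair must be a size_pair or a single ratio in (0, 1)", call. = FALSE)
  }
  th <- conflict_thresholds()
  ## reward-matrix entries at x = 1, y = rho
  e_dd <- rho^2; e_dh <- rho * (1 - rho)^2; e_hd <- 1 - rho; e_hh <- 1
  if (focal_role == "larger" && opponent_type == "dove") {
    coop <- e_dd; other <- e_hd
    labels <- c("cooperate", "aggress"); threshold <- th$phi
  } else if (focal_role == "larger" && opponent_type == "hawk") {
    coop <- e_dh; other <- e_hh
    labels <- c("cooperate", "aggress"); threshold <- th$hawk_shift
  } else if (focal_role == "smaller" && opponent_type == "dove") {
    coop <- e_dd; other <- e_dh
    labels <- c("cooperate", "cheat"); threshold <- th$fib_mark
  } else {
    coop <- e_hd; other <- e_hh
    labels <- c("surrender", "resist"); threshold <- th$surrender_point
  }
  ## tie -> non-aggressive branch, with a relative tolerance so that a ratio
  ## exactly at a threshold constant resolves cooperatively despite rounding;
  ## for smaller-vs-hawk the non-dominated branch is resistance, so surrender
  ## is kept only when it strictly exceeds the resistance payoff (never on
  ## (0, 1)).
  if (focal_role == "smaller" && opponent_type == "hawk") {
    take_coop <- coop > other
  } else {
    take_coop <- coop >= other - 1e-12 * (abs(coop) + abs(other))
  }
  structure(list(focal_role = focal_role, opponent_type = opponent_type,
                 ratio = rho,
                 decision = if (take_coop) labels[1L] else labels[2L],
                 payoff_chosen = max(coop, other),
                 payoff_rejected = min(coop, other),
                 threshold = threshold),
            class = "strategy_decision")
}

#' @export
print.strategy_decision <- function(x, ...) {
  cat(sprintf("%s player vs %s opponent at ratio %.4f -> %s (payoff %.4f over %.4f; threshold %.4f)\n",
              x$focal_role, x$opponent_type, x$ratio, x$decision,
              x$payoff_chosen, x$payoff_rejected, x$threshold))
  invisible(x)
}

#' Strategy decisions for a table of dyads
#'
#' Vectorized wrapper around [predict_strategy()]: one decision per row of a
#' dyad table for a given focal role and opponent type.
#'
#' @param dyads data frame with columns `x` and `y` (`x > y > 0`), e.g. from
#'   [pairwise_descriptors()].
#' @param focal_role,opponent_type as in [predict_strategy()].
#' @return `dyads` with added columns `ratio`, `decision`, `payoff_chosen`,
#'   `payoff_rejected`, `threshold`.
#' @export
decide_dyads <- function(dyads, focal_role = c("larger", "smaller"),
                         opponent_type = c("dove", "hawk")) {
  focal_role <- match.arg(focal_role)
  opponent_type <- match.arg(opponent_type)
  stopifnot(is.data.frame(dyads), all(c("x", "y") %in% names(dyads)))
  res <- lapply(seq_len(nrow(dyads)), function(i) {
    d <- predict_strategy(dyads$y[i] / dyads$x[i], focal_role, opponent_type)
    data.frame(ratio = d$ratio, decision = d$decision,
               payoff_chosen = d$payoff_chosen,
               payoff_rejected = d$payoff_rejected,
               threshold = d$threshold, stringsAsFactors = FALSE)
  })
  cbind(dyads, do.call(rbind, res))
}
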