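#' Construct an ordered size pair
#'
#' Orders the two trait values of a dyad so that `x` is the larger and `y` the
#' smaller player, recording which individual ended up in which role. Trait
#' values must be strictly positive and sufficiently distinct: dyads whose
#' relative difference `(x - y)/x` falls below `eps` are rejected, because every
#' interaction descriptor divides by `x - y` and the dyad has no defined
#' winner/loser geometry at equal size. Ties are never jittered silently.
#'
#' @param a,b trait values of the two individuals (same positive units,
#'   e.g. body mass in grams).
#' @param id_a,id_b identifiers of the two individuals.
#' @param eps relative degeneracy guard on `(x - y)/x` (default `1e-9`).
#' @return An object of class `size_pair`: a list with fields `x`, `y`
#'   (larger/smaller trait value) and `id_x`, `id_y` (matching identifiers).
#' @examples
#' p <- size_pair(1, 2, "f1", "f2")
#' p$x          # 2, the larger player
#' p$id_x       # "f2"
#' @export
size_pair <- function(a, b, id_a = "A", id_b = "B", eps = 1e-9) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b)) {
    stop("trait values must be single finite numbers", call. = FALSE)
  }
  if (a <= 0 || b <= 0) {
    stop("trait values must be strictly positive (got ", a, ", ", b, ")",
         call. = FALSE)
  }
  if (a >= b) {
    x <- a; y <- b; id_x <- id_a; id_y <- id_b
  } else {
    x <- b; y <- a; id_x <- id_b; id_y <- id_a
  }
  if ((x - y) / x < eps) {
    stop(errorCondition(
      sprintf("degenerate dyad (%s, %s): trait values %g and %g are equal or nearly so; interaction descriptors divide by x - y",
              id_x, id_y, x, y),
      class = c("hawkdove_degenerate_error", "error", "condition")))
  }
  structure(list(x = x, y = y, id_x = id_x, id_y = id_y),
            class = "size_pair")
}

#' @export
print.size_pair <- function(x, ...) {
  cat(sprintf("size pair: %s (x = %g) > %s (y = %g), ratio y/x = %.4f\n",
              x$id_x, x$x, x$id_y, x$y, x$y / x$x))
  invisible(x)
}

## vectorized descriptor kernels; callers guarantee x > y > 0
.z_mu <- function(x, y) x * y / (x - y)
.z_an <- function(x, y) 1 / (x * y * (x - y))
.z_ag <- function(x, y) x / y
.z_al <- function(x, y) (x - y) / x

#' Size-based interaction descriptors for a dyad
#'
#' Computes the four dimensionless interaction-strength descriptors of the
#' conflict model for an ordered pair with trait values `x > y > 0`:
#' mutualism `z_mu = x*y/(x - y)` (the product of sizes, scale-adjusted by
#' their difference -- similar-sized pairs score high), antagonism
#' `z_an = 1/(x*y*(x - y))` (the inverse product, same adjustment), aggression
#' `z_ag = x/y` (dominance of the larger over the smaller) and altruism
#' `z_al = (x - y)/x` (the relative size surplus ceded by the larger player).
#'
#' @param pair a [size_pair].
#' @return An object of class `interaction_descriptors`: list with `z_mu`,
#'   `z_an`, `z_ag`, `z_al`, `id_x`, `id_y`.
#' @examples
#' compute_descriptors(size_pair(2, 1))  # z_mu = 2, z_an = 0.5, z_ag = 2, z_al = 0.5
#' @seealso [relativized_matrix()] for the reward matrix these induce.
#' @export
compute_descriptors <- function(pair) {
  stopifnot(inherits(pair, "size_pair"))
  structure(list(z_mu = .z_mu(pair$x, pair$y),
                 z_an = .z_an(pair$x, pair$y),
                 z_ag = .z_ag(pair$x, pair$y),
                 z_al = .z_al(pair$x, pair$y),
                 id_x = pair$id_x, id_y = pair$id_y),
            class = "interaction_descriptors")
}

#' @export
print.interaction_descriptors <- function(x, ...) {
  cat(sprintf("interaction descriptors (%s vs %s):\n", x$id_x, x$id_y))
  cat(sprintf("  mutualism  z_mu = %g\n  antagonism z_an = %g\n", x$z_mu, x$z_an))
  cat(sprintf("  aggression z_ag = %g\n  altruism   z_al = %g\n", x$z_ag, x$z_al))
  invisible(x)
}

#' Antagonism-relativized reward matrix for a dyad
#'
#' The four descriptors form a 2x2 hawk-dove reward matrix; because all four
#' diverge as `x - y -> 0`, each entry is relativized by the antagonism
#' (hawk/hawk) descriptor `z_an`, giving the well-behaved matrix
#' \deqn{\begin{pmatrix} x^2 y^2 & y (x-y)^2 \\ x^2 (x-y) & 1 \end{pmatrix}}
#' with the larger player X choosing rows (dove, hawk) and the smaller player Y
#' choosing columns. The hawk/hawk entry is exactly 1 by construction.
#'
#' @param pair a [size_pair].
#' @return Object of class `reward_matrix`: list with entries `e_dd`
#'   (dove/dove, mutualism), `e_dh` (X dove / Y hawk, altruism), `e_hd`
#'   (X hawk / Y dove, aggression), `e_hh = 1` (hawk/hawk), plus the ids.
#'   Use [as.matrix()] for the 2x2 form.
#' @examples
#' m <- relativized_matrix(size_pair(2, 1))
#' as.matrix(m)
#' @export
relativized_matrix <- function(pair) {
  stopifnot(inherits(pair, "size_pair"))
  x <- pair$x; y <- pair$y
  structure(list(e_dd = x^2 * y^2,
                 e_dh = y * (x - y)^2,
                 e_hd = x^2 * (x - y),
                 e_hh = 1,
                 id_x = pair$id_x, id_y = pair$id_y),
            class = "reward_matrix")
}

#' @export
as.matrix.reward_matrix <- function(x, ...) {
  matrix(c(x$e_dd, x$e_dh, x$e_hd, x$e_hh), nrow = 2, byrow = TRUE,
         dimnames = list(X = c("dove", "hawk"), Y = c("dove", "hawk")))
}

#' @export
print.reward_matrix <- function(x, ...) {
  cat(sprintf("relativized reward matrix (%s as X, %s as Y):\n", x$id_x, x$id_y))
  print(as.matrix(x))
  invisible(x)
}

#' All-pairs interaction descriptors for a cohort
#'
#' Evaluates the four descriptors and the relativized reward-matrix entries for
#' every one of the `n(n-1)/2` dyads of a trait table. Degenerate dyads
#' (relative size difference below `eps`) are dropped with a warning rather
#' than jittered.
#'
#' @param traits data frame with columns `id` and `trait` (positive values).
#' @param eps relative degeneracy guard, as in [size_pair()].
#' @return Data frame with one row per retained dyad: `id_x`, `id_y`, `x`, `y`
#'   (ordered so `x > y`), the four descriptors and the four matrix entries.
#'   Dropped dyads are reported in attribute `"degenerate"`.
#' @examples
#' tr <- data.frame(id = c("a", "b", "c"), trait = c(10, 6.2, 3.8))
#' pairwise_descriptors(tr)
#' @export
pairwise_descriptors <- function(traits, eps = 1e-9) {
  traits <- .validate_traits(traits)
  n <- nrow(traits)
  if (n < 2L) stop("need at least 2 individuals", call. = FALSE)
  idx <- utils::combn(n, 2L)
  a <- traits$trait[idx[1L, ]]; b <- traits$trait[idx[2L, ]]
  ia <- traits$id[idx[1L, ]];   ib <- traits$id[idx[2L, ]]
  swap <- b > a
  x <- ifelse(swap, b, a); y <- ifelse(swap, a, b)
  id_x <- ifelse(swap, ib, ia); id_y <- ifelse(swap, ia, ib)
  degenerate <- (x - y) / x < eps
  out <- data.frame(id_x = id_x, id_y = id_y, x = x, y = y,
                    z_mu = .z_mu(x, y), z_an = .z_an(x, y),
                    z_ag = .z_ag(x, y), z_al = .z_al(x, y),
                    e_dd = x^2 * y^2, e_dh = y * (x - y)^2,
                    e_hd = x^2 * (x - y), e_hh = 1,
                    stringsAsFactors = FALSE)
  if (any(degenerate)) {
    warning(sum(degenerate), " degenerate dyad(s) dropped (equal or near-equal traits): ",
            paste(sprintf("(%s,%s)", id_x[degenerate], id_y[degenerate]),
                  collapse = ", "), call. = FALSE)
  }
  res <- out[!degenerate, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "degenerate") <- out[degenerate, c("id_x", "id_y"), drop = FALSE]
  res
}

.validate_traits <- function(traits) {
  if (!is.data.frame(traits) || !all(c("id", "trait") %in% names(traits))) {
    stop("traits must be a data frame with columns 'id' and 'trait'", call. = FALSE)
  }
  traits$id <- as.character(traits$id)
  if (anyDuplicated(traits$id)) stop("duplicated individual ids", call. = FALSE)
  if (!is.numeric(traits$trait) || any(!is.finite(traits$trait)) ||
      any(traits$trait <= 0)) {
    stop("trait values must all be finite and strictly positive", call. = FALSE)
  }
  traits[, c("id", "trait")]
}
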