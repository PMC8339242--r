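#' Build the four descriptor-based interaction networks over a cohort
#'
#' For every dyad of the cohort the four interaction descriptors are computed
#' ([pairwise_descriptors()]); per network type the `n(n-1)/2` descriptor
#' values are ranked and only the top fraction `q` is retained as edges (the
#' "culling" of small values), weighted by the descriptor. Mutualism and
#' antagonism networks are undirected; aggression and altruism are directed
#' from the larger-trait to the smaller-trait member (hawk upon dove, altruist
#' benefiting egoist). Rank ties break lexicographically by dyad id, so
#' retention is deterministic.
#'
#' @param traits data frame with columns `id`, `trait`.
#' @param q retained-edge fraction in (0, 1]; either a single value or a named
#'   vector/list with entries for `mutualism`, `antagonism`, `aggression`,
#'   `altruism`.
#' @param eps degeneracy guard passed to [pairwise_descriptors()].
#' @return Named list of \pkg{igraph} graphs (one per type), each carrying
#'   graph attributes `type`, `q` and `dyad_values` (the full pre-culling
#'   descriptor vector named by sorted dyad id, used by
#'   [network_correlation()]), vertex attribute `trait` and edge attribute
#'   `weight`. The dyad table itself is attached as attribute `"dyads"` of
#'   the list.
#' @examples
#' tr <- data.frame(id = paste0("f", 1:4), trait = c(10, 6.2, 3.8, 2))
#' nets <- build_networks(tr, q = 1)
#' igraph::ecount(nets$mutualism)  # 6 = all dyads at q = 1
#' @export
build_networks <- function(traits, q = 0.1, eps = 1e-9) {
  traits <- .validate_traits(traits)
  if (nrow(traits) < 3L) stop("need at least 3 individuals", call. = FALSE)
  types <- c("mutualism", "antagonism", "aggression", "altruism")
  q <- .expand_q(q, types)
  dyads <- pairwise_descriptors(traits, eps = eps)
  cols <- c(mutualism = "z_mu", antagonism = "z_an",
            aggression = "z_ag", altruism = "z_al")
  n_all <- nrow(traits) * (nrow(traits) - 1L) / 2L
  nets <- lapply(types, function(ty) {
    w <- dyads[[cols[[ty]]]]
    keep_n <- min(round(q[[ty]] * n_all), nrow(dyads))
    ord <- order(-w, dyads$id_x, dyads$id_y)
    sel <- dyads[ord[seq_len(keep_n)], , drop = FALSE]
    directed <- ty %in% c("aggression", "altruism")
    el <- data.frame(from = sel$id_x, to = sel$id_y,
                     weight = sel[[cols[[ty]]]], stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      el, directed = directed,
      vertices = data.frame(name = traits$id, trait = traits$trait))
    g <- igraph::set_graph_attr(g, "type", ty)
    g <- igraph::set_graph_attr(g, "q", q[[ty]])
    igraph::set_graph_attr(g, "dyad_values",
                           stats::setNames(w, .dyad_key(dyads$id_x, dyads$id_y)))
  })
  names(nets) <- types
  attr(nets, "dyads") <- dyads
  nets
}

.expand_q <- function(q, types) {
  if (is.list(q)) q <- unlist(q)
  if (length(q) == 1L && is.null(names(q))) q <- stats::setNames(rep(q, length(types)), types)
  if (!all(types %in% names(q))) {
    stop("q must be a single fraction or named for each of: ",
         paste(types, collapse = ", "), call. = FALSE)
  }
  q <- q[types]
  if (any(q <= 0 | q > 1)) stop("retention fractions must lie in (0, 1]", call. = FALSE)
  q
}

.dyad_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Assign hierarchy roles in the mutualism network
#'
#' Hubs -- nodes whose degree exceeds the mean degree by more than `k`
#' standard deviations -- are primary leaders. Non-primary neighbours of a
#' primary are secondary leaders. Tertiary leaders are the remaining nodes
#' adjacent to a secondary leader whose every route to a primary leader passes
#' through a secondary (they are disconnected from all primaries once the
#' secondaries are removed). Followers are the remaining nodes adjacent to a
#' tertiary leader but not to a secondary leader. Everything else (including
#' isolated nodes) is unassigned.
#'
#' @param net a mutualism network from [build_networks()] (any undirected
#'   \pkg{igraph} graph works).
#' @param k hub threshold in standard deviations above the mean degree.
#' @return Data frame with columns `id` and `role` (`primary_leader`,
#'   `secondary_leader`, `tertiary_leader`, `follower`, `unassigned`). Warns
#'   when no node qualifies as a hub (e.g. a regular graph).
#' @export
assign_mutualism_hierarchy <- function(net, k = 1) {
  stopifnot(inherits(net, "igraph"))
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  deg <- igraph::degree(net, mode = "all")
  ids <- igraph::V(net)$name
  thr <- mean(deg) + k * stats::sd(deg)
  primary <- ids[deg > thr]
  role <- stats::setNames(rep("unassigned", length(ids)), ids)
  if (length(primary) == 0L) {
    warning("no hub exceeds mean + ", k, " sd of degree; all nodes unassigned",
            call. = FALSE)
    return(data.frame(id = ids, role = unname(role), stringsAsFactors = FALSE))
  }
  role[primary] <- "primary_leader"
  nbrs <- function(v) unique(unlist(lapply(v, function(u) {
    igraph::neighbors(net, u, mode = "all")$name
  })))
  secondary <- setdiff(nbrs(primary), primary)
  role[secondary] <- "secondary_leader"
  ## tertiary: adjacent to a secondary leader, and cut off from every primary
  ## once the secondaries are removed (their routes to the primaries are
  ## "separated by" the secondaries)
  rest <- setdiff(ids, c(primary, secondary))
  if (length(rest) > 0L) {
    adj_sec <- intersect(rest, nbrs(secondary))
    reduced <- igraph::delete_vertices(net, secondary)
    rcomp <- igraph::components(reduced)$membership
    rprim <- intersect(primary, names(rcomp))
    tertiary <- vapply(adj_sec, function(v) {
      !(rcomp[[v]] %in% rcomp[rprim])
    }, TRUE)
    tertiary <- names(tertiary)[tertiary]
    role[tertiary] <- "tertiary_leader"
    ## followers: adjacent to tertiary but not to secondary
    remaining <- setdiff(rest, tertiary)
    if (length(tertiary) > 0L && length(remaining) > 0L) {
      adj_t <- intersect(remaining, nbrs(tertiary))
      adj_s <- if (length(secondary)) nbrs(secondary) else character(0)
      role[setdiff(adj_t, adj_s)] <- "follower"
    }
  }
  data.frame(id = ids, role = unname(role[ids]), stringsAsFactors = FALSE)
}

#' Assign hawk/dove or altruist/egoist roles in a directed network
#'
#' In the aggression network an edge runs from the aggressor (hawk) to its
#' target (dove); in the altruism network from the altruist to the benefiting
#' egoist. A node with only outgoing edges is a pure hawk (altruist), with
#' only incoming edges a pure dove (egoist), with both a mixed hawk-dove
#' (altruist-egoist), and with neither it is isolated.
#'
#' @param net a directed \pkg{igraph} graph whose graph attribute `type` is
#'   `"aggression"` or `"altruism"` (as built by [build_networks()]).
#' @return Data frame with columns `id` and `role`.
#' @export
assign_directional_roles <- function(net) {
  stopifnot(inherits(net, "igraph"))
  if (!igraph::is_directed(net)) stop("network must be directed", call. = FALSE)
  ty <- igraph::graph_attr(net, "type")
  labels <- if (identical(ty, "altruism")) {
    c(out = "altruist", both = "altruist_egoist", incoming = "egoist", none = "isolated")
  } else {
    c(out = "hawk", both = "hawk_dove", incoming = "dove", none = "isolated")
  }
  dout <- igraph::degree(net, mode = "out")
  din <- igraph::degree(net, mode = "in")
  role <- ifelse(dout > 0 & din > 0, labels[["both"]],
          ifelse(dout > 0, labels[["out"]],
          ifelse(din > 0, labels[["incoming"]], labels[["none"]])))
  data.frame(id = igraph::V(net)$name, role = unname(role),
             stringsAsFactors = FALSE)
}

#' Test tier body-mass ratios against a decision threshold
#'
#' Computes, for every cross-tier dyad (restricted to network-connected dyads
#' when a graph is supplied), the ratio of the lower-tier member's trait to
#' the upper-tier member's trait, and tests the mean ratio against a
#' threshold -- the golden section `phi` or the Fibonacci mark `1 - phi` --
#' with a one-sample t-test. An optional node-permutation test (roles
#' reshuffled over the involved nodes) gives a second p-value that does not
#' assume dyad independence.
#'
#' @param roles data frame with columns `id`, `role` (from the role-assignment
#'   functions, or planted tier labels).
#' @param traits data frame with columns `id`, `trait`.
#' @param tier_pair character vector `c(upper, lower)`: the role labels of the
#'   upper and lower tier.
#' @param threshold break-even ratio to test against (default `phi`).
#' @param alternative `"greater"`, `"less"` or `"two.sided"` for the t-test on
#'   the mean ratio vs `threshold`.
#' @param graph optional \pkg{igraph} graph; when given, only connected
#'   cross-tier dyads enter.
#' @param n_perm number of node-label permutations for the permutation
#'   p-value (0 to skip).
#' @param seed seed for the permutation test.
#' @return Object of class `tier_ratio_result`: list with `tier_pair`,
#'   `ratios`, `mean_ratio`, `threshold`, `statistic`, `p_value`,
#'   `p_permutation` (NA unless requested), `direction` (`above`/`below` the
#'   threshold) and `n`.
#' @export
tier_mass_ratio <- function(roles, traits, tier_pair,
                            threshold = conflict_thresholds()$phi,
                            alternative = c("greater", "less", "two.sided"),
                            graph = NULL, n_perm = 0, seed = 1L) {
  alternative <- match.arg(alternative)
  stopifnot(length(tier_pair) == 2L)
  traits <- .validate_traits(traits)
  tr <- stats::setNames(traits$trait, traits$id)
  upper_ids <- roles$id[roles$role == tier_pair[1L]]
  lower_ids <- roles$id[roles$role == tier_pair[2L]]
  if (length(upper_ids) == 0L) stop("empty upper tier '", tier_pair[1L], "'", call. = FALSE)
  if (length(lower_ids) == 0L) stop("empty lower tier '", tier_pair[2L], "'", call. = FALSE)
  dyads <- expand.grid(upper = upper_ids, lower = lower_ids,
                       stringsAsFactors = FALSE)
  if (!is.null(graph)) {
    con <- igraph::as_edgelist(graph)
    keys <- .dyad_key(con[, 1L], con[, 2L])
    dyads <- dyads[.dyad_key(dyads$upper, dyads$lower) %in% keys, , drop = FALSE]
    if (nrow(dyads) == 0L) stop("no connected cross-tier dyads", call. = FALSE)
  }
  ratios <- unname(tr[dyads$lower] / tr[dyads$upper])
  if (length(ratios) >= 2L && stats::sd(ratios) > 1e-10 * mean(ratios)) {
    tt <- stats::t.test(ratios, mu = threshold, alternative = alternative)
    tt <- list(statistic = unname(tt$statistic), p.value = tt$p.value)
  } else {
    ## all ratios (numerically) identical: the t statistic degenerates to 0
    ## at the threshold or +/- infinity away from it
    d <- mean(ratios) - threshold
    stat <- if (abs(d) < 1e-10) 0 else sign(d) * Inf
    pv <- switch(alternative,
      two.sided = if (stat == 0) 1 else 0,
      greater = if (stat == 0) 0.5 else as.numeric(d < 0),
      less = if (stat == 0) 0.5 else as.numeric(d > 0))
    tt <- list(statistic = stat, p.value = pv)
  }
  p_perm <- NA_real_
  if (n_perm > 0) {
    ids <- c(upper_ids, lower_ids)
    obs <- mean(ratios)
    perm_means <- withr::with_seed(seed, replicate(n_perm, {
      shuf <- sample(ids)
      up <- shuf[seq_along(upper_ids)]
      lo <- shuf[-seq_along(upper_ids)]
      mean(outer(tr[lo], tr[up], "/"))
    }))
    p_perm <- switch(alternative,
      greater = mean(perm_means >= obs),
      less = mean(perm_means <= obs),
      two.sided = mean(abs(perm_means - mean(perm_means)) >=
                         abs(obs - mean(perm_means))))
  }
  structure(list(tier_pair = tier_pair, ratios = ratios,
                 mean_ratio = mean(ratios), threshold = threshold,
                 statistic = tt$statistic, p_value = tt$p.value,
                 p_permutation = p_perm,
                 direction = if (mean(ratios) >= threshold) "above" else "below",
                 n = length(ratios)),
            class = "tier_ratio_result")
}

#' @export
print.tier_ratio_result <- function(x, ...) {
  cat(sprintf("tier ratio %s/%s: mean = %.3f over %d dyads, %s threshold %.3f (t = %.2f, p = %.3g)\n",
              x$tier_pair[2L], x$tier_pair[1L], x$mean_ratio, x$n,
              x$direction, x$threshold, x$statistic, x$p_value))
  invisible(x)
}

#' Pairwise identity-by-state similarity from a genotype matrix
#'
#' Allele-sharing similarity for biallelic genotypes coded 0/1/2 (count of one
#' parental allele): for a pair of individuals the per-SNP similarity is
#' `(2 - |g_i - g_j|)/2`, averaged over SNPs where both calls are present.
#' Identical genotypes score 1, opposite homozygotes 0.
#'
#' @param geno numeric matrix, individuals x SNPs, values in `{0, 1, 2, NA}`.
#' @return Symmetric similarity matrix with unit diagonal. Pairs with no
#'   jointly observed SNP are `NA`.
#' @export
ibs_similarity <- function(geno) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno))) rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  if (!all(geno %in% c(0, 1, 2) | is.na(geno))) {
    stop("genotypes must be coded 0/1/2 or NA", call. = FALSE)
  }
  obs <- !is.na(geno)
  g <- geno; g[!obs] <- 0
  obs <- obs * 1
  ## sum over shared SNPs of (g_i - g_j)^2, masked by joint observation
  g2 <- g^2
  cross <- tcrossprod(g)
  s_i <- g2 %*% t(obs)   # sum of g_i^2 over SNPs observed in both
  sq <- s_i + t(s_i) - 2 * cross
  ## (g_i - g_j)^2 differs from |g_i - g_j| only where the difference is 2
  h0 <- (g == 0) * obs; h2 <- (g == 2) * obs
  n22 <- tcrossprod(h0, h2) + tcrossprod(h2, h0)
  absdiff <- sq - 2 * n22
  shared <- tcrossprod(obs)
  sim <- 1 - absdiff / (2 * shared)
  sim[shared == 0] <- NA_real_
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(geno), rownames(geno))
  sim
}

#' Build the SNP relatedness network and assign core/periphery roles
#'
#' Pairwise genetic similarity is the identity-by-state fraction
#' ([ibs_similarity()]); the top fraction `q` of the `n(n-1)/2` similarity
#' values becomes the (undirected) edges, and core members are similarity
#' hubs by the same degree rule as primary leaders (degree above mean + `k`
#' sd); everyone else is periphery.
#'
#' @param geno genotype matrix (individuals x SNPs, 0/1/2/NA); needs at least
#'   3 individuals and 50 SNPs.
#' @param q retained-edge fraction in (0, 1].
#' @param k hub threshold in sd units.
#' @return List with `network` (an \pkg{igraph} graph with `dyad_values`
#'   attribute as in [build_networks()]), `roles` (data frame `id`, `role`
#'   with `core`/`periphery`) and `similarity` (the full matrix).
#' @export
relatedness_network <- function(geno, q = 0.1, k = 1) {
  geno <- as.matrix(geno)
  if (nrow(geno) < 3L) stop("need at least 3 individuals", call. = FALSE)
  if (ncol(geno) < 50L) stop("need at least 50 SNPs", call. = FALSE)
  if (any(q <= 0 | q > 1)) stop("retention fraction must lie in (0, 1]", call. = FALSE)
  sim <- ibs_similarity(geno)
  ids <- rownames(sim)
  idx <- utils::combn(length(ids), 2L)
  vals <- sim[cbind(idx[1L, ], idx[2L, ])]
  id_a <- ids[idx[1L, ]]; id_b <- ids[idx[2L, ]]
  drop <- is.na(vals)
  if (any(drop)) {
    warning(sum(drop), " pair(s) with no jointly observed SNP excluded", call. = FALSE)
  }
  keep_n <- min(round(q * length(vals)), sum(!drop))
  ord <- order(-vals, id_a, id_b, na.last = TRUE)
  sel <- ord[seq_len(keep_n)]
  g <- igraph::graph_from_data_frame(
    data.frame(from = id_a[sel], to = id_b[sel], weight = vals[sel]),
    directed = FALSE, vertices = data.frame(name = ids))
  g <- igraph::set_graph_attr(g, "type", "relatedness")
  g <- igraph::set_graph_attr(g, "q", q)
  g <- igraph::set_graph_attr(
    g, "dyad_values",
    stats::setNames(vals[!drop], .dyad_key(id_a[!drop], id_b[!drop])))
  deg <- igraph::degree(g)
  core <- ids[deg > mean(deg) + k * stats::sd(deg)]
  roles <- data.frame(id = ids,
                      role = ifelse(ids %in% core, "core", "periphery"),
                      stringsAsFactors = FALSE)
  list(network = g, roles = roles, similarity = sim)
}

#' Correlation between two interaction networks
#'
#' Pearson correlation between the pre-culling all-dyads value vectors of two
#' networks (descriptor values or relatedness similarities), aligned by dyad
#' id, so the comparison does not depend on either network's retention
#' fraction.
#'
#' @param net_a,net_b \pkg{igraph} graphs carrying a `dyad_values` graph
#'   attribute (from [build_networks()] or [relatedness_network()]).
#' @return List with `r`, `p` and `n` (number of shared dyads). If either
#'   vector has zero variance the correlation is undefined and `r`/`p` are
#'   `NA` with a warning.
#' @export
network_correlation <- function(net_a, net_b) {
  va <- igraph::graph_attr(net_a, "dyad_values")
  vb <- igraph::graph_attr(net_b, "dyad_values")
  if (is.null(va) || is.null(vb)) {
    stop("both networks need a 'dyad_values' graph attribute", call. = FALSE)
  }
  shared <- intersect(names(va), names(vb))
  if (length(shared) < 3L) stop("fewer than 3 shared dyads", call. = FALSE)
  a <- va[shared]; b <- vb[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in dyad values; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n = length(shared)))
  }
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Compare trait values of core vs periphery members
#'
#' Welch two-sample t-test of the trait (body mass) between the core and
#' periphery of the relatedness network -- the check that social role is not
#' explained by genetic similarity hubs being larger or smaller.
#'
#' @param roles data frame `id`, `role` with roles `core` and `periphery`.
#' @param traits data frame `id`, `trait`.
#' @return List with `statistic`, `p_value`, `mean_core`, `mean_periphery`,
#'   `n_core`, `n_periphery`.
#' @export
compare_core_periphery_trait <- function(roles, traits) {
  traits <- .validate_traits(traits)
  tr <- stats::setNames(traits$trait, traits$id)
  core <- tr[roles$id[roles$role == "core"]]
  peri <- tr[roles$id[roles$role == "periphery"]]
  if (length(core) < 2L || length(peri) < 2L) {
    stop("both groups need at least 2 members", call. = FALSE)
  }
  tt <- stats::t.test(core, peri)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_core = mean(core), mean_periphery = mean(peri),
       n_core = length(core), n_periphery = length(peri))
}
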