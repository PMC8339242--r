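# shared fixtures, built in code

# random valid size pairs (x > y > 0, non-degenerate), fixed seed
random_pairs <- function(n, seed = 1) {
  withr::with_seed(seed, {
    x <- stats::rlnorm(n, 0, 1)
    rho <- stats::runif(n, 0.05, 0.95)
    data.frame(x = x, y = x * rho)
  })
}

# long-format abundance table for one pair from explicit per-time ratios
abund_from_ratios <- function(times, x0, y0, rx, ry, pair = "p1") {
  rbind(
    data.frame(pair_id = pair, strain_id = "a", condition = "coculture",
               time = times, abundance = x0 * rx),
    data.frame(pair_id = pair, strain_id = "b", condition = "coculture",
               time = times, abundance = y0 * ry),
    data.frame(pair_id = pair, strain_id = "a", condition = "monoculture",
               time = times, abundance = x0),
    data.frame(pair_id = pair, strain_id = "b", condition = "monoculture",
               time = times, abundance = y0))
}

# undirected toy graph from an edge list matrix
toy_graph <- function(el, directed = FALSE, type = NULL) {
  g <- igraph::graph_from_edgelist(el, directed = directed)
  if (!is.null(type)) g <- igraph::set_graph_attr(g, "type", type)
  g
}
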