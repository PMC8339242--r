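four_fish <- data.frame(id = paste0("f", 1:4), trait = c(10, 6.2, 3.8, 2))

test_that("full-retention networks carry hand-computed descriptor weights", {
  nets <- build_networks(four_fish, q = 1)
  expect_equal(unname(sapply(nets, igraph::ecount)), rep(6L, 4L))
  dy <- attr(nets, "dyads")
  # brute force over all 6 dyads against the scalar path
  for (i in seq_len(nrow(dy))) {
    d <- compute_descriptors(size_pair(dy$x[i], dy$y[i]))
    expect_equal(dy$z_mu[i], d$z_mu)
    expect_equal(dy$z_an[i], d$z_an)
    expect_equal(dy$z_ag[i], d$z_ag)
    expect_equal(dy$z_al[i], d$z_al)
  }
  # aggression edges all point from the heavier member
  el <- igraph::as_data_frame(nets$aggression)
  tr <- stats::setNames(four_fish$trait, four_fish$id)
  expect_true(all(tr[el$from] > tr[el$to]))
  expect_true(igraph::is_directed(nets$altruism))
  expect_false(igraph::is_directed(nets$mutualism))
})

test_that("edge retention honours the culling contract deterministically", {
  withr::with_seed(3, {
    tr <- data.frame(id = sprintf("i%02d", 1:12),
                     trait = stats::rlnorm(12, log(100), 0.4))
  })
  n_all <- 12 * 11 / 2
  for (q in c(0.1, 0.25, 0.5, 1)) {
    nets <- build_networks(tr, q = q)
    for (g in nets) expect_equal(igraph::ecount(g), round(q * n_all))
  }
  # retained edges are exactly the top-q by weight
  nets <- build_networks(tr, q = 0.2)
  w_kept <- sort(igraph::E(nets$mutualism)$weight, decreasing = TRUE)
  all_w <- sort(igraph::graph_attr(nets$mutualism, "dyad_values"),
                decreasing = TRUE)
  expect_equal(w_kept, unname(all_w[seq_along(w_kept)]))
  # deterministic: same input, same graph
  nets2 <- build_networks(tr, q = 0.2)
  expect_identical(igraph::as_data_frame(nets$aggression),
                   igraph::as_data_frame(nets2$aggression))
  expect_error(build_networks(tr, q = 0), "\\(0, 1\\]")
  expect_error(build_networks(tr, q = 1.2), "\\(0, 1\\]")
})

test_that("mutualism hierarchy follows the hub/adjacency rules", {
  # star: hub primary, leaves secondary, nothing else
  star <- toy_graph(cbind(rep("hub", 6), paste0("leaf", 1:6)))
  r <- assign_mutualism_hierarchy(star)
  expect_equal(r$role[r$id == "hub"], "primary_leader")
  expect_true(all(r$role[r$id != "hub"] == "secondary_leader"))

  # hub -- s -- t -- f chain with an inflated hub degree: roles in order
  el <- rbind(cbind(rep("hub", 5), paste0("x", 1:5)),
              c("hub", "s"), c("s", "t"), c("t", "f"))
  g <- toy_graph(el)
  r2 <- assign_mutualism_hierarchy(g)
  roles <- stats::setNames(r2$role, r2$id)
  expect_equal(unname(roles["hub"]), "primary_leader")
  expect_equal(unname(roles["s"]), "secondary_leader")
  expect_equal(unname(roles["t"]), "tertiary_leader")
  expect_equal(unname(roles["f"]), "follower")

  # regular graph: "much more than average" unsatisfiable
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- paste0("r", 1:8)
  expect_warning(r3 <- assign_mutualism_hierarchy(ring), "no hub")
  expect_true(all(r3$role == "unassigned"))
  expect_error(assign_mutualism_hierarchy(igraph::make_empty_graph(0)), "empty")
})

test_that("roles partition the nodes with exactly one role each", {
  withr::with_seed(13, {
    tr <- data.frame(id = sprintf("i%02d", 1:30),
                     trait = stats::rlnorm(30, log(200), 0.5))
  })
  nets <- build_networks(tr, q = 0.15)
  for (r in list(suppressWarnings(assign_mutualism_hierarchy(nets$mutualism)),
                 assign_directional_roles(nets$aggression),
                 assign_directional_roles(nets$altruism))) {
    expect_equal(sort(r$id), sort(tr$id))
    expect_false(anyNA(r$role))
    expect_equal(anyDuplicated(r$id), 0L)
  }
})

test_that("directional roles classify by in/out edges", {
  g <- toy_graph(rbind(c("A", "B"), c("A", "C")), directed = TRUE,
                 type = "aggression")
  r <- assign_directional_roles(g)
  expect_equal(r$role[r$id == "A"], "hawk")
  expect_true(all(r$role[r$id %in% c("B", "C")] == "dove"))

  g2 <- toy_graph(rbind(c("A", "B"), c("B", "C")), directed = TRUE,
                  type = "altruism")
  r2 <- assign_directional_roles(g2)
  expect_equal(r2$role[r2$id == "B"], "altruist_egoist")

  # 6-node toy vs manual classification
  el <- rbind(c("a", "b"), c("a", "c"), c("d", "a"), c("e", "c"))
  g3 <- igraph::add_vertices(toy_graph(el, directed = TRUE, type = "aggression"),
                             1, name = "loner")
  r3 <- assign_directional_roles(g3)
  expected <- c(a = "hawk_dove", b = "dove", c = "dove", d = "hawk",
                e = "hawk", loner = "isolated")
  expect_equal(stats::setNames(r3$role, r3$id)[names(expected)], expected)
  expect_error(assign_directional_roles(toy_graph(el, directed = FALSE)),
               "directed")
})

test_that("tier mass ratios and threshold tests behave as specified", {
  traits <- data.frame(id = c("u1", "l1", "l2"), trait = c(10, 6.2, 8.2))
  roles <- data.frame(id = traits$id, role = c("upper", "lower", "lower"))
  r <- tier_mass_ratio(roles, traits, c("upper", "lower"),
                       alternative = "two.sided")
  expect_equal(sort(r$ratios), c(0.62, 0.82))
  expect_equal(r$mean_ratio, 0.72)
  # all ratios exactly at the threshold -> t statistic 0
  phi <- conflict_thresholds()$phi
  t2 <- data.frame(id = c("u1", "u2", "l1", "l2"),
                   trait = c(10, 10, 10 * phi, 10 * phi))
  ro2 <- data.frame(id = t2$id, role = c("up", "up", "lo", "lo"))
  r2 <- tier_mass_ratio(ro2, t2, c("up", "lo"), alternative = "two.sided")
  expect_equal(r2$statistic, 0, tolerance = 1e-9)
  expect_equal(r2$mean_ratio, phi)
  # empty tier errors by name
  expect_error(tier_mass_ratio(roles, traits, c("upper", "missing_tier")),
               "missing_tier")
  # graph restriction keeps only connected cross-tier dyads
  g <- toy_graph(rbind(c("u1", "l1")))
  rg <- tier_mass_ratio(roles, traits, c("upper", "lower"), graph = g,
                        alternative = "two.sided")
  expect_equal(rg$ratios, 0.62)
  # permutation p-value is reproducible and in [0, 1]
  rp <- tier_mass_ratio(ro2, t2, c("up", "lo"), alternative = "two.sided",
                        n_perm = 99, seed = 4)
  expect_true(rp$p_permutation >= 0 && rp$p_permutation <= 1)
})

test_that("planted tier cohorts reproduce the qualitative hypothesis split", {
  co <- generate_cohort(tiers = list(sizes = c(5, 12),
                                     bands = list(c(0.70, 0.80))), seed = 17)
  roles <- data.frame(id = co$id,
                      role = ifelse(co$tier == "tier1", "upper", "lower"))
  up <- tier_mass_ratio(roles, co[, c("id", "trait")], c("upper", "lower"),
                        alternative = "greater")
  expect_equal(up$direction, "above")
  expect_lt(up$p_value, 0.001)
  co2 <- generate_cohort(tiers = list(sizes = c(5, 12),
                                      bands = list(c(0.45, 0.58))), seed = 18)
  roles2 <- data.frame(id = co2$id,
                       role = ifelse(co2$tier == "tier1", "upper", "lower"))
  dn <- tier_mass_ratio(roles2, co2[, c("id", "trait")], c("upper", "lower"),
                        alternative = "less")
  expect_equal(dn$direction, "below")
  expect_lt(dn$p_value, 0.001)
})

test_that("IBS similarity matches its definition on edge cases", {
  g <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, NA, 0, 1))
  s <- ibs_similarity(g)
  expect_equal(s["a", "b"], 1)               # identical rows
  expect_equal(s["a", "c"], mean(c(0, 0, 1))) # (|0-2|, |2-0|, |1-1|) over 3 SNPs
  expect_equal(s, t(s))
  g2 <- rbind(a = rep(0, 5), b = rep(2, 5))
  expect_equal(ibs_similarity(g2)["a", "b"], 0)  # opposite homozygotes
  expect_error(ibs_similarity(rbind(c(0, 3))), "0/1/2")
})

test_that("full-sib relatedness network lands in the Mendelian IBS band", {
  geno <- generate_fullsib_genotypes(40, 1000, seed = 23)
  rel <- relatedness_network(geno, q = 0.1)
  sims <- igraph::graph_attr(rel$network, "dyad_values")
  expect_true(mean(sims) > 0.5 && mean(sims) < 0.9)
  expect_equal(igraph::ecount(rel$network), round(0.1 * 40 * 39 / 2))
  expect_true(all(rel$roles$role %in% c("core", "periphery")))
  expect_error(relatedness_network(geno[, 1:10], q = 0.1), "50 SNPs")
})

test_that("network correlation is symmetric and matches direct computation", {
  withr::with_seed(29, {
    tr <- data.frame(id = paste0("n", 1:5),
                     trait = stats::rlnorm(5, log(50), 0.6))
  })
  nets <- build_networks(tr, q = 0.5)
  self <- network_correlation(nets$mutualism, nets$mutualism)
  expect_equal(self$r, 1)
  ab <- network_correlation(nets$aggression, nets$altruism)
  ba <- network_correlation(nets$altruism, nets$aggression)
  expect_equal(ab$r, ba$r)
  # z_ag and z_al both increase with size disparity -> positive r
  expect_gt(ab$r, 0)
  # matches hand computation on the pre-culling vectors
  dy <- attr(nets, "dyads")
  expect_equal(network_correlation(nets$mutualism, nets$antagonism)$r,
               stats::cor(dy$z_mu, dy$z_an))
  # zero variance is reported as undefined
  flat <- igraph::set_graph_attr(nets$mutualism, "dyad_values",
    stats::setNames(rep(1, 10), names(igraph::graph_attr(nets$mutualism, "dyad_values"))))
  expect_warning(und <- network_correlation(flat, nets$antagonism), "zero variance")
  expect_true(is.na(und$r))
})

test_that("core-periphery trait comparison is a calibrated Welch test", {
  tr <- data.frame(id = paste0("i", 1:6), trait = c(5, 6, 7, 5, 6, 7))
  roles <- data.frame(id = tr$id, role = rep(c("core", "periphery"), each = 3))
  same <- compare_core_periphery_trait(roles, tr)
  expect_equal(same$p_value, 1)
  # disjoint support
  tr2 <- data.frame(id = paste0("i", 1:12),
                    trait = c(seq(1, 1.5, length.out = 6),
                              seq(100, 101, length.out = 6)))
  roles2 <- data.frame(id = tr2$id, role = rep(c("core", "periphery"), each = 6))
  expect_lt(compare_core_periphery_trait(roles2, tr2)$p_value, 1e-6)
  expect_error(compare_core_periphery_trait(
    data.frame(id = "i1", role = "core"), tr), "at least 2")
  # type-I calibration under a random split of a normal trait
  rej <- withr::with_seed(41, mean(replicate(500, {
    traits <- data.frame(id = paste0("i", 1:20),
                         trait = stats::rnorm(20, 100, 10))
    rl <- data.frame(id = traits$id,
                     role = sample(rep(c("core", "periphery"), 10)))
    compare_core_periphery_trait(rl, traits)$p_value < 0.05
  })))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
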