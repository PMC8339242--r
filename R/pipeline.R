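#' Run the full conflict-analysis pipeline
#'
#' Executes the two analysis arms over whatever inputs are supplied and writes
#' all tables plus a reproducibility manifest to `out_dir`:
#' \itemize{
#'   \item cohort arm (needs `traits`): all-pairs descriptors, the four
#'     interaction networks at the configured retention fractions, hierarchy
#'     and directional role tables, and tier body-mass ratio tests against
#'     the decision thresholds; with `genotypes` also the relatedness
#'     network, core/periphery comparison and network correlations.
#'   \item co-culture arm (needs `abundances`): per-pair growth fits, phase
#'     partitions, empirical strengths and per-phase descriptor-strength
#'     correlations.
#' }
#'
#' @param traits trait data frame (`id`, `trait`) or path readable by
#'   [read_traits()].
#' @param abundances long-format abundance data frame or path for
#'   [read_abundances()].
#' @param genotypes genotype matrix or path for [read_genotypes()].
#' @param config list of settings overriding the defaults: `q` (retention
#'   fraction(s), default 0.1), `hub_k` (default 1), `phase_p` (default
#'   0.95), `cor_method` (`"pearson"`), `ordering` (`"per_time"`), `eps`
#'   (1e-9), `growth_model` (`"auto"`), `seed` (1).
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return List with the computed components (`dyads`, `networks`, `roles`,
#'   `tier_tests`, `relatedness`, `network_correlations`, `core_periphery`,
#'   `validation`, `thresholds`, `manifest`), invisibly.
#' @export
run_pipeline <- function(traits = NULL, abundances = NULL, genotypes = NULL,
                         config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(q = 0.1, hub_k = 1, phase_p = 0.95,
                                cor_method = "pearson", ordering = "per_time",
                                eps = 1e-9, growth_model = "auto", seed = 1L),
                           config)
  if (is.character(traits)) traits <- read_traits(traits)
  if (is.character(abundances)) abundances <- read_abundances(abundances)
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  res <- list(thresholds = conflict_thresholds(), config = cfg)

  if (!is.null(traits)) {
    nets <- build_networks(traits, q = cfg$q, eps = cfg$eps)
    res$dyads <- attr(nets, "dyads")
    res$networks <- nets
    res$roles <- list(
      mutualism = assign_mutualism_hierarchy(nets$mutualism, k = cfg$hub_k),
      aggression = assign_directional_roles(nets$aggression),
      altruism = assign_directional_roles(nets$altruism))
    res$tier_tests <- .pipeline_tier_tests(res$roles, traits, nets)
    if (!is.null(genotypes)) {
      rel <- relatedness_network(genotypes, q = .expand_q(cfg$q,
               c("mutualism", "antagonism", "aggression", "altruism"))[[1L]],
               k = cfg$hub_k)
      res$relatedness <- rel
      res$core_periphery <- tryCatch(
        compare_core_periphery_trait(rel$roles, traits),
        error = function(e) NULL)
      all_nets <- c(nets, list(relatedness = rel$network))
      res$network_correlations <- .pipeline_net_cors(all_nets)
    } else {
      res$network_correlations <- .pipeline_net_cors(nets)
    }
  }

  if (!is.null(abundances)) {
    res$validation <- coculture_validation(
      abundances, model = cfg$growth_model, method = cfg$cor_method,
      ordering = cfg$ordering, phase_p = cfg$phase_p, eps = cfg$eps)
  }

  if (!is.null(out_dir)) .write_pipeline(res, traits, out_dir, cfg)
  invisible(res)
}

.pipeline_tier_tests <- function(roles, traits, nets) {
  th <- conflict_thresholds()
  specs <- list(
    list("mutualism", c("primary_leader", "secondary_leader"), th$phi, "greater"),
    list("mutualism", c("secondary_leader", "tertiary_leader"), th$phi, "greater"),
    list("aggression", c("hawk", "hawk_dove"), th$phi, "less"),
    list("aggression", c("hawk_dove", "dove"), th$phi, "less"),
    list("altruism", c("altruist", "altruist_egoist"), th$fib_mark, "greater"),
    list("altruism", c("altruist_egoist", "egoist"), th$fib_mark, "greater"))
  out <- list()
  for (s in specs) {
    r <- tryCatch(
      tier_mass_ratio(roles[[s[[1L]]]], traits, s[[2L]], threshold = s[[3L]],
                      alternative = s[[4L]], graph = nets[[s[[1L]]]]),
      error = function(e) NULL)
    if (!is.null(r)) {
      out[[length(out) + 1L]] <- data.frame(
        network = s[[1L]], upper = s[[2L]][1L], lower = s[[2L]][2L],
        mean_ratio = r$mean_ratio, threshold = r$threshold,
        statistic = r$statistic, p_value = r$p_value, n = r$n,
        direction = r$direction, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

.pipeline_net_cors <- function(nets) {
  nms <- names(nets)
  out <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i < j) {
      nc <- tryCatch(suppressWarnings(network_correlation(nets[[i]], nets[[j]])),
                     error = function(e) NULL)
      if (!is.null(nc)) {
        out[[length(out) + 1L]] <- data.frame(
          net_a = nms[i], net_b = nms[j], r = nc$r, p = nc$p, n = nc$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

.write_pipeline <- function(res, traits, out_dir, cfg) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  if (!is.null(res$dyads)) {
    utils::write.csv(res$dyads, p("dyad_descriptors.csv"), row.names = FALSE)
    for (ty in names(res$networks)) {
      write_network(res$networks[[ty]], p(paste0("network_", ty, ".csv")),
                    p(paste0("network_", ty, ".graphml")))
    }
    for (ty in names(res$roles)) {
      utils::write.csv(res$roles[[ty]], p(paste0("roles_", ty, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(res$tier_tests)) {
      utils::write.csv(res$tier_tests, p("tier_ratio_tests.csv"), row.names = FALSE)
    }
    if (!is.null(res$network_correlations)) {
      utils::write.csv(res$network_correlations, p("network_correlations.csv"),
                       row.names = FALSE)
    }
  }
  if (!is.null(res$validation)) {
    utils::write.csv(res$validation$data, p("strengths.csv"), row.names = FALSE)
    utils::write.csv(res$validation$correlations, p("phase_correlations.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "hawkdove",
    version = as.character(utils::packageVersion("hawkdove")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "seed")],
    inputs = list(n_individuals = if (!is.null(traits)) nrow(traits) else NULL),
    thresholds = res$thresholds)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}
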