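# End-to-end pipeline: simulate/score -> associate -> estimate ->
# communities -> bridge -> controllability -> predictability, with a
# machine-readable report bundle.

#' Build a pipeline run configuration
#'
#' Collects all parameters of a reproducible run. Exactly one of
#' `responses`, `subscales` or `simulate_n` must be supplied as the data
#' source. Every stochastic stage receives its own seed derived
#' deterministically from the master seed (stage_seed = master mod 1e6 +
#' 1009 * stage_index), so stages can be re-run in isolation with
#' identical randomness.
#'
#' @param responses Raw item-response data frame, or NULL.
#' @param subscales Pre-scored subscale data frame, or NULL.
#' @param simulate_n Number of participants to simulate from `gt`, or NULL.
#' @param gt Ground-truth network for simulation; default
#'   [make_ground_truth()].
#' @param simulate_items If TRUE simulate item-level responses and score
#'   them; otherwise simulate subscales directly.
#' @param n_boot Bootstrap replicates for edge selection and the bridge
#'   difference tests; default 5000.
#' @param alpha Edge-decision level; default 0.05.
#' @param ci Percentile-interval coverage; must equal `1 - alpha` unless
#'   `allow_ci_alpha_mismatch = TRUE`.
#' @param seed Master seed.
#' @param spq_map,bag_map,reverse_keyed Scoring configuration.
#' @param bridge_metrics Bridge metrics to difference-test.
#' @param allow_ci_alpha_mismatch Permit `ci != 1 - alpha`.
#' @return A `run_config` list.
#' @export
run_config <- function(responses = NULL, subscales = NULL,
                       simulate_n = NULL, gt = make_ground_truth(),
                       simulate_items = FALSE,
                       n_boot = 5000, alpha = 0.05, ci = 1 - alpha,
                       seed = 1L,
                       spq_map = spq_item_map(), bag_map = bag_item_map(),
                       reverse_keyed = bag_reverse_keyed(),
                       bridge_metrics = c("bei", "bcl", "bbw"),
                       allow_ci_alpha_mismatch = FALSE) {
  sources <- c(!is.null(responses), !is.null(subscales), !is.null(simulate_n))
  if (sum(sources) != 1L) {
    stop("supply exactly one of responses, subscales or simulate_n",
         call. = FALSE)
  }
  if (abs(ci - (1 - alpha)) > 1e-12 && !allow_ci_alpha_mismatch) {
    stop("ci must equal 1 - alpha (set allow_ci_alpha_mismatch = TRUE to override)",
         call. = FALSE)
  }
  structure(
    list(responses = responses, subscales = subscales,
         simulate_n = simulate_n, gt = gt, simulate_items = simulate_items,
         n_boot = as.integer(n_boot), alpha = alpha, ci = ci,
         seed = as.integer(seed), spq_map = spq_map, bag_map = bag_map,
         reverse_keyed = reverse_keyed,
         bridge_metrics = match.arg(bridge_metrics, c("bei", "bcl", "bbw"),
                                    several.ok = TRUE),
         allow_ci_alpha_mismatch = allow_ci_alpha_mismatch),
    class = "run_config"
  )
}

# Write the selected network as GraphML through igraph.
write_network_graphml <- function(network, path) {
  w <- selected_weights(network)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured data source and, when `out_dir`
#' is given, writes the report bundle: exclusion report, subscale CSV,
#' correlation tables, network edge list + GraphML + metadata, community
#' partition JSON, bridge metric and significance tables, controllability
#' and predictability CSVs, and a manifest JSON with all parameters, stage
#' seeds and file checksums.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing), or NULL to skip
#'   writing.
#' @return Invisibly, a list with every stage result (`subscales`,
#'   `exclusion_report`, `correlations`, `network`, `partition`, `bridge`,
#'   `bridge_tests`, `controllability`, `predictability`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- list(
    simulate = stage_seed(config$seed, 1L),
    estimate = stage_seed(config$seed, 2L),
    bridge   = stage_seed(config$seed, 3L)
  )

  exclusion_report <- list(n_total = NA_integer_, n_removed = 0L,
                           prop_removed = 0)
  if (!is.null(config$simulate_n)) {
    if (config$simulate_items) {
      responses <- simulate_item_responses(config$gt, config$simulate_n,
                                           seed = seeds$simulate)
      scored <- score_responses(responses, config$spq_map, config$bag_map,
                                config$reverse_keyed)
      subscales <- scored$subscales
      exclusion_report <- scored$exclusion_report
    } else {
      subscales <- simulate_subscales(config$gt, config$simulate_n,
                                      seed = seeds$simulate)
      exclusion_report$n_total <- nrow(subscales)
    }
  } else if (!is.null(config$responses)) {
    scored <- score_responses(config$responses, config$spq_map,
                              config$bag_map, config$reverse_keyed)
    subscales <- scored$subscales
    exclusion_report <- scored$exclusion_report
  } else {
    subscales <- config$subscales
    exclusion_report$n_total <- nrow(subscales)
  }

  correlations <- correlation_matrix(subscales[, !(names(subscales) %in%
                                                     "participant_id")])
  network <- bootstrap_edge_selection(
    subscales, n_boot = config$n_boot, ci = config$ci, alpha = config$alpha,
    seed = seeds$estimate,
    allow_ci_alpha_mismatch = config$allow_ci_alpha_mismatch)
  partition <- fast_greedy(network)
  bridge <- bridge_scores(network, partition)
  bridge_tests <- lapply(stats::setNames(config$bridge_metrics,
                                         config$bridge_metrics),
                         function(m) {
    bridge_difference_test(subscales, network, partition, metric = m,
                           n_boot = config$n_boot, ci = config$ci,
                           seed = seeds$bridge)
  })
  ctrl <- controllability_scores(network)
  pred <- node_predictability(subscales, network)

  manifest <- list(
    parameters = list(n_boot = config$n_boot, alpha = config$alpha,
                      ci = config$ci, master_seed = config$seed),
    stage_seeds = seeds,
    n = network$n,
    repair_count = network$repair_count,
    n_communities = partition$n_communities,
    modularity = partition$Q,
    conventions = list(
      bridge_distance = attr(bridge, "distance"),
      community_weights = "absolute selected weights",
      controllability_scaling = attr(ctrl, "scaling"),
      controllability_spectral_radius = attr(ctrl, "spectral_radius")
    )
  )

  result <- list(ground_truth = if (!is.null(config$simulate_n)) config$gt,
                 subscales = subscales, exclusion_report = exclusion_report,
                 correlations = correlations, network = network,
                 partition = partition, bridge = bridge,
                 bridge_tests = bridge_tests, controllability = ctrl,
                 predictability = pred, manifest = manifest)

  if (!is.null(out_dir)) {
    result$manifest <- write_report_bundle(result, out_dir)
  }
  invisible(result)
}

# Serialize every stage product; returns the manifest (with checksums).
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)

  jsonlite::write_json(result$exclusion_report, fp("exclusion_report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$ground_truth)) {
    write_ground_truth(result$ground_truth, fp("ground_truth"))
  }
  write.csv(result$subscales, fp("subscales.csv"), row.names = FALSE)
  write.csv(correlation_long(result$correlations),
            fp("correlations_long.csv"), row.names = FALSE)
  write.csv(round(result$correlations$rho, 6), fp("correlations_matrix.csv"))
  utils::write.table(network_edges(result$network), fp("network_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_network_graphml(result$network, fp("network.graphml"))
  jsonlite::write_json(
    list(node = names(result$partition$membership),
         community = unname(result$partition$membership),
         Q = result$partition$Q,
         merge_history = result$partition$merge_history),
    fp("communities.json"), auto_unbox = TRUE, digits = NA)
  write.csv(result$bridge, fp("bridge_scores.csv"), row.names = FALSE)
  for (m in names(result$bridge_tests)) {
    write.csv(result$bridge_tests[[m]]$significant * 1L,
              fp(sprintf("bridge_sig_%s.csv", m)))
  }
  write.csv(result$controllability, fp("controllability.csv"),
            row.names = FALSE)
  write.csv(result$predictability, fp("predictability.csv"),
            row.names = FALSE)

  files <- setdiff(list.files(out_dir), "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- c(result$manifest, list(checksums = checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
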