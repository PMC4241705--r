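#' Pipeline configuration
#'
#' @param hub_percentile Degree quantile defining hubs (default 0.95).
#' @param alpha Structural-score weight in `[0, 1]` (default 0.5).
#' @param beam_width Candidates retained per collection (default 100).
#' @param seed Reserved; the pipeline is fully deterministic and consumes
#'   no randomness.
#' @return An object of class `pinalign_config`.
#' @export
pinalign_config <- function(hub_percentile = 0.95, alpha = 0.5,
                            beam_width = 100, seed = NULL) {
  if (hub_percentile <= 0 || hub_percentile >= 1) {
    abort("`hub_percentile` must be in (0, 1)")
  }
  params <- scoring_params(alpha = alpha, beam_width = beam_width)
  structure(list(hub_percentile = hub_percentile, alpha = params$alpha,
                 beam_width = params$beam_width, seed = seed),
            class = "pinalign_config")
}

#' Align two protein-protein interaction networks
#'
#' Runs the full local-alignment pipeline: hub selection and clustering of
#' the first network, per-cluster candidate construction by beam-pruned
#' merging, the candidate-derived similarity bipartite graph, its
#' duplication-aware matching reduction, and greedy extraction of the
#' final set of one-to-one and one-to-two matches. Only the first network
#' is clustered; the roles of the two networks are not symmetric.
#'
#' @param g1 The clustered [ppi_network].
#' @param g2 The second [ppi_network].
#' @param scores A [score_table] of cross-network bit scores (may be
#'   empty, yielding an empty alignment).
#' @param config A [pinalign_config].
#' @param quiet Suppress stage progress messages.
#' @return An object of class `pinalign_result`: list with `alignment`
#'   (a [ppi_alignment]), `clustering`, `final_collections`, `isbg`,
#'   `sim_graph`, `config` and `stats` (one-row tibble of stage counts).
#' @export
run_pinalign <- function(g1, g2, scores, config = pinalign_config(),
                         quiet = FALSE) {
  stopifnot(inherits(g1, "ppi_network"), inherits(g2, "ppi_network"),
            inherits(scores, "score_table"), inherits(config, "pinalign_config"))
  if (length(g1$nodes) == 0 || length(g2$nodes) == 0) {
    abort("both networks must be nonempty")
  }
  say <- function(...) if (!quiet) inform(sprintf(...))
  params <- scoring_params(alpha = config$alpha,
                           beam_width = config$beam_width)

  hubs <- select_hubs(g1, config$hub_percentile)
  clustering <- assign_to_clusters(g1, hubs)
  clusters <- cluster_members(clustering)
  say("hub clustering: %d hubs, %d clusters, %d unassigned node(s)",
      length(hubs), length(clusters), length(clustering$unassigned))

  ctx <- list(P1 = prob_matrix(g1), P2 = prob_matrix(g2),
              g2_nodes = g2$nodes)
  final_ccs <- purrr::map(clusters, function(cl) {
    withCallingHandlers(
      align_hub_cluster_impl(cl, ctx, scores, params),
      message = function(m) if (quiet) invokeRestart("muffleMessage"))
  })
  say("candidate engine: final collection sizes [%s], cardinalities [%s]",
      paste(vapply(final_ccs, function(cc) length(cc$g1_vertices), 0L),
            collapse = ","),
      paste(vapply(final_ccs, function(cc) length(cc$candidates), 0L),
            collapse = ","))

  isbg <- build_isbg(final_ccs, g1, g2, scores)
  simg <- build_sim_graph(isbg)
  say("similarity graph: %d ISBG edges -> %d reduced edges",
      nrow(isbg$edges), nrow(simg$edges))

  alignment <- greedy_final_alignment(simg)
  say("alignment: %d matches, %d one-to-two matches, total weight %.4g",
      sum(alignment$type == "match"), sum(alignment$type == "dmatch"),
      sum(alignment$weight))

  stats <- tibble(
    n_hubs = length(hubs),
    n_clusters = length(clusters),
    n_unassigned = length(clustering$unassigned),
    n_isbg_edges = nrow(isbg$edges),
    n_simg_edges = nrow(simg$edges),
    n_matches = sum(alignment$type == "match"),
    n_dmatches = sum(alignment$type == "dmatch"),
    total_weight = sum(alignment$weight))

  structure(list(alignment = alignment, clustering = clustering,
                 final_collections = final_ccs, isbg = isbg,
                 sim_graph = simg, config = config, stats = stats),
            class = "pinalign_result")
}

#' @export
print.pinalign_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<pinalign_result> %d matches + %d one-to-two matches (total weight %.4g)\n",
              s$n_matches, s$n_dmatches, s$total_weight))
  cat(sprintf("%d hub clusters, %d ISBG edges, %d reduced edges\n",
              s$n_clusters, s$n_isbg_edges, s$n_simg_edges))
  invisible(x)
}

#' Alignment records of a pipeline result
#'
#' @param x A `pinalign_result`.
#' @param ... Unused.
#' @return The alignment as a tibble (`type`, `g1_members`, `g2_members`,
#'   `weight`).
#' @method tidy pinalign_result
#' @export
tidy.pinalign_result <- function(x, ...) {
  as_tibble(x$alignment)
}

#' One-row summary of a pipeline result
#'
#' @param x A `pinalign_result`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts and the total alignment weight.
#' @method glance pinalign_result
#' @export
glance.pinalign_result <- function(x, ...) {
  x$stats
}

#' Record-weight plot of a pipeline result
#'
#' @param object A `pinalign_result`.
#' @param ... Passed on to [autoplot.ppi_alignment()].
#' @return A ggplot object.
#' @method autoplot pinalign_result
#' @export
autoplot.pinalign_result <- function(object, ...) {
  autoplot(object$alignment, ...)
}

#' Write the intermediate similarity graphs of a result
#'
#' Dumps the ISBG and the reduced similarity graph as weighted edge-list
#' TSVs (`isbg.tsv`, `simg.tsv`) for inspection or to resume the matching
#' stage.
#'
#' @param result A `pinalign_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_intermediates <- function(result, dir) {
  stopifnot(inherits(result, "pinalign_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("isbg", "sim_graph")) {
    df <- as.data.frame(result[[nm]]$edges)
    if (nrow(df)) {
      df$weight <- format(df$weight, digits = 15, trim = TRUE,
                          scientific = FALSE)
    }
    write.table(df, file.path(dir, if (nm == "isbg") "isbg.tsv" else "simg.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
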