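#' Weighted protein-protein interaction network
#'
#' A `ppi_network` stores an undirected network whose nodes are protein
#' identifiers and whose edges carry the probability that the two proteins
#' interact. Edge probabilities must lie in `(0, 1]`; the corresponding edge
#' *length*, used by shortest-path steps, is `-log(p)` (0 exactly when
#' `p = 1`). Self-loops are dropped with a warning and duplicate edges are
#' collapsed to the maximum probability.
#'
#' @param edges A data frame with columns `node1`, `node2` and optionally
#'   `prob` (defaults to 1 when absent). Extra columns are ignored.
#' @param nodes Optional character vector of additional node identifiers
#'   (e.g. proteins with no observed interaction); the node set is the union
#'   of these and all edge endpoints.
#' @param species Species tag carried along for labelling.
#'
#' @return An object of class `ppi_network`: a list with elements `edges`
#'   (tibble `node1`, `node2`, `prob`, canonically ordered), `nodes`
#'   (sorted character vector) and `species`.
#'
#' @details Node identifiers are opaque, case-sensitive strings; no accession
#' normalisation is attempted. A probability of exactly 0 is rejected rather
#' than read as "no edge": absent edges are simply absent.
#'
#' @examples
#' net <- ppi_network(data.frame(node1 = c("a", "b"), node2 = c("b", "c"),
#'                               prob = c(0.5, 0.9)))
#' net$nodes
#' @export
ppi_network <- function(edges, nodes = NULL, species = "") {
  edges <- as_tibble(edges)
  if (!all(c("node1", "node2") %in% names(edges))) {
    abort("`edges` must have columns `node1` and `node2`.")
  }
  if (!"prob" %in% names(edges)) edges$prob <- 1
  edges <- edges[, c("node1", "node2", "prob")]
  edges$node1 <- as.character(edges$node1)
  edges$node2 <- as.character(edges$node2)
  edges$prob <- as.numeric(edges$prob)
  bad <- !is.finite(edges$prob) | edges$prob <= 0 | edges$prob > 1
  if (any(bad)) {
    abort(sprintf("edge probabilities must lie in (0, 1]; %d offending edge(s), first: %s-%s p=%s",
                  sum(bad), edges$node1[bad][1], edges$node2[bad][1],
                  format(edges$prob[bad][1])))
  }
  loops <- edges$node1 == edges$node2
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical orientation, duplicates collapse to max probability
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  edges$node1 <- a
  edges$node2 <- b
  edges <- edges |>
    group_by(.data$node1, .data$node2) |>
    summarise(prob = max(.data$prob), .groups = "drop") |>
    arrange(.data$node1, .data$node2)
  all_nodes <- sort(unique(c(edges$node1, edges$node2, as.character(nodes))))
  structure(list(edges = edges, nodes = all_nodes, species = species),
            class = "ppi_network")
}

#' Read a PPI network from a text file
#'
#' Two dialects are supported: a 2-3 column whitespace/tab separated edge
#' list (`node1 node2 [prob]`, probability defaulting to 1 when the third
#' column is missing) and the SIF dialect (`node1 relation node2`, all edges
#' given probability 1).
#'
#' @param path Path to the file.
#' @param format `"tsv"` (edge list, default) or `"sif"`.
#' @param species Species tag attached to the result.
#' @return A [ppi_network].
#' @export
read_network <- function(path, format = c("tsv", "sif"), species = "") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  n1 <- character(length(fields)); n2 <- character(length(fields))
  pr <- numeric(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (format == "sif") {
      if (length(f) != 3) {
        abort(sprintf("line %d: SIF rows need 3 fields, got %d", idx[i], length(f)))
      }
      n1[i] <- f[1]; n2[i] <- f[3]; pr[i] <- 1
    } else {
      if (length(f) < 2 || length(f) > 3) {
        abort(sprintf("line %d: expected 2 or 3 fields, got %d", idx[i], length(f)))
      }
      n1[i] <- f[1]; n2[i] <- f[2]
      if (length(f) == 3) {
        p <- suppressWarnings(as.numeric(f[3]))
        if (is.na(p)) abort(sprintf("line %d: cannot parse probability '%s'", idx[i], f[3]))
        if (p <= 0 || p > 1) {
          abort(sprintf("line %d: probability %s outside (0, 1]", idx[i], f[3]))
        }
        pr[i] <- p
      } else {
        pr[i] <- 1
      }
    }
  }
  ppi_network(tibble(node1 = n1, node2 = n2, prob = pr), species = species)
}

#' Serialise a network as a 3-column edge list
#'
#' @param net A [ppi_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  df <- as.data.frame(net$edges)
  df$prob <- format(df$prob, digits = 15, trim = TRUE, scientific = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network%s> %d nodes, %d edges\n",
              if (nzchar(x$species)) paste0(" ", x$species) else "",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# igraph view of a network; edge attribute `prob`, `length` = -log(prob)
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
  igraph::E(g)$length <- -log(igraph::E(g)$prob)
  g
}

# dense symmetric probability matrix, 0 = no edge, dimnames = nodes.
# Intended for desk-scale networks (the DP scoring needs random access).
prob_matrix <- function(net) {
  n <- length(net$nodes)
  P <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  i <- match(net$edges$node1, net$nodes)
  j <- match(net$edges$node2, net$nodes)
  P[cbind(i, j)] <- net$edges$prob
  P[cbind(j, i)] <- net$edges$prob
  P
}

# degree of every node (isolated nodes count 0)
node_degrees <- function(net) {
  tab <- table(c(net$edges$node1, net$edges$node2))
  d <- setNames(rep(0L, length(net$nodes)), net$nodes)
  d[names(tab)] <- as.integer(tab)
  d
}

# adjacency list: node -> character vector of neighbours
neighbour_list <- function(net) {
  nb <- split(c(net$edges$node2, net$edges$node1),
              c(net$edges$node1, net$edges$node2))
  out <- setNames(vector("list", length(net$nodes)), net$nodes)
  out[names(nb)] <- nb
  out
}

#' Degree distribution plot for a network
#'
#' @param object A [ppi_network].
#' @param ... Unused.
#' @return A ggplot object showing the node-degree distribution on
#'   log-scaled axes (hubs appear in the upper tail).
#' @method autoplot ppi_network
#' @export
autoplot.ppi_network <- function(object, ...) {
  d <- node_degrees(object)
  df <- tibble(degree = as.integer(names(table(d))),
               count = as.integer(table(d)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "number of nodes",
                  title = sprintf("Degree distribution%s",
                                  if (nzchar(object$species))
                                    paste0(" (", object$species, ")") else ""))
}
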