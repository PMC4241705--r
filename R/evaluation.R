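#' Equivalence classes of an alignment
#'
#' Aligned-to is made transitive: a match links its two proteins, a
#' one-to-two match links its centre to both partners, and the connected
#' components of the resulting relation are the equivalence classes (each
#' of size >= 2). Proteins are tracked together with the network they come
#' from, so identical identifiers in the two networks stay distinct.
#'
#' @param alignment A [ppi_alignment].
#' @return An object of class `equivalence_classes`: a tibble with columns
#'   `class_id`, `protein`, `network` (`"g1"`/`"g2"`).
#' @export
to_equivalence_classes <- function(alignment) {
  pairs <- alignment_pairs(alignment)   # also validates record consistency
  if (nrow(pairs) == 0) {
    out <- tibble(class_id = integer(), protein = character(),
                  network = character())
    class(out) <- c("equivalence_classes", class(out))
    return(out)
  }
  a <- paste0("g1\r", pairs$g1)
  b <- paste0("g2\r", pairs$g2)
  g <- igraph::graph_from_data_frame(data.frame(from = a, to = b),
                                     directed = FALSE)
  comp <- igraph::components(g)
  nm <- names(comp$membership)
  parts <- strsplit(nm, "\r", fixed = TRUE)
  out <- tibble(class_id = as.integer(comp$membership),
                protein = vapply(parts, `[`, "", 2),
                network = vapply(parts, `[`, "", 1)) |>
    arrange(.data$class_id, .data$network, .data$protein)
  class(out) <- c("equivalence_classes", class(tibble()))
  out
}

#' Specificity and sensitivity of an alignment against ortholog groups
#'
#' A class is correct iff every member is annotated and all annotations
#' agree. The four measures: `c_eq`, the fraction of classes that are
#' correct (specificity); `c_node`, the fraction of member proteins lying
#' in correct classes (specificity); `c_or`, the number of proteins in
#' correct classes (sensitivity); `tot`, the number of classes containing
#' proteins of both networks (sensitivity).
#'
#' @param classes An `equivalence_classes` tibble from
#'   [to_equivalence_classes()].
#' @param ko A [ko_mapping].
#' @param exclude_unannotated If `TRUE`, classes containing any unannotated
#'   protein are dropped from the denominators instead of counting as
#'   incorrect.
#' @return A one-row tibble with columns `c_eq`, `c_node`, `c_or`, `tot`.
#' @export
score_against_groups <- function(classes, ko, exclude_unannotated = FALSE) {
  stopifnot(inherits(ko, "ko_mapping"))
  if (nrow(classes) == 0) {
    inform("no equivalence classes; all metrics are 0")
    return(tibble(c_eq = 0, c_node = 0, c_or = 0L, tot = 0L))
  }
  per_class <- classes |>
    mutate(group = ko_lookup(ko, .data$protein)) |>
    group_by(.data$class_id) |>
    summarise(size = n(),
              n_species = dplyr::n_distinct(.data$network),
              annotated = !anyNA(.data$group),
              correct = !anyNA(.data$group) &&
                dplyr::n_distinct(.data$group) == 1L,
              .groups = "drop")
  tot <- sum(per_class$n_species == 2L)
  if (exclude_unannotated) per_class <- filter(per_class, .data$annotated)
  n_classes <- nrow(per_class)
  n_nodes <- sum(per_class$size)
  c_or <- sum(per_class$size[per_class$correct])
  tibble(c_eq = if (n_classes) sum(per_class$correct) / n_classes else 0,
         c_node = if (n_nodes) c_or / n_nodes else 0,
         c_or = as.integer(c_or),
         tot = as.integer(tot))
}

#' Evaluate an alignment against an ortholog-group mapping
#'
#' Convenience wrapper: [to_equivalence_classes()] then
#' [score_against_groups()].
#'
#' @inheritParams to_equivalence_classes
#' @inheritParams score_against_groups
#' @return A one-row tibble `c_eq`, `c_node`, `c_or`, `tot`.
#' @export
evaluate_alignment <- function(alignment, ko, exclude_unannotated = FALSE) {
  score_against_groups(to_equivalence_classes(alignment), ko,
                       exclude_unannotated = exclude_unannotated)
}
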