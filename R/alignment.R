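#' Alignment record table
#'
#' The final alignment is a tibble of records, one per row, with class
#' `ppi_alignment`. A `match` row pairs one network-1 protein with one
#' network-2 protein. A `dmatch` row aligns a centre protein from one
#' network with two partner proteins from the other (modelling gene
#' duplication/divergence); the centre sits alone in its network's column.
#' No protein appears in more than one record.
#'
#' @param records A data frame with columns `type` (`"match"`/`"dmatch"`),
#'   `g1_members`, `g2_members` (comma-joined protein IDs) and `weight`.
#' @return A `ppi_alignment` tibble, rows ordered by first network-1 member.
#' @export
ppi_alignment <- function(records) {
  records <- as_tibble(records)
  need <- c("type", "g1_members", "g2_members", "weight")
  if (!all(need %in% names(records))) {
    abort("records need columns type, g1_members, g2_members, weight")
  }
  records <- records[, need]
  records$type <- as.character(records$type)
  records$g1_members <- as.character(records$g1_members)
  records$g2_members <- as.character(records$g2_members)
  records$weight <- as.numeric(records$weight)
  if (!all(records$type %in% c("match", "dmatch"))) {
    abort("record type must be 'match' or 'dmatch'")
  }
  g1 <- strsplit(records$g1_members, ",", fixed = TRUE)
  g2 <- strsplit(records$g2_members, ",", fixed = TRUE)
  sizes_ok <- (records$type == "match" & lengths(g1) == 1 & lengths(g2) == 1) |
    (records$type == "dmatch" &
       ((lengths(g1) == 1 & lengths(g2) == 2) |
          (lengths(g1) == 2 & lengths(g2) == 1)))
  if (!all(sizes_ok)) {
    abort("match rows need 1+1 members; dmatch rows need 1+2 or 2+1")
  }
  if (anyDuplicated(unlist(g1)) || anyDuplicated(unlist(g2))) {
    abort("a protein appears in more than one alignment record")
  }
  records <- records[order(vapply(g1, `[`, "", 1),
                           vapply(g2, `[`, "", 1)), , drop = FALSE]
  class(records) <- c("ppi_alignment", class(tibble()))
  records
}

#' Write an alignment to a TSV file
#'
#' Columns `type`, `g1_members`, `g2_members`, `weight`; deterministic row
#' order (sorted by first network-1 member). An empty alignment yields a
#' header-only file.
#'
#' @param alignment A [ppi_alignment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  alignment <- ppi_alignment(alignment)
  df <- as.data.frame(alignment)
  df$weight <- format(df$weight, digits = 15, trim = TRUE, scientific = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an alignment written by [write_alignment()]
#'
#' @param path Path to the TSV file.
#' @return A [ppi_alignment].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "character", "numeric"))
  ppi_alignment(df)
}

#' Expand an alignment into aligned protein pairs
#'
#' Each `match` contributes one (network-1, network-2) pair; each `dmatch`
#' contributes two pairs sharing its centre.
#'
#' @param alignment A [ppi_alignment].
#' @return A tibble with columns `g1`, `g2`, `record` (row index of the
#'   originating record).
#' @export
alignment_pairs <- function(alignment) {
  alignment <- ppi_alignment(alignment)
  if (nrow(alignment) == 0) {
    return(tibble(g1 = character(), g2 = character(), record = integer()))
  }
  g1 <- strsplit(alignment$g1_members, ",", fixed = TRUE)
  g2 <- strsplit(alignment$g2_members, ",", fixed = TRUE)
  purrr::map_dfr(seq_len(nrow(alignment)), function(i) {
    tidyr::expand_grid(g1 = g1[[i]], g2 = g2[[i]]) |>
      mutate(record = i)
  })
}

#' Weight histogram of alignment records
#'
#' @param object A [ppi_alignment].
#' @param ... Unused.
#' @return A ggplot object: record weights by record type.
#' @method autoplot ppi_alignment
#' @export
autoplot.ppi_alignment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$weight, fill = .data$type)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::labs(x = "record weight", y = "records",
                  title = "Alignment record weights")
}
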