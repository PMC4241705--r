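#' Sparse cross-species similarity score table
#'
#' Stores BLAST bit scores between proteins of the first and second network
#' as a sparse map: only strictly positive scores are kept, and looking up
#' an absent pair returns 0. Duplicate pairs collapse to the maximum score.
#'
#' @param pairs A data frame with columns `id1` (protein in network 1),
#'   `id2` (protein in network 2) and `score` (bit score, `>= 0`).
#' @return An object of class `score_table`: list with `pairs` (tibble of
#'   the stored positive entries) and an internal lookup index.
#' @export
score_table <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("id1", "id2", "score") %in% names(pairs))) {
    abort("`pairs` must have columns `id1`, `id2`, `score`.")
  }
  pairs$id1 <- as.character(pairs$id1)
  pairs$id2 <- as.character(pairs$id2)
  pairs$score <- as.numeric(pairs$score)
  if (any(!is.finite(pairs$score) | pairs$score < 0)) {
    abort("scores must be finite and >= 0")
  }
  pairs <- filter(pairs, .data$score > 0)
  if (nrow(pairs) > 0) {
    pairs <- pairs |>
      group_by(.data$id1, .data$id2) |>
      summarise(score = max(.data$score), .groups = "drop") |>
      arrange(.data$id1, .data$id2)
  }
  index <- setNames(pairs$score, pair_key(pairs$id1, pairs$id2))
  structure(list(pairs = pairs, index = index), class = "score_table")
}

#' Read a similarity score table
#'
#' Expects whitespace/tab separated rows `id1 id2 score`. Zero scores are
#' not stored; duplicates keep the maximum; negative scores are an error.
#'
#' @param path Path to the file.
#' @return A [score_table].
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(fields) != 3)
  if (length(bad)) {
    abort(sprintf("line %d: expected 3 fields, got %d",
                  idx[bad[1]], lengths(fields)[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 3, byrow = TRUE)
  sc <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(sc)) {
    i <- which(is.na(sc))[1]
    abort(sprintf("line %d: cannot parse score '%s'", idx[i], m[i, 3]))
  }
  if (any(sc < 0)) {
    i <- which(sc < 0)[1]
    abort(sprintf("line %d: negative score %s", idx[i], m[i, 3]))
  }
  score_table(tibble(id1 = m[, 1], id2 = m[, 2], score = sc))
}

#' Look up bit scores for protein pairs
#'
#' @param scores A [score_table].
#' @param id1,id2 Character vectors (recycled to common length).
#' @return Numeric vector of scores; 0 for pairs not stored.
#' @export
score_lookup <- function(scores, id1, id2) {
  stopifnot(inherits(scores, "score_table"))
  v <- unname(scores$index[pair_key(id1, id2)])
  v[is.na(v)] <- 0
  v
}

# all stored partners (and scores) of one network-1 protein
score_partners <- function(scores, id1) {
  p <- scores$pairs[scores$pairs$id1 == id1, , drop = FALSE]
  setNames(p$score, p$id2)
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d positive pairs, %d x %d proteins\n",
              nrow(x$pairs), length(unique(x$pairs$id1)),
              length(unique(x$pairs$id2))))
  invisible(x)
}
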