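#' Protein to ortholog-group mapping
#'
#' Maps protein identifiers to ortholog-group identifiers (e.g. KEGG
#' Orthology IDs). Each protein belongs to at most one group; proteins
#' absent from the mapping are treated as unannotated.
#'
#' @param mapping A data frame with columns `protein` and `group`.
#' @return An object of class `ko_mapping`.
#' @export
ko_mapping <- function(mapping) {
  mapping <- as_tibble(mapping)
  if (!all(c("protein", "group") %in% names(mapping))) {
    abort("`mapping` must have columns `protein` and `group`.")
  }
  mapping$protein <- as.character(mapping$protein)
  mapping$group <- as.character(mapping$group)
  mapping <- distinct(mapping, .data$protein, .data$group)
  dup <- duplicated(mapping$protein)
  if (any(dup)) {
    abort(sprintf("protein(s) mapped to more than one group, first: %s",
                  mapping$protein[dup][1]))
  }
  mapping <- arrange(mapping, .data$protein)
  structure(list(mapping = mapping,
                 index = setNames(mapping$group, mapping$protein)),
            class = "ko_mapping")
}

#' Read an ortholog-group mapping from a 2-column file
#'
#' Rows are `protein group`, whitespace/tab separated.
#'
#' @param path Path to the file.
#' @return A [ko_mapping].
#' @export
read_ko_mapping <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(fields) != 2)
  if (length(bad)) {
    abort(sprintf("line %d: expected 2 fields, got %d",
                  idx[bad[1]], lengths(fields)[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 2, byrow = TRUE)
  ko_mapping(tibble(protein = m[, 1], group = m[, 2]))
}

# group of each protein; NA when unannotated
ko_lookup <- function(ko, proteins) {
  unname(ko$index[proteins])
}

#' @export
print.ko_mapping <- function(x, ...) {
  cat(sprintf("<ko_mapping> %d proteins in %d groups\n",
              nrow(x$mapping), length(unique(x$mapping$group))))
  invisible(x)
}
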