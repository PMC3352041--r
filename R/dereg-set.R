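#' Deregulation sets
#'
#' A deregulation set maps entity identifiers (gene symbols or miRNA ids) to
#' a direction of deregulation: `+1` (up-regulated) or `-1` (down-regulated).
#' Identifiers are normalized on construction: surrounding whitespace is
#' trimmed, gene symbols are upper-cased, and miRNA ids keep their original
#' case but are compared case-insensitively (the field's own usage mixes
#' e.g. `hsa-miR-17` and `hsa-mir-17`).
#'
#' @param ids character vector of identifiers.
#' @param directions integer/numeric vector of `+1` / `-1`, recycled to
#'   length 1 only if scalar.
#' @param entity_class `"miRNA"` or `"gene"`.
#'
#' @return An object of class `dereg_set`: a list with elements
#'   `entity_class` and `entries`, a data frame with columns `id` (display
#'   identifier), `key` (normalized identifier used for all matching) and
#'   `direction`.
#' @export
dereg_set <- function(ids, directions, entity_class = c("miRNA", "gene")) {
  entity_class <- match.arg(entity_class)
  stopifnot(length(ids) == length(directions))
  ids <- trimws(as.character(ids))
  directions <- as.integer(directions)
  if (any(is.na(directions)) || !all(directions %in% c(1L, -1L))) {
    stop("directions must be +1 or -1")
  }
  key <- normalize_id(ids, entity_class)

  df <- data.frame(id = ids, key = key, direction = directions,
                   stringsAsFactors = FALSE)
  df <- unique(df[, c("key", "id", "direction")])
  # identical duplicate rows are dropped silently; conflicting directions
  # for one normalized identifier are an error, never last-wins
  dup <- df$key[duplicated(df$key)]
  if (length(dup) > 0) {
    conflicting <- unique(dup[vapply(dup, function(k) {
      length(unique(df$direction[df$key == k])) > 1L
    }, logical(1))])
    if (length(conflicting) > 0) {
      stop("conflicting deregulation directions for: ",
           paste(conflicting, collapse = ", "))
    }
    df <- df[!duplicated(df$key), ]
  }
  df <- df[order(df$key), c("id", "key", "direction")]
  rownames(df) <- NULL
  structure(list(entity_class = entity_class, entries = df),
            class = "dereg_set")
}

#' Normalize identifiers for matching
#'
#' Gene symbols are compared upper-case; miRNA ids case-insensitively
#' (lower-cased key, display case preserved elsewhere).
#'
#' @param ids character vector.
#' @param entity_class `"miRNA"` or `"gene"`.
#' @return character vector of normalized keys.
#' @export
normalize_id <- function(ids, entity_class = c("miRNA", "gene")) {
  entity_class <- match.arg(entity_class)
  ids <- trimws(ids)
  if (entity_class == "gene") toupper(ids) else tolower(ids)
}

#' @export
print.dereg_set <- function(x, ...) {
  n_up <- sum(x$entries$direction == 1L)
  n_down <- sum(x$entries$direction == -1L)
  cat(sprintf("<dereg_set> %s: %d entries (%d up, %d down)\n",
              x$entity_class, nrow(x$entries), n_up, n_down))
  invisible(x)
}

#' Number of entries in a deregulation set
#' @param x a `dereg_set`.
#' @export
dereg_size <- function(x) nrow(x$entries)

#' Normalized identifiers of a deregulation set
#' @param x a `dereg_set`.
#' @param direction optional `+1` or `-1` to restrict to one direction.
#' @return character vector of normalized keys.
#' @export
dereg_keys <- function(x, direction = NULL) {
  e <- x$entries
  if (!is.null(direction)) e <- e[e$direction == direction, ]
  e$key
}

#' Direction lookup for arbitrary identifiers
#'
#' Maps identifiers to their deregulation status against a set: `+1`, `-1`,
#' or `0` for identifiers absent from the set.
#'
#' @param x a `dereg_set`.
#' @param ids character vector of identifiers (normalized internally).
#' @return integer vector of the same length as `ids`.
#' @export
dereg_status <- function(x, ids) {
  key <- normalize_id(ids, x$entity_class)
  dir <- x$entries$direction[match(key, x$entries$key)]
  dir[is.na(dir)] <- 0L
  dir
}

#' Per-class summary of deregulation counts
#'
#' @param mir_dereg a miRNA `dereg_set`.
#' @param gene_dereg a gene `dereg_set`.
#' @return data frame with one row per entity class and columns
#'   `entity_class`, `n_up`, `n_down`, `n_total` (`n_up + n_down`).
#' @export
summarize_inputs <- function(mir_dereg, gene_dereg) {
  one <- function(x, label) {
    data.frame(entity_class = label,
               n_up = sum(x$entries$direction == 1L),
               n_down = sum(x$entries$direction == -1L),
               n_total = nrow(x$entries),
               stringsAsFactors = FALSE)
  }
  rbind(one(gene_dereg, "genes"), one(mir_dereg, "miRNAs"))
}
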