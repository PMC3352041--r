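#' Read a two-column deregulation list
#'
#' Each non-empty line holds an identifier and a direction token, separated
#' by tabs or whitespace. The direction is `1` for up-regulation and `-1`
#' for down-regulation; both the ASCII hyphen (`-1`) and the Unicode minus
#' (`−1`) are accepted. Identical duplicate lines are dropped silently;
#' the same identifier with two different directions is an error.
#'
#' @param path path to the list file.
#' @param entity_class `"miRNA"` or `"gene"`.
#' @return a [dereg_set()].
#' @export
read_deregulation_file <- function(path, entity_class = c("miRNA", "gene")) {
  entity_class <- match.arg(entity_class)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("empty deregulation file: ", path)

  parts <- strsplit(trimws(lines), "[\t[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    stop(sprintf("line %d of %s: expected two columns (identifier, direction)",
                 lineno[bad[1]], path))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  tok <- vapply(parts, `[[`, character(1), 2L)
  tok <- gsub("−", "-", tok)   # Unicode minus -> ASCII hyphen
  ok <- tok %in% c("1", "+1", "-1")
  if (!all(ok)) {
    stop(sprintf("line %d of %s: malformed direction token '%s' (must be 1 or -1)",
                 lineno[which(!ok)[1]], path, tok[which(!ok)[1]]))
  }
  dereg_set(ids, ifelse(tok == "-1", -1L, 1L), entity_class)
}

#' Write a deregulation list
#'
#' Inverse of [read_deregulation_file()]: one `identifier<TAB>direction`
#' line per entry, in normalized-key order.
#'
#' @param x a `dereg_set`.
#' @param path output path.
#' @export
write_deregulation_file <- function(x, path) {
  stopifnot(inherits(x, "dereg_set"))
  writeLines(sprintf("%s\t%d", x$entries$id, x$entries$direction), path)
  invisible(path)
}

#' miRNA-target interaction tables
#'
#' Constructor for the regulatory universe: unique (miRNA, gene) pairs with
#' an optional prediction score in \[0, 1\]. Duplicate pairs collapse to the
#' smallest score. All miRNA ids must share one organism prefix (the token
#' before the first `-`, e.g. `hsa`).
#'
#' @param mirna,gene character vectors of equal length.
#' @param score optional numeric vector of prediction p-values in \[0, 1\]
#'   (`NA` allowed for unscored rows).
#' @return object of class `interaction_table`: list with `pairs` (data
#'   frame `mirna`, `gene`, `score`, plus normalized `mirna_key`,
#'   `gene_key`) and `organism`.
#' @export
interaction_table <- function(mirna, gene, score = NULL) {
  stopifnot(length(mirna) == length(gene))
  mirna <- trimws(as.character(mirna)); gene <- trimws(as.character(gene))
  if (length(mirna) == 0) stop("interaction table is empty")
  if (is.null(score)) score <- rep(NA_real_, length(mirna))
  score <- as.numeric(score)
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    stop("interaction scores must lie in [0, 1]")
  }
  prefix <- sub("-.*$", "", tolower(mirna))
  org <- unique(prefix)
  if (length(org) != 1) {
    stop("mixed organism prefixes in miRNA ids: ", paste(org, collapse = ", "))
  }
  df <- data.frame(mirna = mirna, gene = gene, score = score,
                   mirna_key = normalize_id(mirna, "miRNA"),
                   gene_key = normalize_id(gene, "gene"),
                   stringsAsFactors = FALSE)
  # collapse duplicate pairs keeping the smallest (most confident) score
  o <- order(df$mirna_key, df$gene_key, df$score, na.last = TRUE)
  df <- df[o, ]
  df <- df[!duplicated(df[, c("mirna_key", "gene_key")]), ]
  rownames(df) <- NULL
  structure(list(pairs = df, organism = org), class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> %d pairs, %d miRNAs, %d genes, organism '%s'\n",
              nrow(x$pairs), length(unique(x$pairs$mirna_key)),
              length(unique(x$pairs$gene_key)), x$organism))
  invisible(x)
}

#' Read a miRNA-target interaction table
#'
#' Tab-delimited columns: miRNA id, gene id, optional prediction p-value.
#' When a score column is present, rows are retained only if their score is
#' strictly below `score_threshold`; unscored rows are always retained.
#' Duplicate pairs collapse to the smallest score. The organism is inferred
#' from the miRNA id prefix and all rows must agree.
#'
#' @param path path to the table.
#' @param score_threshold retain scored rows with score `< score_threshold`
#'   (default 0.01, the conventional prediction cut-off).
#' @return an [interaction_table()].
#' @export
read_interaction_table <- function(path, score_threshold = 0.01) {
  stopifnot(score_threshold > 0, score_threshold <= 1)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty interaction file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 2 | nc > 3)) {
    stop("interaction rows must have 2 or 3 tab-delimited columns: ", path)
  }
  mirna <- vapply(parts, `[[`, character(1), 1L)
  gene <- vapply(parts, `[[`, character(1), 2L)
  score <- rep(NA_real_, length(parts))
  has3 <- nc == 3L
  score[has3] <- suppressWarnings(
    as.numeric(vapply(parts[has3], `[[`, character(1), 3L)))
  if (any(has3 & is.na(score))) stop("non-numeric score in: ", path)

  keep <- is.na(score) | score < score_threshold
  if (!any(keep)) stop("no interactions remain below threshold ",
                       score_threshold)
  interaction_table(mirna[keep], gene[keep], score[keep])
}

#' Write an interaction table
#'
#' Scored rows are written with three columns, unscored rows with two.
#'
#' @param x an `interaction_table`.
#' @param path output path.
#' @export
write_interaction_table <- function(x, path) {
  stopifnot(inherits(x, "interaction_table"))
  p <- x$pairs
  out <- ifelse(is.na(p$score),
                sprintf("%s\t%s", p$mirna, p$gene),
                sprintf("%s\t%s\t%.*g", p$mirna, p$gene, 15, p$score))
  writeLines(out, path)
  invisible(path)
}

#' All gene keys / miRNA keys of an interaction table
#' @param x an `interaction_table`.
#' @return sorted character vector of normalized keys.
#' @export
interaction_genes <- function(x) sort(unique(x$pairs$gene_key))

#' @rdname interaction_genes
#' @export
interaction_mirnas <- function(x) sort(unique(x$pairs$mirna_key))

#' Gene-set category databases (GMT)
#'
#' @param categories named list of character vectors (category name ->
#'   member gene ids); member sets must be non-empty and names unique.
#' @param source_label free-text provenance label.
#' @return object of class `category_db`.
#' @export
category_db <- function(categories, source_label = "custom") {
  if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stop("all categories must be named")
  }
  if (anyDuplicated(names(categories))) {
    stop("duplicate category name: ",
         names(categories)[duplicated(names(categories))][1])
  }
  if (any(lengths(categories) == 0)) stop("empty category member set")
  categories <- lapply(categories, function(g) sort(unique(toupper(trimws(g)))))
  structure(list(categories = categories, source_label = source_label),
            class = "category_db")
}

#' @export
print.category_db <- function(x, ...) {
  cat(sprintf("<category_db> '%s': %d categories (sizes %d-%d)\n",
              x$source_label, length(x$categories),
              min(lengths(x$categories)), max(lengths(x$categories))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: per line, category name, description, then member gene ids,
#' all tab-delimited. Empty member lists and duplicate names are rejected.
#'
#' @param path path to the GMT file.
#' @param source_label provenance label (defaults to the file name).
#' @return a [category_db()].
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop("GMT lines need name, description and at least one member: ", path)
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate category name in GMT: ", nm[duplicated(nm)][1])
  }
  members <- lapply(parts, function(p) p[-(1:2)])
  names(members) <- nm
  category_db(members, source_label = source_label)
}

#' Write a GMT gene-set file
#'
#' @param x a `category_db`.
#' @param path output path.
#' @param descriptions optional named character vector of descriptions;
#'   defaults to `"na"`.
#' @export
write_gmt <- function(x, path, descriptions = NULL) {
  stopifnot(inherits(x, "category_db"))
  nm <- names(x$categories)
  desc <- if (is.null(descriptions)) rep("na", length(nm)) else descriptions[nm]
  writeLines(vapply(seq_along(nm), function(i) {
    paste(c(nm[i], desc[i], x$categories[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' miRNA family databases
#'
#' @param families named list of character vectors (family name -> member
#'   miRNA ids). Member sets must be non-empty and a miRNA may belong to at
#'   most one family (compared case-insensitively).
#' @param accessions optional named character vector of family accessions.
#' @return object of class `family_db`.
#' @export
family_db <- function(families, accessions = NULL) {
  if (length(families) > 0) {
    if (is.null(names(families)) || any(!nzchar(names(families)))) {
      stop("all families must be named")
    }
    if (anyDuplicated(names(families))) stop("duplicate family name")
    if (any(lengths(families) == 0)) stop("empty family member set")
    families <- lapply(families, function(m) sort(unique(trimws(m))))
    keys <- tolower(unlist(families, use.names = FALSE))
    if (anyDuplicated(keys)) {
      stop("miRNA assigned to more than one family: ",
           keys[duplicated(keys)][1])
    }
  }
  structure(list(families = families, accessions = accessions),
            class = "family_db")
}

#' @export
print.family_db <- function(x, ...) {
  cat(sprintf("<family_db> %d families, %d member miRNAs\n",
              length(x$families), length(unlist(x$families))))
  invisible(x)
}

#' Read a miFam-style miRNA family file
#'
#' The miFam dialect groups records separated by `//` lines. Each record has
#' an `AC` accession line, an `ID` family-name line, and `MI` member lines
#' whose last token is the miRNA id. Members are matched downstream
#' case-insensitively.
#'
#' @param path path to the family file.
#' @return a [family_db()]; empty files give an empty database.
#' @export
read_mifam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(family_db(list()))

  rec_end <- grepl("^//", lines)
  rec_id <- cumsum(c(0, head(rec_end, -1))) + 1L
  fams <- list(); accs <- character(0)
  for (r in split(lines[!rec_end], rec_id[!rec_end])) {
    tag <- sub("^([A-Z]+).*$", "\\1", r)
    idl <- r[tag == "ID"]
    if (length(idl) == 0) stop("miFam record missing ID line in: ", path)
    fam_name <- trimws(sub("^ID\\s+", "", idl[1]))
    acl <- r[tag == "AC"]
    mil <- r[tag == "MI"]
    members <- vapply(strsplit(trimws(mil), "[[:space:]]+"),
                      function(p) p[length(p)], character(1))
    if (length(members) == 0) stop("miFam record '", fam_name,
                                   "' has no MI member lines")
    fams[[fam_name]] <- members
    accs[fam_name] <- if (length(acl) > 0) {
      trimws(sub("^AC\\s+", "", acl[1]))
    } else NA_character_
  }
  family_db(fams, accessions = accs)
}

#' Write a miFam-style miRNA family file
#'
#' @param x a `family_db`.
#' @param path output path.
#' @export
write_mifam <- function(x, path) {
  stopifnot(inherits(x, "family_db"))
  out <- character(0)
  for (fam in names(x$families)) {
    acc <- if (!is.null(x$accessions) && !is.na(x$accessions[fam])) {
      x$accessions[fam]
    } else sprintf("MIPF%07d", match(fam, names(x$families)))
    members <- x$families[[fam]]
    out <- c(out,
             sprintf("AC   %s", acc),
             sprintf("ID   %s", fam),
             sprintf("MI   MI%07d  %s", seq_along(members), members),
             "//")
  }
  writeLines(out, path)
  invisible(path)
}
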