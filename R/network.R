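#' Build the multipartite regulatory graph
#'
#' The graph is r-partite over up to three vertex classes — miRNAs, genes
#' and an optional disease label — with edges only between classes.
#' Admission follows the rule that only the most relevant entities are
#' drawn: miRNA vertices are the deregulated miRNAs having at least one
#' deregulated target, gene vertices are the deregulated targets of those
#' miRNAs, and miRNA-gene edges are the corresponding interaction pairs.
#' When a disease label is given, one disease vertex is connected to every
#' miRNA and gene vertex.
#'
#' Vertex attributes: `node_class` (`"miRNA"`, `"gene"` or `"disease"`),
#' `regulation` (`+1`, `-1`, `0`) and `degree` (number of incident
#' miRNA-gene edges — disease edges do not count). Edge attribute:
#' `edge_class` (`"targets"` or `"disease"`). These attributes encode the
#' drawing conventions of network viewers (shape by class, color by
#' regulation, node size by degree).
#'
#' @inheritParams build_contingency
#' @param disease optional disease label (single string).
#' @return an undirected [igraph::igraph] graph; possibly empty.
#' @export
build_graph <- function(mir_dereg, gene_dereg, interactions, disease = NULL) {
  sets <- derive_gene_sets(mir_dereg, gene_dereg, interactions)
  genes <- sets$dereg_targets_of_dereg_mirs
  p <- interactions$pairs
  keep <- p$mirna_key %in% dereg_keys(mir_dereg) & p$gene_key %in% genes
  edges <- p[keep, c("mirna_key", "gene_key")]
  mirs <- sort(unique(edges$mirna_key))

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(mirs), name = mirs,
                            node_class = "miRNA",
                            regulation = dereg_status(mir_dereg, mirs))
  g <- igraph::add_vertices(g, length(genes), name = genes,
                            node_class = "gene",
                            regulation = dereg_status(gene_dereg, genes))
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$mirna_key, edges$gene_key),
                           edge_class = "targets")
  }
  igraph::V(g)$degree <- igraph::degree(g)
  if (!is.null(disease)) {
    stopifnot(is.character(disease), length(disease) == 1, nzchar(disease))
    deg <- igraph::V(g)$degree
    others <- igraph::V(g)$name
    g <- igraph::add_vertices(g, 1, name = disease, node_class = "disease",
                              regulation = 0L, degree = 0L)
    if (length(others) > 0) {
      g <- igraph::add_edges(g, rbind(others, disease), edge_class = "disease")
      igraph::V(g)$degree <- c(deg, 0L)  # degree counts miRNA-gene edges only
    }
  }
  igraph::graph_attr(g, "disease") <- disease %||% NA_character_
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vertex names of one class
graph_class_vertices <- function(graph, class) {
  igraph::V(graph)$name[igraph::V(graph)$node_class == class]
}

#' Rank miRNAs by their number of deregulated targets
#'
#' @param graph a regulatory graph from [build_graph()].
#' @return data frame with columns `mirna` and `n_dereg_targets`, sorted
#'   descending by count with ties broken lexicographically by id.
#' @export
rank_mirnas_by_dereg_targets <- function(graph) {
  mirs <- graph_class_vertices(graph, "miRNA")
  counts <- vapply(mirs, function(m) {
    nb <- igraph::neighbors(graph, m)
    sum(nb$node_class == "gene")
  }, integer(1))
  o <- order(-counts, mirs)
  data.frame(mirna = mirs[o], n_dereg_targets = unname(counts[o]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Degree-constrained subnetwork selection
#'
#' Given a set of chosen miRNAs and a degree constraint `k`, retains the
#' gene vertices adjacent to at least `k` of the *chosen* miRNAs (degree is
#' counted over the chosen miRNAs only, not over all deregulated miRNAs),
#' then drops chosen miRNAs none of whose targets survive. The induced
#' subgraph is returned with recomputed degrees; the original full-graph
#' degree is preserved as `degree_total`.
#'
#' @param graph a regulatory graph from [build_graph()].
#' @param chosen_mirnas character vector of miRNA ids present in the graph.
#' @param k minimum number of chosen miRNAs that must target a gene
#'   (default 1).
#' @return object of class `subnetwork_selection`: list with
#'   `chosen_mirnas`, `k`, `genes`, `retained_mirnas` and `graph` (the
#'   induced igraph subgraph, disease vertex carried over when present).
#' @export
select_subnetwork <- function(graph, chosen_mirnas, k = 1) {
  stopifnot(k >= 1)
  chosen <- normalize_id(chosen_mirnas, "miRNA")
  mirs <- graph_class_vertices(graph, "miRNA")
  unknown <- setdiff(chosen, mirs)
  if (length(unknown) > 0) {
    stop("unknown miRNA id(s): ", paste(unknown, collapse = ", "))
  }
  genes <- graph_class_vertices(graph, "gene")
  n_chosen_nb <- vapply(genes, function(g) {
    nb <- igraph::neighbors(graph, g)
    sum(nb$name %in% chosen)
  }, integer(1))
  kept_genes <- genes[n_chosen_nb >= k]
  retained <- chosen[vapply(chosen, function(m) {
    any(igraph::neighbors(graph, m)$name %in% kept_genes)
  }, logical(1))]

  keep_names <- c(retained, kept_genes)
  dis <- graph_class_vertices(graph, "disease")
  if (length(dis) > 0 && length(keep_names) > 0) keep_names <- c(keep_names, dis)
  sub <- igraph::induced_subgraph(graph, keep_names)
  if (igraph::vcount(sub) > 0) {
    igraph::V(sub)$degree_total <- igraph::V(sub)$degree
    is_dis <- igraph::V(sub)$node_class == "disease"
    deg <- igraph::degree(sub)
    # exclude disease edges from the displayed degree
    if (any(is_dis)) deg <- deg - as.integer(!is_dis)
    deg[is_dis] <- 0L
    igraph::V(sub)$degree <- deg
  }
  structure(list(chosen_mirnas = sort(chosen), k = as.integer(k),
                 genes = sort(kept_genes), retained_mirnas = sort(retained),
                 graph = sub),
            class = "subnetwork_selection")
}

#' @export
print.subnetwork_selection <- function(x, ...) {
  cat(sprintf(paste0("<subnetwork_selection> k = %d: %d/%d chosen miRNAs ",
                     "retained, %d genes\n"),
              x$k, length(x$retained_mirnas), length(x$chosen_mirnas),
              length(x$genes)))
  invisible(x)
}

#' Gene list of a subnetwork selection
#'
#' The genes retained by the degree constraint, for export and for the
#' focused over-representation analysis.
#'
#' @param selection a [select_subnetwork()] result.
#' @param path optional path; when given, the genes are written one per
#'   line.
#' @return character vector of gene ids (invisibly when writing).
#' @export
subnetwork_gene_list <- function(selection, path = NULL) {
  stopifnot(inherits(selection, "subnetwork_selection"))
  genes <- selection$genes
  if (length(genes) == 0) warning("subnetwork selection contains no genes")
  if (!is.null(path)) {
    writeLines(genes, path)
    return(invisible(genes))
  }
  genes
}

#' Compose a PubMed query for selected entities and a disease
#'
#' Inclusive mode joins the entity terms with OR (publications mentioning
#' any entity), exclusive mode with AND (publications mentioning all of
#' them); the entity clause is then AND-combined with the disease term and
#' URL-encoded. No network request is performed.
#'
#' @param entities character vector of miRNA/gene ids (at least one).
#' @param disease non-empty disease label.
#' @param mode `"inclusive"` or `"exclusive"`.
#' @return list with `term` (the readable query) and `url` (the encoded
#'   PubMed search URL).
#' @export
pubmed_query <- function(entities, disease, mode = c("inclusive", "exclusive")) {
  mode <- match.arg(mode)
  entities <- trimws(entities)
  entities <- entities[nzchar(entities)]
  if (length(entities) == 0) stop("at least one entity is required")
  if (missing(disease) || is.null(disease) || !nzchar(trimws(disease))) {
    stop("a non-empty disease label is required")
  }
  joiner <- if (mode == "inclusive") " OR " else " AND "
  clause <- paste(entities, collapse = joiner)
  if (length(entities) > 1) clause <- paste0("(", clause, ")")
  term <- paste(clause, "AND", trimws(disease))
  list(term = term,
       url = paste0("https://pubmed.ncbi.nlm.nih.gov/?term=",
                    utils::URLencode(term, reserved = TRUE)))
}

#' Export a regulatory graph as GraphML
#'
#' Node attributes `node_class`, `regulation` and `degree` (and
#' `degree_total` when present) are carried into the file so external
#' viewers can reproduce shape, color and size conventions.
#'
#' @param graph an igraph regulatory graph.
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Export a regulatory graph as SIF
#'
#' One `source<TAB>relation<TAB>target` line per edge; miRNA-gene edges use
#' relation `targets` with the miRNA as source, disease edges use relation
#' `disease`. An empty graph gives an empty (but valid) file.
#'
#' @param graph an igraph regulatory graph.
#' @param path output path.
#' @export
write_sif <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::ecount(graph) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ends <- igraph::as_edgelist(graph)
  cls <- igraph::V(graph)$node_class[match(ends[, 1], igraph::V(graph)$name)]
  rel <- igraph::E(graph)$edge_class %||% rep("targets", nrow(ends))
  # orient miRNA-gene edges with the miRNA as source
  flip <- rel == "targets" & cls != "miRNA"
  src <- ifelse(flip, ends[, 2], ends[, 1])
  dst <- ifelse(flip, ends[, 1], ends[, 2])
  writeLines(sprintf("%s\t%s\t%s", src, rel, dst), path)
  invisible(path)
}
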