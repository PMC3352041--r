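#' Configure a full joint analysis
#'
#' Bundles the input paths and parameters of one end-to-end run.
#'
#' @param mirna_dereg_path,gene_dereg_path two-column deregulation lists.
#' @param interactions_path miRNA-target interaction table (2 or 3
#'   columns).
#' @param categories_path GMT gene-set file.
#' @param families_path optional miFam-style family file.
#' @param score_threshold prediction p-value cut-off (strictly-below
#'   filter), default 0.01.
#' @param alpha significance level, default 0.05.
#' @param adjust `"BH"` for Benjamini-Hochberg adjusted p-values in
#'   significance calls, `"raw"` to use unadjusted p-values.
#' @param disease optional disease label (enables the disease vertex and
#'   PubMed queries).
#' @param select_mirnas optional explicit miRNA ids for the subnetwork.
#' @param select_top_n select the top-N miRNAs by deregulated-target
#'   count.
#' @param select_min_targets select miRNAs with strictly more deregulated
#'   targets than this cut-off.
#' @param select_families select the member miRNAs of these families.
#' @param degree_constraint minimum number of selected miRNAs targeting a
#'   retained gene, default 1.
#' @param seed integer seed used for any randomization stage.
#' @param randomize_reps replicates for the empirical randomization
#'   p-value (0 disables the randomization control).
#' @param out_dir output directory for result tables and the report.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(mirna_dereg_path, gene_dereg_path,
                            interactions_path, categories_path,
                            families_path = NULL,
                            score_threshold = 0.01, alpha = 0.05,
                            adjust = c("BH", "raw"), disease = NULL,
                            select_mirnas = NULL, select_top_n = NULL,
                            select_min_targets = NULL,
                            select_families = NULL,
                            degree_constraint = 1, seed = 1,
                            randomize_reps = 0, out_dir = "mirlink_results") {
  adjust <- match.arg(adjust)
  stopifnot(score_threshold > 0, score_threshold <= 1,
            alpha > 0, alpha < 1, degree_constraint >= 1,
            randomize_reps >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "analysis_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ora_table <- function(res) {
  df <- as.data.frame(res)
  df$expected <- round(df$expected, 6)
  df$p_raw <- signif(df$p_raw, 6)
  df$p_adj <- signif(df$p_adj, 6)
  df
}

# resolve the subnetwork miRNA selection from the config
resolve_selection <- function(cfg, ranking, families) {
  if (!is.null(cfg$select_mirnas)) {
    return(normalize_id(cfg$select_mirnas, "miRNA"))
  }
  if (!is.null(cfg$select_families)) {
    if (is.null(families)) stop("family selection requires a family file")
    member <- unlist(families$families[cfg$select_families], use.names = FALSE)
    if (length(member) == 0) stop("unknown family name(s) in selection")
    return(intersect(ranking$mirna, normalize_id(member, "miRNA")))
  }
  if (!is.null(cfg$select_min_targets)) {
    return(ranking$mirna[ranking$n_dereg_targets > cfg$select_min_targets])
  }
  n <- if (!is.null(cfg$select_top_n)) cfg$select_top_n else nrow(ranking)
  utils::head(ranking$mirna, n)
}

#' Run the full joint miRNA/mRNA deregulation analysis
#'
#' Executes the complete workflow on the configured inputs, in order:
#' input summary; contingency table and chi-squared independence test
#' (with its refusal note when applicable, and an optional empirical
#' randomization p-value); Venn overlap of deregulated genes and miRNA
#' targets; the three coordinated over-representation analyses and their
#' overlap-code table; miRNA-family enrichment; the regulatory graph with
#' the miRNA ranking by deregulated targets; the degree-constrained
#' subnetwork (exported as GraphML, SIF and a gene list); a focused ORA on
#' the subnetwork genes; and PubMed query strings when a disease label was
#' given. All tables are written as TSV under `out_dir` together with a
#' Markdown report and a run log; outputs are deterministic for a fixed
#' config and seed.
#'
#' @param config an [analysis_config()].
#' @return the results bundle, invisibly: a list with every intermediate
#'   object and a `files` vector of written paths.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  log_lines <- c("mirlink run log",
                 sprintf("parameter %s = %s", names(unclass(cfg)),
                         vapply(unclass(cfg), function(v) {
                           if (is.null(v)) "NULL" else paste(v, collapse = ",")
                         }, character(1))))
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    write_tsv(df, path)
    files[[name]] <<- path
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## inputs -------------------------------------------------------------
  mir_dereg <- stage("read miRNA deregulation",
                     read_deregulation_file(cfg$mirna_dereg_path, "miRNA"))
  gene_dereg <- stage("read gene deregulation",
                      read_deregulation_file(cfg$gene_dereg_path, "gene"))
  interactions <- stage("read interactions",
                        read_interaction_table(cfg$interactions_path,
                                               cfg$score_threshold))
  categories <- stage("read categories", read_gmt(cfg$categories_path))
  families <- if (!is.null(cfg$families_path)) {
    stage("read families", read_mifam(cfg$families_path))
  } else NULL

  summary_tab <- summarize_inputs(mir_dereg, gene_dereg)
  emit(summary_tab, "input_summary.tsv")

  ## independence --------------------------------------------------------
  contingency <- stage("contingency",
                       build_contingency(mir_dereg, gene_dereg, interactions))
  indep <- chi_squared_independence(contingency, gene_dereg)
  ct <- as.data.frame.matrix(unclass(contingency))
  emit(cbind(mirna_status = rownames(ct), ct), "contingency_table.tsv")
  rand <- NULL
  if (cfg$randomize_reps > 0 && indep$p_allowed) {
    rand <- stage("randomization control",
                  randomization_pvalue(mir_dereg, gene_dereg, interactions,
                                       n_reps = cfg$randomize_reps,
                                       seed = cfg$seed))
  }

  ## gene sets, Venn, ORAs ----------------------------------------------
  sets <- derive_gene_sets(mir_dereg, gene_dereg, interactions)
  venn <- stage("venn overlap",
                venn_overlap(sets$dereg_genes, sets$targets_of_dereg_mirs,
                             sets$universe))
  use_adj <- cfg$adjust == "BH"
  ora_a <- stage("ORA targets of deregulated miRNAs",
                 ora(sets$targets_of_dereg_mirs, sets$universe, categories,
                     cfg$alpha))
  ora_b <- stage("ORA deregulated targets",
                 ora(sets$dereg_targets_of_dereg_mirs, sets$universe,
                     categories, cfg$alpha))
  ora_c <- stage("ORA deregulated genes",
                 ora(sets$dereg_genes, sets$universe, categories, cfg$alpha))
  emit(ora_table(ora_a), "ora_targets_of_dereg_mirs.tsv")
  emit(ora_table(ora_b), "ora_dereg_targets.tsv")
  emit(ora_table(ora_c), "ora_dereg_genes.tsv")
  codes <- overlap_codes(ora_a, ora_b, ora_c, alpha = cfg$alpha,
                         use_adjusted = use_adj)
  emit(as.data.frame(codes), "overlap_codes.tsv")

  fam_res <- NULL
  if (!is.null(families) && length(families$families) > 0) {
    mir_universe <- unique(c(interaction_mirnas(interactions),
                             dereg_keys(mir_dereg)))
    fam_res <- stage("family ORA",
                     family_ora(mir_dereg, families, mir_universe, cfg$alpha))
    emit(ora_table(fam_res), "family_ora.tsv")
  }

  ## network -------------------------------------------------------------
  graph <- stage("build graph",
                 build_graph(mir_dereg, gene_dereg, interactions,
                             disease = cfg$disease))
  ranking <- rank_mirnas_by_dereg_targets(graph)
  emit(ranking, "mirna_ranking.tsv")

  selection <- NULL; focused <- NULL; queries <- NULL
  if (nrow(ranking) > 0) {
    chosen <- stage("resolve selection",
                    resolve_selection(cfg, ranking, families))
    selection <- stage("select subnetwork",
                       select_subnetwork(graph, chosen,
                                         k = cfg$degree_constraint))
    write_graphml(selection$graph, file.path(cfg$out_dir, "subnetwork.graphml"))
    write_sif(selection$graph, file.path(cfg$out_dir, "subnetwork.sif"))
    files[["subnetwork.graphml"]] <- file.path(cfg$out_dir, "subnetwork.graphml")
    files[["subnetwork.sif"]] <- file.path(cfg$out_dir, "subnetwork.sif")
    genes <- suppressWarnings(
      subnetwork_gene_list(selection,
                           file.path(cfg$out_dir, "subnetwork_genes.txt")))
    files[["subnetwork_genes.txt"]] <- file.path(cfg$out_dir,
                                                 "subnetwork_genes.txt")
    if (length(genes) == 0) {
      log_lines <- c(log_lines, "warning: subnetwork selection is empty")
    } else {
      focused <- stage("focused ORA",
                       ora(genes, sets$universe, categories, cfg$alpha))
      emit(ora_table(focused), "focused_ora.tsv")
    }
    if (!is.null(cfg$disease) && length(genes) > 0) {
      ents <- c(selection$retained_mirnas, utils::head(genes, 5))
      queries <- list(
        inclusive = pubmed_query(ents, cfg$disease, "inclusive"),
        exclusive = pubmed_query(ents, cfg$disease, "exclusive"))
      writeLines(c(sprintf("inclusive\t%s", queries$inclusive$url),
                   sprintf("exclusive\t%s", queries$exclusive$url)),
                 file.path(cfg$out_dir, "pubmed_queries.txt"))
      files[["pubmed_queries.txt"]] <- file.path(cfg$out_dir,
                                                 "pubmed_queries.txt")
    }
  }

  ## report --------------------------------------------------------------
  report <- render_report(summary_tab, indep, rand, venn, codes, fam_res,
                          ranking, selection, focused, queries, cfg)
  writeLines(report, file.path(cfg$out_dir, "report.md"))
  files[["report.md"]] <- file.path(cfg$out_dir, "report.md")
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  files[["run_log.txt"]] <- file.path(cfg$out_dir, "run_log.txt")

  invisible(list(config = cfg, summary = summary_tab,
                 contingency = contingency, independence = indep,
                 randomization = rand, gene_sets = sets, venn = venn,
                 ora_a = ora_a, ora_b = ora_b, ora_c = ora_c,
                 overlap_codes = codes, family_ora = fam_res, graph = graph,
                 ranking = ranking, selection = selection,
                 focused_ora = focused, pubmed = queries, files = files))
}

fmt_num <- function(x) format(signif(x, 6), scientific = TRUE)

render_report <- function(summary_tab, indep, rand, venn, codes, fam_res,
                          ranking, selection, focused, queries, cfg) {
  md_table <- function(df) {
    if (nrow(df) == 0) return("(none)")
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                            " |"))
    c(hdr, sep, rows)
  }
  out <- c("# Joint miRNA/mRNA deregulation analysis", "",
           "## Input summary", "", md_table(summary_tab), "",
           "## Independence of deregulation status", "",
           md_table(cbind(mirna_status = rownames(indep$table),
                          as.data.frame.matrix(unclass(indep$table)))), "",
           sprintf("chi-squared = %.4f on %d df", indep$chi2, indep$df))
  out <- c(out, if (indep$p_allowed) {
    sprintf("p-value = %s", fmt_num(indep$p_value))
  } else {
    paste("p-value not computed:", indep$refusal_reason)
  })
  out <- c(out, sprintf("pairs deregulated in the same direction: %d",
                        indep$same_direction_count), "")
  if (!is.null(rand)) {
    out <- c(out, sprintf(
      "empirical randomization p-value = %s (%d replicates)",
      fmt_num(rand$p_empirical), rand$n_reps), "")
  }
  out <- c(out, "## Venn overlap", "",
           sprintf(paste0("targets-only %d | overlap %d | deregulated-only ",
                          "%d (universe %d); hypergeometric p = %s"),
                   venn$left, venn$overlap, venn$right, venn$universe_size,
                   fmt_num(venn$p_value)), "",
           "## Categories significant in at least two analyses", "",
           md_table(as.data.frame(codes)), "")
  if (!is.null(fam_res)) {
    pre <- as.data.frame(fam_res)[fam_res$preselected,
                                  c("category", "test_hits", "ref_hits",
                                    "p_adj")]
    out <- c(out, "## Preselected miRNA families", "", md_table(pre), "")
  }
  out <- c(out, "## miRNAs ranked by deregulated targets", "",
           md_table(utils::head(ranking, 20)), "")
  if (!is.null(selection)) {
    out <- c(out, "## Subnetwork selection", "",
             sprintf("degree constraint k = %d; %d/%d chosen miRNAs retained; %d genes",
                     selection$k, length(selection$retained_mirnas),
                     length(selection$chosen_mirnas),
                     length(selection$genes)), "")
  }
  if (!is.null(focused)) {
    out <- c(out, "## Focused ORA on the subnetwork gene list", "",
             md_table(utils::head(ora_table(focused), 10)), "")
  }
  if (!is.null(queries)) {
    out <- c(out, "## PubMed queries", "",
             sprintf("- inclusive: %s", queries$inclusive$term),
             sprintf("- exclusive: %s", queries$exclusive$term), "")
  }
  out
}
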