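#' Exact hypergeometric tail probabilities
#'
#' Tail probability of the hypergeometric distribution: drawing `draws`
#' items without replacement from a population of size `population` that
#' contains `successes` marked items, `side = "upper"` gives
#' `P(X >= observed)` and `side = "lower"` gives `P(X <= observed)`.
#'
#' The tail is computed by exact summation of the hypergeometric mass in
#' log space (log-binomial terms combined with log-sum-exp), which keeps
#' the sum stable for large populations where individual masses underflow.
#'
#' @param population population size (>= 0).
#' @param successes number of marked items (<= population).
#' @param draws number of items drawn (<= population).
#' @param observed observed number of marked items among the draws.
#' @param side `"upper"` or `"lower"`.
#' @return the tail probability, a number in \[0, 1\].
#' @export
hypergeom_tail <- function(population, successes, draws, observed,
                           side = c("upper", "lower")) {
  side <- match.arg(side)
  if (population < 0 || successes < 0 || draws < 0 ||
      successes > population || draws > population) {
    stop("invalid hypergeometric parameters")
  }
  k_min <- max(0, draws - (population - successes))
  k_max <- min(draws, successes)
  if (observed < k_min || observed > k_max) {
    # outside the support: tails are trivially 0 or 1 at the boundaries
    if (side == "upper") return(if (observed <= k_min) 1 else 0)
    return(if (observed >= k_max) 1 else 0)
  }
  ks <- if (side == "upper") observed:k_max else k_min:observed
  logp <- lchoose(successes, ks) +
    lchoose(population - successes, draws - ks) -
    lchoose(population, draws)
  m <- max(logp)
  min(1, exp(m + log(sum(exp(logp - m)))))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output order matches input
#' order and every adjusted p-value satisfies `p_raw <= p_adj <= 1`.
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return numeric vector of adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a gene set against categories
#'
#' For every category, the member count in the test set is compared with
#' the count expected from the reference set using the hypergeometric
#' distribution. Categories are first restricted to the reference set;
#' categories with no member in the reference are skipped with a message.
#' The reported direction is `enriched` when the observed hit count is at
#' least the expected count and `depleted` otherwise; the raw p-value is
#' the corresponding one-sided tail doubled (capped at 1), and adjusted
#' p-values are Benjamini-Hochberg across all tested categories.
#'
#' @param test_set character vector of entity ids (subset of the reference).
#' @param reference_set character vector: the reference universe.
#' @param categories a [category_db()].
#' @param alpha significance level used by downstream overlap coding
#'   (stored on the result as an attribute).
#' @return data frame of class `ora_result`, one row per tested category,
#'   sorted by adjusted then raw p-value, with columns `category`,
#'   `test_hits`, `test_size`, `ref_hits`, `ref_size`, `expected`,
#'   `direction`, `p_raw`, `p_adj`.
#' @export
ora <- function(test_set, reference_set, categories, alpha = 0.05) {
  stopifnot(inherits(categories, "category_db"))
  reference_set <- unique(toupper(trimws(reference_set)))
  test_set <- unique(toupper(trimws(test_set)))
  if (length(reference_set) == 0) stop("reference set is empty")
  missing <- setdiff(test_set, reference_set)
  if (length(missing) > 0) {
    stop("test set not contained in reference set (e.g. ",
         missing[1], ")")
  }
  N <- length(reference_set)
  n <- length(test_set)

  rows <- lapply(names(categories$categories), function(nm) {
    members <- intersect(categories$categories[[nm]], reference_set)
    K <- length(members)
    if (K == 0) {
      message("skipping category with no member in the reference: ", nm)
      return(NULL)
    }
    k <- length(intersect(members, test_set))
    expected <- n * K / N
    enriched <- k >= expected
    tail <- hypergeom_tail(N, K, n, k,
                           side = if (enriched) "upper" else "lower")
    data.frame(category = nm, test_hits = k, test_size = n, ref_hits = K,
               ref_size = N, expected = expected,
               direction = if (enriched) "enriched" else "depleted",
               p_raw = min(1, 2 * tail), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no category overlaps the reference set")
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p_raw)
  res <- res[order(res$p_adj, res$p_raw, res$category), ]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  class(res) <- c("ora_result", class(res))
  res
}

#' Derive the three coordinated gene sets
#'
#' The joint analysis tests three gene sets against one reference universe:
#' * `A`, `targets_of_dereg_mirs`: all targets of deregulated miRNAs;
#' * `B`, `dereg_targets_of_dereg_mirs`: the deregulated among them
#'   (`B = A` intersected with `C` by construction);
#' * `C`, `dereg_genes`: all uploaded deregulated genes.
#'
#' The reference universe is every gene occurring in the interaction table
#' unioned with the uploaded deregulated genes.
#'
#' @inheritParams build_contingency
#' @return list with character vectors `targets_of_dereg_mirs`,
#'   `dereg_targets_of_dereg_mirs`, `dereg_genes` and `universe`
#'   (normalized gene keys).
#' @export
derive_gene_sets <- function(mir_dereg, gene_dereg, interactions) {
  stopifnot(inherits(interactions, "interaction_table"))
  dereg_mirs <- dereg_keys(mir_dereg)
  p <- interactions$pairs
  A <- sort(unique(p$gene_key[p$mirna_key %in% dereg_mirs]))
  C <- sort(dereg_keys(gene_dereg))
  list(targets_of_dereg_mirs = A,
       dereg_targets_of_dereg_mirs = intersect(A, C),
       dereg_genes = C,
       universe = sort(unique(c(interaction_genes(interactions), C))))
}

#' Venn overlap of deregulated genes and miRNA targets
#'
#' Partitions the relevant genes into three regions: targets of deregulated
#' miRNAs that are not deregulated (`left`), deregulated targets of
#' deregulated miRNAs (`overlap`) and deregulated genes that are not
#' targets (`right`). Significance of the overlap is the upper-tail
#' hypergeometric probability of drawing at least `overlap` targets when
#' `|dereg_genes|` genes are drawn from the universe.
#'
#' @param dereg_genes character vector of deregulated genes.
#' @param targets_of_dereg_mirs character vector of targets of deregulated
#'   miRNAs.
#' @param universe character vector containing both sets.
#' @return object of class `venn_result`: list with `left`, `overlap`,
#'   `right`, `universe_size` and `p_value`.
#' @export
venn_overlap <- function(dereg_genes, targets_of_dereg_mirs, universe) {
  dereg_genes <- unique(toupper(trimws(dereg_genes)))
  targets <- unique(toupper(trimws(targets_of_dereg_mirs)))
  universe <- unique(toupper(trimws(universe)))
  out <- c(setdiff(dereg_genes, universe), setdiff(targets, universe))
  if (length(out) > 0) stop("sets not contained in universe (e.g. ", out[1], ")")
  ov <- length(intersect(dereg_genes, targets))
  structure(list(left = length(targets) - ov,
                 overlap = ov,
                 right = length(dereg_genes) - ov,
                 universe_size = length(universe),
                 p_value = hypergeom_tail(length(universe), length(targets),
                                          length(dereg_genes), ov, "upper")),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf(paste0("Venn overlap: %d targets-only | %d overlap | ",
                     "%d deregulated-only (universe %d)\n"),
              x$left, x$overlap, x$right, x$universe_size))
  cat(sprintf("hypergeometric p (overlap at least as large) = %.4g\n",
              x$p_value))
  invisible(x)
}

#' Overlap coding of three coordinated enrichment analyses
#'
#' A category is "found" in an analysis when its adjusted (or raw, see
#' `use_adjusted`) p-value is below `alpha`. Categories found in at least
#' two of the three analyses are tabulated with the letters of the
#' analyses they were found in (`a` = targets of deregulated miRNAs,
#' `b` = deregulated targets of deregulated miRNAs, `c` = deregulated
#' genes) and a permission-style bitmask over the pairwise overlaps:
#' bit 1 for `a&b`, bit 2 for `b&c`, bit 4 for `a&c`. The achievable codes
#' are 1, 2, 4 and 7 (7 = found in all three analyses).
#'
#' @param results_a,results_b,results_c [ora()] results over the same
#'   category database for analyses A, B and C.
#' @param alpha significance cut-off.
#' @param use_adjusted use `p_adj` (default) or `p_raw` for the cut-off.
#' @return data frame of class `overlap_code_table` with columns
#'   `category`, `membership` (e.g. `"b, c"`) and `code`; zero rows when no
#'   category is shared.
#' @export
overlap_codes <- function(results_a, results_b, results_c, alpha = 0.05,
                          use_adjusted = TRUE) {
  cats <- sort(unique(c(results_a$category, results_b$category,
                        results_c$category)))
  mismatch <- function(r) !setequal(r$category, cats)
  if (mismatch(results_a) || mismatch(results_b) || mismatch(results_c)) {
    stop("the three analyses must cover the same categories")
  }
  sig <- function(r) {
    p <- if (use_adjusted) r$p_adj else r$p_raw
    r$category[p < alpha]
  }
  in_a <- cats %in% sig(results_a)
  in_b <- cats %in% sig(results_b)
  in_c <- cats %in% sig(results_c)
  n_found <- in_a + in_b + in_c
  keep <- n_found >= 2
  code <- 1L * (in_a & in_b) + 2L * (in_b & in_c) + 4L * (in_a & in_c)
  membership <- vapply(seq_along(cats), function(i) {
    paste(c("a", "b", "c")[c(in_a[i], in_b[i], in_c[i])], collapse = ", ")
  }, character(1))
  res <- data.frame(category = cats[keep], membership = membership[keep],
                    code = code[keep], stringsAsFactors = FALSE)
  res <- res[order(-res$code, res$category), ]
  rownames(res) <- NULL
  class(res) <- c("overlap_code_table", class(res))
  res
}

#' miRNA-family over-representation analysis
#'
#' The same hypergeometric statistic as [ora()], with miRNAs in place of
#' genes and families in place of categories. Ids are matched
#' case-insensitively. Families significant after adjustment are flagged
#' `preselected`, mirroring the convention of preselecting significant
#' families for subnetwork construction.
#'
#' @param mir_dereg miRNA [dereg_set()].
#' @param families a [family_db()].
#' @param mir_universe character vector of all miRNA ids forming the
#'   reference (typically the interaction-table miRNAs unioned with the
#'   uploaded ones).
#' @param alpha preselection cut-off on adjusted p-values.
#' @return an [ora()]-style data frame with an extra logical column
#'   `preselected`.
#' @export
family_ora <- function(mir_dereg, families, mir_universe, alpha = 0.05) {
  stopifnot(inherits(families, "family_db"))
  if (length(families$families) == 0) stop("family database is empty")
  universe <- unique(tolower(trimws(mir_universe)))
  test <- dereg_keys(mir_dereg)
  if (length(setdiff(test, universe)) > 0) {
    stop("deregulated miRNAs not contained in the miRNA universe")
  }
  # reuse the gene-set machinery on lower-cased miRNA ids; ora() upper-cases
  # internally, which is a harmless bijection here
  fam_db <- category_db(lapply(families$families, tolower),
                        source_label = "miRNA families")
  res <- ora(test, universe, fam_db, alpha = alpha)
  res$preselected <- res$p_adj < alpha & res$direction == "enriched"
  res
}
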