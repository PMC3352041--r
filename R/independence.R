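#' Tabulate deregulation status over interaction pairs
#'
#' Every (miRNA, gene) interaction pair is classified by the deregulation
#' status of its miRNA (rows) and of its target gene (columns): `up`,
#' `down`, or `not` for entities absent from the respective deregulation
#' set. Each pair contributes to exactly one of the nine cells, so the cell
#' total always equals the number of interaction pairs.
#'
#' @param mir_dereg miRNA [dereg_set()].
#' @param gene_dereg gene [dereg_set()].
#' @param interactions an [interaction_table()].
#' @return a 3x3 integer matrix of class `contingency_table` with dimnames
#'   `mirna` = `up/down/not` and `target` = `up/down/not`.
#' @export
build_contingency <- function(mir_dereg, gene_dereg, interactions) {
  stopifnot(inherits(mir_dereg, "dereg_set"),
            mir_dereg$entity_class == "miRNA",
            inherits(gene_dereg, "dereg_set"),
            gene_dereg$entity_class == "gene",
            inherits(interactions, "interaction_table"))
  lv <- c("up", "down", "not")
  as_status <- function(x) factor(c("not", "up", "down")[match(x, c(0L, 1L, -1L))],
                                  levels = lv)
  ms <- as_status(dereg_status(mir_dereg, interactions$pairs$mirna_key))
  gs <- as_status(dereg_status(gene_dereg, interactions$pairs$gene_key))
  tab <- table(mirna = ms, target = gs)
  m <- matrix(as.integer(tab), nrow = 3,
              dimnames = list(mirna = lv, target = lv))
  structure(m, class = c("contingency_table", class(m)))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Interaction pairs by deregulation status (miRNA x target):\n")
  print(unclass(x))
  invisible(x)
}

#' Chi-squared test of independence of deregulation status
#'
#' Pearson chi-squared statistic over the nine cells of the contingency
#' table, referred to the upper tail of the chi-squared distribution with
#' 4 = (3-1)(3-1) degrees of freedom. Cells whose expected count is zero
#' (possible only when a whole row or column margin is zero) contribute
#' nothing to the statistic.
#'
#' The p-value is refused — reported as `NA` with `p_allowed = FALSE` and a
#' reason — in two situations: when the uploaded gene deregulation set is
#' one-directional (only up or only down), and when any row or column
#' margin is zero, leaving expected counts undefined. The table itself is
#' always returned.
#'
#' @param table a `contingency_table` from [build_contingency()].
#' @param gene_dereg the gene [dereg_set()] used to build the table (needed
#'   for the one-direction refusal rule).
#' @return object of class `independence_result`: list with `table`,
#'   `chi2`, `df` (always 4), `p_value` (`NA` when refused), `p_allowed`,
#'   `refusal_reason` (`NA` when allowed) and `same_direction_count`
#'   (pairs where miRNA and target are deregulated in the same direction).
#' @export
chi_squared_independence <- function(table, gene_dereg) {
  stopifnot(inherits(table, "contingency_table"))
  m <- unclass(table)
  n <- sum(m)
  rs <- rowSums(m); cs <- colSums(m)
  E <- outer(rs, cs) / max(n, 1L)
  nz <- E > 0
  chi2 <- sum((m[nz] - E[nz])^2 / E[nz])

  dirs <- unique(gene_dereg$entries$direction)
  refusal <- NA_character_
  if (length(dirs) < 2) {
    refusal <- "gene deregulation set is one-directional"
  } else if (any(rs == 0) || any(cs == 0)) {
    refusal <- "zero row or column margin: expected counts undefined"
  }
  p_allowed <- is.na(refusal)
  p <- if (p_allowed) stats::pchisq(chi2, df = 4, lower.tail = FALSE) else NA_real_

  structure(list(table = table, chi2 = chi2, df = 4L, p_value = p,
                 p_allowed = p_allowed, refusal_reason = refusal,
                 same_direction_count = m["up", "up"] + m["down", "down"]),
            class = "independence_result")
}

#' @export
print.independence_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-squared = %.4f on %d df\n", x$chi2, x$df))
  if (x$p_allowed) {
    cat(sprintf("p-value = %.4g\n", x$p_value))
  } else {
    cat("p-value not computed:", x$refusal_reason, "\n")
  }
  cat(sprintf("pairs deregulated in the same direction: %d\n",
              x$same_direction_count))
  invisible(x)
}

# run expr with a private, restored RNG stream seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Randomize deregulation labels over the identifier universe
#'
#' The deregulation pattern (how many entities are up- and down-regulated)
#' is kept as-is while the identifiers carrying those labels are resampled
#' uniformly without replacement from the identifier universe: all miRNAs
#' (respectively genes) occurring in the interaction table, unioned with
#' the uploaded identifiers. This is the negative control for the
#' independence test — it preserves the margins but destroys any real
#' miRNA-target coupling.
#'
#' @inheritParams build_contingency
#' @param seed integer seed; the same seed reproduces the same draw.
#' @return list with elements `mir_dereg` and `gene_dereg`, randomized
#'   [dereg_set()]s with the original up/down counts.
#' @export
randomize_deregulation <- function(mir_dereg, gene_dereg, interactions, seed) {
  mir_universe <- sort(unique(c(interaction_mirnas(interactions),
                                dereg_keys(mir_dereg))))
  gene_universe <- sort(unique(c(interaction_genes(interactions),
                                 dereg_keys(gene_dereg))))
  resample <- function(set, universe, class) {
    n <- dereg_size(set)
    if (length(universe) < n) {
      stop("identifier universe (", length(universe),
           ") smaller than deregulation set (", n, ")")
    }
    ids <- sample(universe, n)
    dereg_set(ids, sort(set$entries$direction, decreasing = TRUE)[sample.int(n)],
              class)
  }
  with_seed(seed, {
    list(mir_dereg = resample(mir_dereg, mir_universe, "miRNA"),
         gene_dereg = resample(gene_dereg, gene_universe, "gene"))
  })
}

#' Empirical randomization p-value for the independence test
#'
#' Generalizes the single-shot randomization control to an empirical null:
#' the observed chi-squared statistic is compared against `n_reps`
#' label-randomized replicates, and the p-value is the smoothed exceedance
#' fraction `(1 + #{chi2_rand >= chi2_obs}) / (n_reps + 1)`.
#'
#' @inheritParams randomize_deregulation
#' @param n_reps number of randomized replicates (>= 1).
#' @return list with `p_empirical`, `chi2_observed`, `n_reps`, and the
#'   analytic `observed` [chi_squared_independence()] result. Refusal of
#'   the analytic p-value (one-directional genes, zero margins) propagates:
#'   `p_empirical` is then `NA`.
#' @export
randomization_pvalue <- function(mir_dereg, gene_dereg, interactions,
                                 n_reps = 100, seed = 1) {
  stopifnot(n_reps >= 1)
  obs <- chi_squared_independence(
    build_contingency(mir_dereg, gene_dereg, interactions), gene_dereg)
  if (!obs$p_allowed) {
    return(list(p_empirical = NA_real_, chi2_observed = obs$chi2,
                n_reps = n_reps, observed = obs))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_reps), function(i) {
      r <- randomize_deregulation(mir_dereg, gene_dereg, interactions,
                                  seed = sample.int(.Machine$integer.max, 1))
      tab <- build_contingency(r$mir_dereg, r$gene_dereg, interactions)
      chi_squared_independence(tab, r$gene_dereg)$chi2 >= obs$chi2
    }, logical(1)))
  })
  list(p_empirical = (1 + exceed) / (n_reps + 1),
       chi2_observed = obs$chi2, n_reps = n_reps, observed = obs)
}
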