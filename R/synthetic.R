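#' Specify a synthetic joint-deregulation scenario
#'
#' A scenario describes a complete synthetic study: a miRNA-target
#' interaction universe, deregulation calls for miRNAs and genes with a
#' tunable dependence between them, gene-set categories with an optional
#' planted enriched category, and miRNA families with an optional planted
#' enriched family. Every draw is reproducible from `seed`.
#'
#' Defaults describe a sparse desk-scale study: 150 miRNAs and 2000 genes
#' connected by 3000 predicted interactions (about 20 targets per miRNA),
#' with 30% of each entity class deregulated — dense enough for stable
#' contingency counts, sparse enough that interaction pairs behave like
#' near-independent observations.
#'
#' @param n_mirnas,n_genes,n_interactions scenario dimensions;
#'   `n_interactions` counts all generated rows (scored above and below
#'   the threshold) and must not exceed `n_mirnas * n_genes`.
#' @param frac_dereg_mirnas,frac_dereg_genes fraction of each class that is
#'   deregulated (split evenly between up and down, the extra entity going
#'   to `down`).
#' @param n_up_mirnas,n_down_mirnas,n_up_genes,n_down_genes optional exact
#'   per-direction counts overriding the fractions.
#' @param dependence_strength excess probability, in \[0, 1\], that a gene
#'   targeted by a deregulated miRNA is itself deregulated:
#'   `P(dereg | targeted) = p0 + rho * (1 - p0)` where `p0` is the
#'   baseline deregulation probability. 0 gives the independence null.
#' @param direction_bias probability that a dependently deregulated target
#'   takes the same direction as its deregulated miRNA (0.5 = symmetric).
#' @param score_threshold,frac_above_threshold interaction prediction
#'   p-values are drawn below the threshold for retained rows and in
#'   `[threshold, 1)` for a fraction `frac_above_threshold` of rows, so the
#'   reader's threshold filter has known effect.
#' @param n_categories,category_size,planted_category_odds gene-set
#'   categories; when `planted_category_odds > 1`, the first category
#'   samples deregulated genes with that odds weighting (planted
#'   enrichment relative to the deregulated-gene analysis).
#' @param n_families,family_size,plant_family,planted_family_odds miRNA
#'   families (disjoint memberships); when `plant_family` is `TRUE`, the
#'   first family samples deregulated miRNAs with odds
#'   `planted_family_odds`.
#' @param organism miRNA id prefix.
#' @param seed integer seed.
#' @return validated list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_mirnas = 150, n_genes = 2000,
                          n_interactions = 3000,
                          frac_dereg_mirnas = 0.3, frac_dereg_genes = 0.3,
                          n_up_mirnas = NULL, n_down_mirnas = NULL,
                          n_up_genes = NULL, n_down_genes = NULL,
                          dependence_strength = 0, direction_bias = 0.5,
                          score_threshold = 0.01, frac_above_threshold = 0.2,
                          n_categories = 20, category_size = 40,
                          planted_category_odds = 1,
                          n_families = 10, family_size = 5,
                          plant_family = FALSE, planted_family_odds = 10,
                          organism = "hsa", seed = 1) {
  spec <- as.list(environment())
  stopifnot(n_mirnas >= 1, n_genes >= 1,
            n_interactions >= 1,
            frac_dereg_mirnas >= 0, frac_dereg_mirnas <= 1,
            frac_dereg_genes >= 0, frac_dereg_genes <= 1,
            dependence_strength >= 0, dependence_strength <= 1,
            direction_bias >= 0, direction_bias <= 1,
            score_threshold > 0, score_threshold <= 1,
            frac_above_threshold >= 0, frac_above_threshold < 1,
            n_categories >= 1, category_size >= 1,
            planted_category_odds >= 1,
            n_families >= 0, family_size >= 1, planted_family_odds >= 1)
  if (n_interactions > as.double(n_mirnas) * n_genes) {
    stop("infeasible: n_interactions exceeds n_mirnas * n_genes")
  }
  if (n_families * family_size > n_mirnas) {
    stop("infeasible: families would need more miRNAs than exist")
  }
  class(spec) <- "scenario_spec"
  spec
}

# split a deregulation total into (up, down) honoring explicit overrides
split_directions <- function(n, frac, n_up, n_down) {
  if (!is.null(n_up) || !is.null(n_down)) {
    stopifnot(!is.null(n_up), !is.null(n_down))
    return(c(up = as.integer(n_up), down = as.integer(n_down)))
  }
  total <- round(frac * n)
  c(up = floor(total / 2), down = ceiling(total / 2))
}

#' Simulate a scenario in memory
#'
#' Draws the full synthetic study described by a [scenario_spec()] and
#' returns ready-to-use analysis objects plus the ground truth of every
#' planted quantity.
#'
#' @param spec a [scenario_spec()].
#' @return list of class `scenario` with elements `mir_dereg`,
#'   `gene_dereg` ([dereg_set()]s), `interactions` (threshold-filtered
#'   [interaction_table()]), `raw_interactions` (data frame of all rows
#'   incl. above-threshold scores), `categories` ([category_db()]),
#'   `families` ([family_db()]), `spec` and `truth` (planted category and
#'   family names, per-direction counts, retained interaction count,
#'   realized dependence fraction).
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, simulate_scenario_impl(spec))
}

simulate_scenario_impl <- function(spec) {
  mirna_ids <- sprintf("%s-miR-%04d", spec$organism, seq_len(spec$n_mirnas))
  gene_ids <- sprintf("GENE%05d", seq_len(spec$n_genes))

  # interaction universe: distinct pairs drawn uniformly
  idx <- sample(as.double(spec$n_mirnas) * spec$n_genes, spec$n_interactions)
  pair_m <- ((idx - 1) %% spec$n_mirnas) + 1
  pair_g <- ((idx - 1) %/% spec$n_mirnas) + 1
  n_above <- round(spec$frac_above_threshold * spec$n_interactions)
  above <- seq_len(spec$n_interactions) %in%
    sample.int(spec$n_interactions, n_above)
  score <- numeric(spec$n_interactions)
  score[above] <- stats::runif(n_above, spec$score_threshold, 1)
  score[!above] <- stats::runif(spec$n_interactions - n_above,
                                spec$score_threshold * 1e-4,
                                spec$score_threshold * 0.999)
  raw <- data.frame(mirna = mirna_ids[pair_m], gene = gene_ids[pair_g],
                    score = score, stringsAsFactors = FALSE)

  # miRNA deregulation
  nm <- split_directions(spec$n_mirnas, spec$frac_dereg_mirnas,
                         spec$n_up_mirnas, spec$n_down_mirnas)
  dereg_mir_idx <- sample.int(spec$n_mirnas, sum(nm))
  mir_dir <- rep(c(1L, -1L), nm)[sample.int(sum(nm))]
  mir_dereg <- dereg_set(mirna_ids[dereg_mir_idx], mir_dir, "miRNA")

  # gene deregulation with planted dependence on being targeted (below
  # threshold) by a deregulated miRNA
  retained <- !above
  targeted <- rep(FALSE, spec$n_genes)
  tgt_dir <- rep(0L, spec$n_genes)
  hit <- retained & pair_m %in% dereg_mir_idx
  if (any(hit)) {
    # per gene: targeted flag and the direction of one targeting miRNA
    ord <- sample(which(hit))
    first <- ord[!duplicated(pair_g[ord])]
    targeted[pair_g[first]] <- TRUE
    tgt_dir[pair_g[first]] <- mir_dir[match(pair_m[first], dereg_mir_idx)]
  }

  ng <- split_directions(spec$n_genes, spec$frac_dereg_genes,
                         spec$n_up_genes, spec$n_down_genes)
  exact <- !is.null(spec$n_up_genes)
  p0 <- if (exact) sum(ng) / spec$n_genes else spec$frac_dereg_genes
  rho <- spec$dependence_strength
  p_dep <- p0 + rho * (1 - p0)
  if (exact) {
    # exact totals: weighted sampling of status, directions fill the quota
    w <- ifelse(targeted, p_dep / max(p0, 1e-12), 1)
    dereg_gene_idx <- sample.int(spec$n_genes, sum(ng), prob = w)
    gene_dir <- rep(c(1L, -1L), ng)[sample.int(sum(ng))]
  } else {
    prob <- ifelse(targeted, p_dep, p0)
    is_dereg <- stats::runif(spec$n_genes) < prob
    dereg_gene_idx <- which(is_dereg)
    gene_dir <- integer(length(dereg_gene_idx))
    for (j in seq_along(dereg_gene_idx)) {
      i <- dereg_gene_idx[j]
      gene_dir[j] <- if (targeted[i] && tgt_dir[i] != 0L) {
        if (stats::runif(1) < spec$direction_bias) tgt_dir[i] else -tgt_dir[i]
      } else {
        sample(c(1L, -1L), 1)
      }
    }
  }
  if (length(dereg_gene_idx) == 0) {
    stop("scenario produced no deregulated genes; increase frac_dereg_genes")
  }
  gene_dereg <- dereg_set(gene_ids[dereg_gene_idx], gene_dir, "gene")

  # gene-set categories, first one optionally enriched for deregulated genes
  dereg_gene_names <- gene_ids[dereg_gene_idx]
  cat_w <- ifelse(gene_ids %in% dereg_gene_names,
                  spec$planted_category_odds, 1)
  cats <- list()
  for (i in seq_len(spec$n_categories)) {
    w <- if (i == 1) cat_w else rep(1, spec$n_genes)
    cats[[sprintf("CAT%03d", i)]] <-
      gene_ids[sample.int(spec$n_genes, min(spec$category_size, spec$n_genes),
                          prob = w)]
  }
  categories <- category_db(cats, source_label = "synthetic")

  # miRNA families: disjoint memberships, first one optionally planted
  families <- family_db(list())
  planted_family <- NA_character_
  if (spec$n_families > 0) {
    fams <- list()
    avail <- seq_len(spec$n_mirnas)
    for (i in seq_len(spec$n_families)) {
      w <- if (i == 1 && spec$plant_family) {
        ifelse(avail %in% dereg_mir_idx, spec$planted_family_odds, 1)
      } else rep(1, length(avail))
      pick <- avail[sample.int(length(avail), spec$family_size, prob = w)]
      fams[[sprintf("mir-fam-%02d", i)]] <- mirna_ids[pick]
      avail <- setdiff(avail, pick)
    }
    families <- family_db(fams)
    if (spec$plant_family) planted_family <- names(fams)[1]
  }

  interactions <- interaction_table(raw$mirna[retained], raw$gene[retained],
                                    raw$score[retained])
  structure(list(
    mir_dereg = mir_dereg, gene_dereg = gene_dereg,
    interactions = interactions, raw_interactions = raw,
    categories = categories, families = families, spec = spec,
    truth = list(
      planted_category = if (spec$planted_category_odds > 1) "CAT001"
                         else NA_character_,
      planted_family = planted_family,
      n_up_mirnas = unname(nm["up"]), n_down_mirnas = unname(nm["down"]),
      n_up_genes = sum(gene_dir == 1L), n_down_genes = sum(gene_dir == -1L),
      n_retained_interactions = sum(retained),
      n_above_threshold = n_above,
      frac_targeted_dereg = if (any(targeted)) {
        mean(gene_ids[targeted] %in% dereg_gene_names)
      } else NA_real_)),
    class = "scenario")
}

#' Write a scenario to disk as the five input file dialects
#'
#' Emits the miRNA and gene deregulation lists, the scored interaction
#' table (including the rows above the score threshold, so the reader's
#' filter is exercised), the GMT category file and the miFam family file,
#' plus a JSON manifest recording paths, the spec and the ground truth.
#'
#' @param spec a [scenario_spec()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly: list with `files` (named paths),
#'   `spec` and `truth`.
#' @export
generate_scenario <- function(spec, out_dir) {
  sc <- simulate_scenario(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(mirna_dereg = file.path(out_dir, "mirna_deregulation.tsv"),
             gene_dereg = file.path(out_dir, "gene_deregulation.tsv"),
             interactions = file.path(out_dir, "interactions.tsv"),
             categories = file.path(out_dir, "categories.gmt"),
             families = file.path(out_dir, "families.mifam"),
             manifest = file.path(out_dir, "manifest.json"))
  write_deregulation_file(sc$mir_dereg, files["mirna_dereg"])
  write_deregulation_file(sc$gene_dereg, files["gene_dereg"])
  raw <- sc$raw_interactions
  writeLines(sprintf("%s\t%s\t%.*g", raw$mirna, raw$gene, 15, raw$score),
             files["interactions"])
  write_gmt(sc$categories, files["categories"])
  write_mifam(sc$families, files["families"])
  manifest <- list(files = as.list(files[setdiff(names(files), "manifest")]),
                   spec = unclass(sc$spec), truth = sc$truth)
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(manifest, list(manifest_path = unname(files["manifest"]))))
}

#' Synthetic melanoma-shaped example bundle
#'
#' A fixed-seed scenario whose deregulation summary matches the shape of a
#' published melanoma case study: 2550 up- and 2218 down-regulated genes,
#' 16 up- and 17 down-regulated miRNAs, and about 280,000 interactions
#' retained below the 0.01 prediction threshold (700 miRNAs x 20,000
#' genes). This is a synthetic stand-in generated by [generate_scenario()]
#' — identifiers, interactions and category content are simulated, only
#' the summary shape is matched.
#'
#' @param out_dir output directory.
#' @param seed seed (fixed default so regeneration is byte-identical).
#' @param scale shrink factor in (0, 1] applied to the interaction
#'   universe for quick runs; 1 gives the full-size bundle.
#' @return the manifest, invisibly (see [generate_scenario()]).
#' @export
melanoma_example_bundle <- function(out_dir, seed = 20120L, scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  spec <- scenario_spec(
    n_mirnas = 700, n_genes = round(20000 * scale),
    n_interactions = round(350000 * scale),
    n_up_mirnas = 16, n_down_mirnas = 17,
    n_up_genes = round(2550 * scale), n_down_genes = round(2218 * scale),
    frac_dereg_mirnas = 33 / 700, frac_dereg_genes = 4768 / 20000,
    dependence_strength = 0.15,
    score_threshold = 0.01, frac_above_threshold = 0.2,
    n_categories = 30, category_size = 60, planted_category_odds = 4,
    n_families = 20, family_size = 8, plant_family = TRUE,
    seed = seed)
  generate_scenario(spec, out_dir)
}
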