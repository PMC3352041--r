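# shared fixture builders and independent oracles

# write lines to a self-deleting temp file
tmp_lines <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(.local_envir = env)
  writeLines(lines, path)
  path
}

# a small coherent study: 3 miRNAs x 6 genes
tiny_study <- function() {
  mir <- dereg_set(c("hsa-miR-1", "hsa-miR-2"), c(1, -1), "miRNA")
  gene <- dereg_set(c("G1", "G2", "G5"), c(1, -1, 1), "gene")
  int <- interaction_table(
    mirna = c("hsa-miR-1", "hsa-miR-1", "hsa-miR-2", "hsa-miR-3",
              "hsa-miR-3"),
    gene = c("G1", "G2", "G1", "G3", "G4"))
  list(mir = mir, gene = gene, int = int)
}

# exhaustive hypergeometric oracle: enumerate every draw of `draws` items
# from a population with `successes` marked ones and count marked items
enum_hypergeom_mass <- function(population, successes, draws) {
  if (draws == 0) return(c(`0` = 1))
  subsets <- utils::combn(population, draws)
  marked <- colSums(subsets <= successes)  # items 1..successes are marked
  table(marked) / ncol(subsets)
}

enum_tail <- function(population, successes, draws, observed, side) {
  mass <- enum_hypergeom_mass(population, successes, draws)
  ks <- as.integer(names(mass))
  if (side == "upper") sum(mass[ks >= observed]) else sum(mass[ks <= observed])
}

# independent Pearson chi-squared on a 3x3 matrix of counts
pearson_chi2 <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum(((m - E)^2 / E)[E > 0])
}

# a random scenario for property-style loops; ... overrides the defaults
random_scenario <- function(seed, ...) {
  args <- list(n_mirnas = 40, n_genes = 300, n_interactions = 500,
               n_families = 5, family_size = 4, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_scenario(do.call(scenario_spec, args))
}
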