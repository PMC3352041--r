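test_that("the regulatory graph admits only deregulated, connected entities", {
  # m1 has a deregulated target; m2 is deregulated but all its targets are
  # not; m3 is not deregulated at all
  mir <- dereg_set(c("hsa-miR-1", "hsa-miR-2"), c(1, -1), "miRNA")
  gene <- dereg_set("G1", -1, "gene")
  int <- interaction_table(c("hsa-miR-1", "hsa-miR-2", "hsa-miR-3"),
                           c("G1", "G2", "G1"))
  g <- build_graph(mir, gene, int)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$node_class, c("miRNA", "gene"))
  expect_equal(sort(igraph::V(g)$regulation), c(-1, 1))

  # no deregulated genes: empty graph
  g0 <- build_graph(mir, dereg_set("ZZ", 1, "gene"), int)
  expect_equal(igraph::vcount(g0), 0)

  # optional disease vertex connects to every miRNA and gene vertex
  gd <- build_graph(mir, gene, int, disease = "melanoma")
  expect_equal(igraph::vcount(gd), 3)
  dis <- igraph::V(gd)[igraph::V(gd)$node_class == "disease"]
  expect_equal(length(igraph::neighbors(gd, dis)), 2)
  expect_equal(dis$regulation, 0)
  # disease edges do not count towards the displayed degree
  expect_equal(sort(igraph::V(gd)$degree), c(0, 1, 1))
})

test_that("graphs are r-partite on random fixtures", {
  for (seed in 41:44) {
    sc <- random_scenario(seed)
    g <- build_graph(sc$mir_dereg, sc$gene_dereg, sc$interactions,
                     disease = if (seed %% 2) "disease-x" else NULL)
    cls <- igraph::V(g)$node_class
    ends <- igraph::as_edgelist(g)
    c1 <- cls[match(ends[, 1], igraph::V(g)$name)]
    c2 <- cls[match(ends[, 2], igraph::V(g)$name)]
    expect_true(all(c1 != c2))
    # every gene vertex is deregulated and targeted by a deregulated miRNA
    genes <- igraph::V(g)[cls == "gene"]
    expect_true(all(genes$regulation %in% c(-1, 1)))
    expect_true(all(genes$name %in%
                      derive_gene_sets(sc$mir_dereg, sc$gene_dereg,
                                       sc$interactions)$dereg_targets_of_dereg_mirs))
  }
})

# star fixture: gene Gk is targeted by the first k of 8 chosen miRNAs
star_graph <- function() {
  mirs <- sprintf("hsa-miR-%d", 1:8)
  pairs <- do.call(rbind, lapply(1:8, function(k) {
    data.frame(m = mirs[1:k], g = sprintf("G%d", k))
  }))
  mir <- dereg_set(mirs, rep(c(1, -1), 4), "miRNA")
  gene <- dereg_set(sprintf("G%d", 1:8), rep(c(1, -1), 4), "gene")
  build_graph(mir, gene, interaction_table(pairs$m, pairs$g))
}

test_that("degree-constrained selection keeps genes hit by >= k chosen miRNAs", {
  g <- star_graph()
  chosen <- sprintf("hsa-miR-%d", 1:8)

  s3 <- select_subnetwork(g, chosen, k = 3)
  expect_setequal(s3$genes, sprintf("G%d", 3:8))
  s4 <- select_subnetwork(g, chosen, k = 4)
  expect_false("G3" %in% s4$genes)       # threshold boundary

  # k = 1: union of the chosen miRNAs' deregulated targets
  s1 <- select_subnetwork(g, chosen[1:2], k = 1)
  expect_setequal(s1$genes, sprintf("G%d", 1:8))

  # a chosen miRNA with no surviving target is dropped from the drawing
  s8 <- select_subnetwork(g, chosen, k = 8)
  expect_equal(s8$genes, "G8")
  expect_setequal(s8$retained_mirnas, tolower(chosen))
  sx <- select_subnetwork(g, chosen[c(1, 8)], k = 2)
  expect_equal(sx$genes, "G8")           # only G8 sees both chosen miRNAs
  expect_setequal(sx$retained_mirnas, tolower(chosen[c(1, 8)]))
  # a chosen miRNA none of whose targets survive is dropped entirely
  mir <- dereg_set(c("hsa-miR-x", "hsa-miR-y", "hsa-miR-z"), c(1, 1, -1),
                   "miRNA")
  gene <- dereg_set(c("GA", "GB", "GC"), c(1, -1, 1), "gene")
  gd <- build_graph(mir, gene, interaction_table(
    c("hsa-miR-x", "hsa-miR-y", "hsa-miR-y", "hsa-miR-z", "hsa-miR-z"),
    c("GA", "GB", "GC", "GB", "GC")))
  sd <- select_subnetwork(gd, c("hsa-miR-x", "hsa-miR-y", "hsa-miR-z"),
                          k = 2)
  expect_setequal(sd$genes, c("GB", "GC"))
  expect_setequal(sd$retained_mirnas, c("hsa-mir-y", "hsa-mir-z"))
  expect_false("hsa-mir-x" %in% igraph::V(sd$graph)$name)

  expect_error(select_subnetwork(g, "hsa-miR-99"), "unknown miRNA")

  # degree is counted over chosen miRNAs only, then recomputed on the
  # induced subgraph
  expect_equal(sort(unique(igraph::V(s3$graph)$node_class)),
               c("gene", "miRNA"))
  v <- igraph::V(s3$graph)
  expect_equal(v$degree[v$name == "G3"], 3)
})

test_that("degree-constraint selection is monotone in k", {
  for (seed in 51:53) {
    sc <- random_scenario(seed, n_interactions = 900)
    g <- build_graph(sc$mir_dereg, sc$gene_dereg, sc$interactions)
    mirs <- rank_mirnas_by_dereg_targets(g)$mirna
    if (length(mirs) < 3) next
    chosen <- utils::head(mirs, 6)
    prev_genes <- NULL; prev_mirs <- NULL
    for (k in 1:4) {
      s <- select_subnetwork(g, chosen, k = k)
      if (!is.null(prev_genes)) {
        expect_true(all(s$genes %in% prev_genes))
        expect_true(all(s$retained_mirnas %in% prev_mirs))
      }
      prev_genes <- s$genes; prev_mirs <- s$retained_mirnas
    }
  }
})

test_that("miRNA ranking counts deregulated targets deterministically", {
  mir <- dereg_set(c("hsa-miR-b", "hsa-miR-a", "hsa-miR-c"),
                   c(1, -1, 1), "miRNA")
  gene <- dereg_set(sprintf("G%d", 1:4), rep(1, 4), "gene")
  int <- interaction_table(
    c("hsa-miR-b", "hsa-miR-b", "hsa-miR-b", "hsa-miR-a",
      "hsa-miR-c", "hsa-miR-c"),
    c("G1", "G2", "G3", "G1", "G2", "G4"))
  rk <- rank_mirnas_by_dereg_targets(build_graph(mir, gene, int))
  expect_equal(rk$mirna, c("hsa-mir-b", "hsa-mir-c", "hsa-mir-a"))
  expect_equal(rk$n_dereg_targets, c(3, 2, 1))

  # tie on counts: lexicographic order
  int2 <- interaction_table(c("hsa-miR-b", "hsa-miR-a"), c("G1", "G2"))
  rk2 <- rank_mirnas_by_dereg_targets(build_graph(mir, gene, int2))
  expect_equal(rk2$mirna, c("hsa-mir-a", "hsa-mir-b"))

  # counts equal brute-force recount from the pair list
  sc <- random_scenario(61)
  g <- build_graph(sc$mir_dereg, sc$gene_dereg, sc$interactions)
  rk3 <- rank_mirnas_by_dereg_targets(g)
  p <- sc$interactions$pairs
  dg <- derive_gene_sets(sc$mir_dereg, sc$gene_dereg,
                         sc$interactions)$dereg_targets_of_dereg_mirs
  for (i in seq_len(min(5, nrow(rk3)))) {
    m <- rk3$mirna[i]
    expect_equal(rk3$n_dereg_targets[i],
                 length(unique(p$gene_key[p$mirna_key == m &
                                            p$gene_key %in% dg])))
  }
})

test_that("subnetwork gene lists export and stay union-consistent", {
  g <- star_graph()
  s <- select_subnetwork(g, sprintf("hsa-miR-%d", 1:8), k = 5)
  path <- withr::local_tempfile()
  subnetwork_gene_list(s, path)
  expect_equal(readLines(path), s$genes)

  # equals the union over retained miRNAs' retained targets
  ends <- igraph::as_edgelist(s$graph)
  expect_setequal(s$genes,
                  unique(c(ends[ends[, 1] %in% s$retained_mirnas, 2],
                           ends[ends[, 2] %in% s$retained_mirnas, 1])))

  s0 <- select_subnetwork(g, "hsa-miR-1", k = 7)
  expect_warning(gl <- subnetwork_gene_list(s0), "no genes")
  expect_length(gl, 0)
})

test_that("PubMed queries join entities per mode and URL-encode cleanly", {
  q <- pubmed_query(c("PTCH1", "RASA1"), "melanoma", "exclusive")
  expect_equal(q$term, "(PTCH1 AND RASA1) AND melanoma")
  expect_match(q$url, "pubmed", fixed = TRUE)
  expect_equal(utils::URLdecode(sub(".*term=", "", q$url)), q$term)

  qi <- pubmed_query(c("PTCH1", "RASA1"), "melanoma", "inclusive")
  expect_equal(qi$term, "(PTCH1 OR RASA1) AND melanoma")

  # single entity: both modes coincide
  expect_equal(pubmed_query("TP53", "glioma", "inclusive")$term,
               pubmed_query("TP53", "glioma", "exclusive")$term)

  expect_error(pubmed_query(character(0), "melanoma"), "entity")
  expect_error(pubmed_query("TP53", ""), "disease")
})
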