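test_that("hypergeometric tails agree with exhaustive enumeration", {
  # spot grid in the unit suite; the full population <= 12 sweep runs in
  # the acceptance suite
  for (pop in c(5, 8, 10)) {
    for (succ in c(0, 2, pop %/% 2, pop)) {
      for (draws in c(1, pop %/% 2, pop)) {
        for (obs in 0:min(draws, succ)) {
          for (side in c("upper", "lower")) {
            expect_equal(hypergeom_tail(pop, succ, draws, obs, side),
                         enum_tail(pop, succ, draws, obs, side),
                         tolerance = 1e-12,
                         label = sprintf("pop=%d succ=%d draws=%d obs=%d %s",
                                         pop, succ, draws, obs, side))
          }
        }
      }
    }
  }
  expect_equal(hypergeom_tail(10, 4, 5, 4, "upper"), 6 / 252)
  expect_equal(hypergeom_tail(10, 0, 5, 0, "lower"), 1)
  expect_equal(hypergeom_tail(10, 4, 5, 0, "upper"), 1)
  expect_error(hypergeom_tail(5, 6, 2, 1, "upper"), "invalid")
})

test_that("upper and lower tails partition the mass", {
  for (pop in c(6, 11, 40)) {
    for (succ in c(1, pop %/% 3)) {
      for (draws in c(2, pop %/% 2)) {
        for (obs in 1:min(draws, succ)) {
          expect_equal(hypergeom_tail(pop, succ, draws, obs, "upper") +
                         hypergeom_tail(pop, succ, draws, obs - 1, "lower"),
                       1, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeometric tails stay stable for large populations", {
  # log-space summation must not underflow where single masses do
  p <- hypergeom_tail(20000, 400, 5000, 250, "upper")
  expect_equal(p, stats::phyper(249, 400, 19600, 5000, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_gt(p, 0)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  # permutation invariance and dominance
  set.seed(9)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
})

test_that("ORA matches the enumeration oracle and validates its inputs", {
  ref <- sprintf("G%02d", 1:10)
  db <- category_db(list(CAT = ref[1:4]))
  res <- ora(ref[c(1:4, 8)], ref, db)
  expect_equal(res$test_hits, 4)
  expect_equal(res$expected, 5 * 4 / 10)
  expect_equal(res$direction, "enriched")
  expect_equal(res$p_raw, 2 * 6 / 252)
  expect_equal(res$p_adj, res$p_raw)

  # degenerate: test set equals the reference
  rfull <- ora(ref, ref, db)
  expect_equal(rfull$test_hits, rfull$ref_hits)
  expect_equal(rfull$p_raw, 1)

  expect_error(ora(c(ref[1], "NOT_THERE"), ref, db), "not contained")
  db2 <- category_db(list(CAT = ref[1:4], GONE = c("X1", "X2")))
  expect_message(ora(ref[1:5], ref, db2), "no member in the reference")
})

test_that("a planted enriched category ranks first by adjusted p", {
  hits <- 0L
  for (seed in 1:10) {
    sc <- random_scenario(seed, planted_category_odds = 10,
                          n_categories = 10, category_size = 30)
    sets <- derive_gene_sets(sc$mir_dereg, sc$gene_dereg, sc$interactions)
    res <- ora(sets$dereg_genes, sets$universe, sc$categories)
    hits <- hits + (res$category[1] == sc$truth$planted_category)
  }
  expect_gte(hits, 9)
})

test_that("the three coordinated gene sets obey their set identities", {
  mir <- dereg_set("hsa-miR-1", 1, "miRNA")
  gene <- dereg_set(c("G1", "G3"), c(1, -1), "gene")
  int <- interaction_table(c("hsa-miR-1", "hsa-miR-1", "hsa-miR-2"),
                           c("G1", "G2", "G4"))
  s <- derive_gene_sets(mir, gene, int)
  expect_setequal(s$targets_of_dereg_mirs, c("G1", "G2"))
  expect_setequal(s$dereg_genes, c("G1", "G3"))
  expect_equal(s$dereg_targets_of_dereg_mirs, "G1")
  expect_setequal(s$universe, c("G1", "G2", "G3", "G4"))

  none <- derive_gene_sets(dereg_set("hsa-miR-9", 1, "miRNA"), gene, int)
  expect_length(none$targets_of_dereg_mirs, 0)
  expect_length(none$dereg_targets_of_dereg_mirs, 0)

  for (seed in 11:14) {
    sc <- random_scenario(seed)
    s <- derive_gene_sets(sc$mir_dereg, sc$gene_dereg, sc$interactions)
    expect_true(all(s$dereg_targets_of_dereg_mirs %in%
                      s$targets_of_dereg_mirs))
    expect_true(all(s$dereg_targets_of_dereg_mirs %in% s$dereg_genes))
    expect_true(all(s$targets_of_dereg_mirs %in% s$universe))
    expect_true(all(s$dereg_genes %in% s$universe))
  }
})

test_that("Venn regions partition the sets and score the overlap", {
  u <- sprintf("g%d", 1:6)
  v <- venn_overlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"), u)
  expect_equal(c(v$left, v$overlap, v$right), c(1, 2, 1))
  expect_equal(v$p_value, 0.5)

  vd <- venn_overlap(c("g1", "g2"), c("g3", "g4"), u)
  expect_equal(vd$overlap, 0)
  expect_equal(vd$p_value, 1)

  vi <- venn_overlap(u, u, u)
  expect_equal(c(vi$left, vi$right), c(0, 0))
  expect_equal(vi$p_value, 1)

  expect_error(venn_overlap(c("g1", "zz"), "g2", u), "universe")

  # partition identities on random fixtures
  for (seed in 21:24) {
    sc <- random_scenario(seed)
    s <- derive_gene_sets(sc$mir_dereg, sc$gene_dereg, sc$interactions)
    v <- venn_overlap(s$dereg_genes, s$targets_of_dereg_mirs, s$universe)
    expect_equal(v$left + v$overlap, length(s$targets_of_dereg_mirs))
    expect_equal(v$overlap + v$right, length(s$dereg_genes))
  }
})

# build an ora_result-shaped frame with chosen significant categories
fake_ora <- function(cats, sig) {
  data.frame(category = cats,
             p_raw = ifelse(cats %in% sig, 1e-6, 0.9),
             p_adj = ifelse(cats %in% sig, 1e-5, 0.95),
             stringsAsFactors = FALSE)
}

test_that("overlap codes implement the pairwise bitmask", {
  cats <- sprintf("P%d", 1:6)
  res <- overlap_codes(fake_ora(cats, c("P2", "P6")),       # A
                       fake_ora(cats, c("P1", "P2", "P3")), # B
                       fake_ora(cats, c("P1", "P2", "P4"))) # C
  expect_equal(res$code[res$category == "P1"], 2)   # b, c
  expect_equal(res$membership[res$category == "P1"], "b, c")
  expect_equal(res$code[res$category == "P2"], 7)   # a, b, c
  expect_false("P6" %in% res$category)              # significant in A only
  expect_false("P5" %in% res$category)              # nowhere significant
  expect_true(all(res$code %in% c(1, 2, 4, 7)))

  ab <- overlap_codes(fake_ora(cats, "P1"), fake_ora(cats, "P1"),
                      fake_ora(cats, character(0)))
  expect_equal(ab$code, 1)
  ac <- overlap_codes(fake_ora(cats, "P1"), fake_ora(cats, character(0)),
                      fake_ora(cats, "P1"))
  expect_equal(ac$code, 4)

  expect_error(overlap_codes(fake_ora(cats[1:3], "P1"), fake_ora(cats, "P1"),
                             fake_ora(cats, "P1")), "same categories")
})

test_that("miRNA family enrichment mirrors the gene-set statistic", {
  universe <- sprintf("hsa-miR-%d", 1:20)
  fams <- family_db(list(hit = universe[1:4], miss = universe[11:14],
                         part = universe[c(5, 6, 15, 16)]))
  dereg <- dereg_set(universe[1:6], rep(c(1, -1), 3), "miRNA")
  res <- family_ora(dereg, fams, universe)
  expect_equal(res$category[1], "hit")   # wholly contained family wins
  expect_true(res$preselected[1])
  expect_equal(res$direction[res$category == "miss"], "depleted")
  expect_error(family_ora(dereg, fams, universe[1:3]), "universe")

  # planted family recovery on synthetic scenarios
  found <- 0L
  for (seed in 31:36) {
    sc <- random_scenario(seed, plant_family = TRUE,
                          planted_family_odds = 10, n_families = 5,
                          family_size = 6)
    mu <- unique(c(interaction_mirnas(sc$interactions),
                   dereg_keys(sc$mir_dereg)))
    fr <- family_ora(sc$mir_dereg, sc$families, mu)
    found <- found + (tolower(fr$category[1]) ==
                        tolower(sc$truth$planted_family))
  }
  expect_gte(found, 5)
})
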