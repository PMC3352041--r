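# deterministic construction of three coordinated gene sets over a
# 1000-gene universe in which one category is enriched only in analyses B
# (deregulated targets of deregulated miRNAs) and C (deregulated genes),
# and another in all three analyses, exercising the overlap-coding scheme
# end to end through real ora() runs
overlap_code_study <- function(seed = 1) {
  set.seed(seed)
  u <- sprintf("G%04d", 1:1000)
  cat_bc <- u[1:40]
  cat_abc <- u[41:80]
  nulls <- lapply(1:8, function(i) sample(u[101:1000], 40))
  db <- category_db(c(list(CAT_BC = cat_bc, CAT_ABC = cat_abc),
                      setNames(nulls, sprintf("NULL%02d", 1:8))))

  filler_a <- sample(u[101:1000], 346)
  set_a <- c(u[1:18], u[41:76], filler_a)              # 400 genes
  c_in_a <- c(u[1:16], u[41:60], sample(filler_a, 24)) # 60 genes, all in A
  c_out <- sample(setdiff(u[101:1000], set_a), 60)
  set_c <- c(c_in_a, c_out)                            # 120 genes
  set_b <- intersect(set_a, set_c)                     # 60 genes

  list(universe = u, categories = db,
       a = set_a, b = set_b, c = set_c)
}
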