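pub_exercise <- published_response_table("exercise")
pub_training <- published_response_table("training_mti")

test_that("significance sets honour threshold and direction", {
  aa <- published_meta_table(pub_exercise, "ACUTE_AEROBIC")
  up <- significant_set(aa, 0.01, "UP")
  expect_true("NR4A3" %in% up)          # logFC 2.99, FDR 2.0e-07
  tr <- published_meta_table(pub_exercise, "TRAINING_RESISTANCE")
  expect_false("NR4A3" %in% significant_set(tr, 0.01))  # FDR 8.7e-01
  expect_equal(
    significant_set(aa[0, ], 0.01),
    character(0)
  )
  # monotone in the threshold
  for (th in list(c(0.001, 0.01), c(0.01, 0.05), c(0.05, 0.5))) {
    expect_true(all(significant_set(aa, th[1]) %in%
                      significant_set(aa, th[2])))
  }
  # direction partitions the unsigned set
  expect_setequal(
    c(significant_set(aa, 0.05, "UP"), significant_set(aa, 0.05, "DOWN")),
    significant_set(aa, 0.05, "ANY")
  )
})

test_that("Venn regions are exhaustive and sum to the union", {
  v <- venn_counts(list(X = c("A", "B"), Y = c("B", "C")))
  expect_equal(v[["X"]], 1L)
  expect_equal(v[["Y"]], 1L)
  expect_equal(v[["X&Y"]], 1L)

  disj <- venn_counts(list(X = c("A"), Y = c("B"), Z = c("C")))
  expect_equal(disj[["X&Y&Z"]], 0L)
  expect_equal(sum(disj), 3L)

  # brute-force check against membership enumeration on random sets
  set.seed(91)
  pool <- sprintf("g%d", 1:12)
  for (rep in 1:10) {
    sets <- lapply(1:3, function(i) sample(pool, sample(3:8, 1)))
    names(sets) <- c("P", "Q", "R")
    v <- venn_counts(sets)
    expect_equal(sum(v), length(unique(unlist(sets))))
    # triple region by direct enumeration
    expect_equal(v[["P&Q&R"]],
                 sum(pool %in% sets$P & pool %in% sets$Q & pool %in% sets$R))
    # each single-set region
    expect_equal(v[["P"]],
                 sum(pool %in% sets$P & !pool %in% sets$Q & !pool %in% sets$R))
  }
  expect_error(venn_counts(lapply(1:6, function(i) "a")), NULL)
})

test_that("top responders reproduce the printed acute-aerobic ranking", {
  aa <- published_meta_table(pub_exercise, "ACUTE_AEROBIC")
  top <- top_n_genes(aa, 5)
  expect_equal(top$up, c("NR4A3", "EGR1", "FOS", "MAFF", "CYR61"))
  # n beyond the table size returns the full ordered list
  all_up <- top_n_genes(aa, 1000)$up
  expect_equal(length(all_up), nrow(aa))
  expect_equal(head(all_up, 5), top$up)
  # ties on mu break by smaller FDR, then gene id
  tied <- data.frame(gene = c("B", "A", "C"), mu = c(1, 1, 1),
                     fdr = c(0.2, 0.01, 0.2), status = "OK")
  expect_equal(top_n_genes(tied, 3)$up, c("A", "B", "C"))
})

test_that("healthy-specific rule flags printed genes", {
  hly <- published_meta_table(pub_training, "aerobic_hly")
  mti <- published_meta_table(pub_training, "aerobic_mti")
  expect_equal(healthy_specific(hly, mti, 0.01, 0.9),
               sort(c("GUCY1B1", "KANSL3", "ARNT", "TOP2B", "IGIP")))
  # PTGDS fails the healthy bound for aerobic (FDR 8.2e-01)
  expect_false("PTGDS" %in% healthy_specific(hly, mti, 0.01, 0.9))
  empty <- data.frame(gene = character(), fdr = numeric())
  expect_equal(healthy_specific(empty, empty), character(0))
})

test_that("concordance overlap intersects all up and down sets", {
  got <- concordance_overlap(
    up_sets = list(c("NR4A3", "EGR1"), c("NR4A3", "MAFF")),
    down_sets = list("NR4A3")
  )
  expect_equal(got, "NR4A3")
  expect_equal(concordance_overlap(list(character(0)), list("X")),
               character(0))
  s <- c("a", "b")
  expect_equal(concordance_overlap(list(s, s), list(s)), s)
})

test_that("hypergeometric enrichment matches closed form and handles edge sets", {
  universe <- sprintf("u%d", 1:10)
  inset <- universe[1:5]
  res <- ora_hypergeometric(inset, universe, list(S = inset))
  expect_equal(res$p, 1 / choose(10, 5))
  expect_equal(res$overlap, 5L)

  # query disjoint from the set: no evidence of enrichment
  res2 <- ora_hypergeometric(universe[6:10], universe, list(S = inset))
  expect_gt(res2$p, 0.5)

  # set equal to the universe: overlap is certain
  res3 <- ora_hypergeometric(inset, universe, list(S = universe))
  expect_equal(res3$p, 1)

  expect_error(ora_hypergeometric(c("zz"), universe, list(S = inset)),
               "outside the universe")
  # sets with no universe overlap are dropped
  res4 <- ora_hypergeometric(inset, universe,
                             list(S = inset, GONE = c("x1", "x2")))
  expect_equal(res4$set_name, "S")
})

test_that("complex projection averages pooled member effects", {
  res <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    mu = c(0.2, 0.4, 0.1, -0.1),
                    fdr = 0.5,
                    status = c("OK", "OK", "TOO_FEW_STUDIES", "OK"))
  cmap <- list(C1 = c("g1", "g2"),       # plain mean: 0.3
               C2 = c("g2", "g3"),       # one member unmeasured: 0.4
               C3 = c("g2", "gX"),       # unknown member ignored
               C4 = c("gX", "gY"))       # nothing measured: NA
  pm <- complex_projection(list(AA = res), cmap)
  expect_equal(pm["C1", "AA"], 0.3)
  expect_equal(pm["C2", "AA"], 0.4)
  expect_equal(pm["C3", "AA"], 0.4)
  expect_true(is.na(pm["C4", "AA"]))
  # cancellation
  pm2 <- complex_projection(
    list(AA = data.frame(gene = c("a", "b"), mu = c(0.1, -0.1),
                         fdr = 0.5, status = "OK")),
    list(C = c("a", "b"))
  )
  expect_equal(pm2["C", "AA"], 0)
})
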