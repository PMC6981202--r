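test_that("expression tables parse with pairing metadata", {
  path <- write_tsv_fixture(c(
    "gene\tA:PRE\tA:POST\tB:PRE\tB:POST",
    "g1\t1\t2\t3\t4",
    "g2\t2\t2\t2\t2",
    "g3\t0\t1\t0\t1"
  ))
  st <- read_expression_table(path, layout = list(design = "PAIRED"))
  expect_s3_class(st, "expression_study")
  expect_equal(st$design, "PAIRED")
  expect_equal(nrow(st$values), 3L)
  expect_equal(sort(unique(st$samples$subject_id)), c("A", "B"))

  # subject present only in PRE violates the paired invariant ...
  bad <- write_tsv_fixture(c(
    "gene\tA:PRE\tA:POST\tB:PRE",
    "g1\t1\t2\t3"
  ))
  expect_error(read_expression_table(bad, layout = list(design = "PAIRED")),
               "PAIRED")
  # ... but the same file is accepted when declared unpaired
  st2 <- read_expression_table(bad, layout = list(design = "UNPAIRED"))
  expect_equal(st2$design, "UNPAIRED")
})

test_that("malformed expression tables name the offending line", {
  ragged <- write_tsv_fixture(c(
    "gene\tA:PRE\tA:POST",
    "g1\t1\t2",
    "g2\t1"
  ))
  expect_error(read_expression_table(ragged), "line 3")

  alpha <- write_tsv_fixture(c(
    "gene\tA:PRE\tA:POST",
    "g1\t1\tx"
  ))
  expect_error(read_expression_table(alpha), "non-numeric")

  badhdr <- write_tsv_fixture(c(
    "gene\tA_PRE\tA_POST",
    "g1\t1\t2"
  ))
  expect_error(read_expression_table(badhdr), "malformed header")
})

test_that("quantile normalization equalizes column distributions", {
  st <- make_paired_study(cbind(c(1, 2, 3)), cbind(c(4, 5, 6)))
  qn <- quantile_normalize(st)
  expect_equal(sort(qn$values[, 1]), c(2.5, 3.5, 4.5),
               ignore_attr = TRUE)
  expect_equal(sort(qn$values[, 2]), c(2.5, 3.5, 4.5),
               ignore_attr = TRUE)

  # already-identical columns are a fixed point; single column untouched
  same <- make_paired_study(cbind(c(1, 5, 9)), cbind(c(1, 5, 9)))
  expect_equal(quantile_normalize(same)$values, same$values)

  na_st <- make_paired_study(cbind(c(1, NA, 3)), cbind(c(4, 5, 6)))
  expect_error(quantile_normalize(na_st), "missing")
})

test_that("quantile normalization matches the sorted-row-means oracle and preserves ranks", {
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(rnorm(60), 10, 6,
                dimnames = list(sprintf("g%d", 1:10), NULL))
    subj <- sprintf("P%d", 1:3)
    st <- expression_study(
      "q", `colnames<-`(x, c(paste0(subj, ":PRE"), paste0(subj, ":POST"))),
      data.frame(subject_id = rep(subj, 2),
                 condition = rep(c("PRE", "POST"), each = 3)),
      "PAIRED"
    )
    qn <- quantile_normalize(st)$values
    # all columns share the same sorted values, exactly
    ref <- sort(qn[, 1])
    for (j in 2:6) expect_equal(sort(qn[, j]), ref, ignore_attr = TRUE)
    # continuous input: matches the no-ties oracle, ranks preserved
    expect_equal(qn, qn_oracle(st$values))
    for (j in 1:6) expect_equal(rank(qn[, j]), rank(st$values[, j]))
  }
})

test_that("median-of-ratios size factors follow the stated rule", {
  cnt <- matrix(c(1, 2, 4, 2, 4, 8), 3, 2,
                dimnames = list(c("g1", "g2", "g3"),
                                c("P1:PRE", "P1:POST")))
  st <- median_ratio_log_normalize(cnt, pseudocount = 0.5)
  sf <- attr(st$values, "size_factors")
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  # identical columns: all size factors 1
  cnt2 <- matrix(c(3, 5, 9, 3, 5, 9), 3, 2,
                 dimnames = dimnames(cnt))
  expect_equal(unname(attr(median_ratio_log_normalize(cnt2)$values,
                           "size_factors")), c(1, 1))

  # a zero count with pseudocount 1 and unit size factor maps to log2(1) = 0
  cnt3 <- matrix(c(0, 2, 4, 0, 2, 4), 3, 2, dimnames = dimnames(cnt))
  st3 <- median_ratio_log_normalize(cnt3, pseudocount = 1)
  expect_equal(unname(st3$values[1, ]), c(0, 0))

  expect_error(
    median_ratio_log_normalize(matrix(c(0, 0, 1, 2), 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("P1:PRE", "P1:POST")))),
    "all-zero"
  )
})

test_that("size factors scale with the sample and agree with the count-package estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(21)
  for (rep in 1:5) {
    cnt <- matrix(rpois(80, 50) + 1, 20, 4)
    dimnames(cnt) <- list(sprintf("g%d", 1:20),
                          sprintf("P%d:%s", rep(1:2, 2),
                                  rep(c("PRE", "POST"), each = 2)))
    sf <- attr(median_ratio_log_normalize(cnt)$values, "size_factors")
    expect_equal(unname(sf),
                 unname(DESeq2::estimateSizeFactorsForMatrix(cnt)),
                 tolerance = 1e-10)
    # scaling one sample by c multiplies its relative size factor by c
    # (size factors are defined up to a common rescaling of the
    # geometric-mean reference)
    cnt2 <- cnt
    cnt2[, 2] <- cnt2[, 2] * 4
    sf2 <- attr(median_ratio_log_normalize(cnt2)$values, "size_factors")
    expect_equal(unname(sf2[2] / sf2[1]), unname(sf[2] / sf[1]) * 4,
                 tolerance = 1e-10)
  }
})

test_that("probe collapse takes per-sample medians and is idempotent", {
  st <- make_paired_study(cbind(c(1, 3, 1, 2, 10)), cbind(c(2, 4, 5, 6, 7)),
                          genes = c("p1", "p2", "p3", "p4", "p5"))
  pm <- data.frame(probe = c("p1", "p2", "p3", "p4", "p5"),
                   gene = c("GA", "GA", "GB", "GB", "GB"))
  coll <- collapse_to_genes(st, pm)
  expect_equal(unname(coll$values["GA", 1]), 2)   # median of 1, 3
  expect_equal(unname(coll$values["GB", 1]), 2)   # median of 1, 2, 10
  # single probe per gene: values unchanged up to relabeling
  single <- collapse_to_genes(
    make_paired_study(cbind(1:2), cbind(3:4), genes = c("pA", "pB")),
    data.frame(probe = c("pA", "pB"), gene = c("gA", "gB"))
  )
  expect_equal(unname(single$values), matrix(c(1, 2, 3, 4), 2))
  # idempotent on collapsed input
  again <- collapse_to_genes(coll, data.frame(probe = c("GA", "GB"),
                                              gene = c("GA", "GB")))
  expect_equal(again$values, coll$values)
  expect_error(
    collapse_to_genes(st, data.frame(probe = "zz", gene = "GZ")),
    "no probe"
  )
})

test_that("GMT and complex-map readers parse the standard formats", {
  gmt <- write_tsv_fixture(c(
    "SET_A\tfirst set\tg1\tg2\tg3",
    "SET_B\tsecond set\tg2\tg4"
  ))
  gs <- read_gmt(gmt)
  expect_named(gs$sets, c("SET_A", "SET_B"))
  expect_equal(gs$sets$SET_B, c("g2", "g4"))
  bad <- write_tsv_fixture("ONLY_NAME\tdesc")
  expect_error(read_gmt(bad), "malformed GMT")

  cm <- write_tsv_fixture(c(
    "complex_id\tgene_id",
    "CPLX1\tg1",
    "CPLX1\tg2",
    "CPLX2\tg3"
  ))
  cmap <- read_complex_map(cm)
  expect_equal(cmap$CPLX1, c("g1", "g2"))
  expect_equal(lengths(cmap), c(CPLX1 = 2L, CPLX2 = 1L))
})
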