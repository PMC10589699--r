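test_that("item-trajectory CSVs parse verbatim and repair non-monotone rows", {
  f <- withr::local_tempfile(lines = c("item,16,17", "a,0.5,1.0", "b,0.0,0.5"))
  tab <- load_acquisition_table(f, month_range = c(16L, 17L))
  expect_equal(unname(tab$probs), rbind(c(0.5, 1), c(0, 0.5)))
  expect_equal(tab$concepts, c("a", "b"))

  g <- withr::local_tempfile(lines = c("item,16,17", "a,0.6,0.4"))
  expect_warning(tab2 <- load_acquisition_table(g, c(16L, 17L)), "clipped")
  expect_equal(unname(tab2$probs[1, ]), c(0.6, 0.6))

  h <- withr::local_tempfile(lines = c("item,16,18", "a,0.1,0.2"))
  expect_error(load_acquisition_table(h, c(16L, 18L)), "missing month")
  i <- withr::local_tempfile(lines = c("item,16,17", "a,0.5,1.7"))
  expect_error(load_acquisition_table(i, c(16L, 17L)), "\\[0, 1\\]")
})

test_that("multiword items without an alias are dropped with a warning; aliases remap", {
  f <- withr::local_tempfile(lines = c("item,16,17", "teddy bear,0.2,0.4", "dog,0.5,1.0"))
  expect_warning(tab <- load_acquisition_table(f, c(16L, 17L)), "multiword")
  expect_equal(tab$concepts, "dog")
  tab2 <- load_acquisition_table(f, c(16L, 17L),
                                 alias_map = c("teddy bear" = "teddybear"))
  expect_setequal(tab2$concepts, c("teddybear", "dog"))
})

test_that("monthly counts follow rounded cumulative probability sums", {
  sch <- monthly_counts(toy_table())
  expect_equal(sch$N_m, c(1L, 2L))
  expect_equal(sch$n_m, c(1L, 1L))
  single <- acquisition_table(matrix(1, 1, 1), "a", 16L)
  s1 <- monthly_counts(single)
  expect_equal(s1$N_m, 1L)
  expect_equal(s1$n_m, 1L)
  # rounding is half away from zero: column sums 0.5, 2.5 -> N = 1, 3
  t2 <- acquisition_table(rbind(c(0.25, 1), c(0.25, 1), c(0, 0.5)),
                          c("a", "b", "c"), 16:17)
  expect_equal(monthly_counts(t2)$N_m, c(1L, 3L))
})

test_that("per-month counts always sum to the final cumulative count", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    probs <- t(apply(matrix(runif(n * 4), n, 4), 1, function(r) cummax(r)))
    tab <- acquisition_table(probs, sprintf("c%d", 1:n), 16:19)
    sch <- monthly_counts(tab)
    expect_equal(sum(sch$n_m), sch$N_m[length(sch$N_m)])
  }
})

test_that("acquisition distributions renormalize over unacquired concepts", {
  tab <- acquisition_table(rbind(0.2, 0.6), c("a", "b"), 16L)
  expect_equal(acquisition_distribution(tab, 16), c(a = 0.25, b = 0.75))
  expect_equal(acquisition_distribution(tab, 16, known = "a"), c(b = 1))

  # brute-force renormalization oracle, 5 concepts with 2 known
  set.seed(2)
  p5 <- cbind(runif(5))
  tab5 <- acquisition_table(p5, letters[1:5], 16L)
  known <- c("b", "d")
  got <- acquisition_distribution(tab5, 16, known)
  manual <- p5[c(1, 3, 5), 1] / sum(p5[c(1, 3, 5), 1])
  expect_equal(unname(got), unname(manual))

  zero <- acquisition_table(rbind(c(0, 1), c(0, 1)), c("a", "b"), 16:17)
  expect_warning(u <- acquisition_distribution(zero, 16), "uniform")
  expect_equal(unname(u), c(0.5, 0.5))
})

test_that("a concept's sampling mass never grows when competitors strengthen", {
  base <- acquisition_table(rbind(0.3, 0.2, 0.1), c("a", "b", "c"), 16L)
  p0 <- acquisition_distribution(base, 16)[["a"]]
  stronger <- acquisition_table(rbind(0.3, 0.6, 0.1), c("a", "b", "c"), 16L)
  p1 <- acquisition_distribution(stronger, 16)[["a"]]
  expect_lt(p1, p0)
})

test_that("bootstrap distributions are exact for deterministic tables and obey split invariants", {
  det <- acquisition_table(rbind(c(1, 1), c(0, 1), c(1, 1), c(0, 1)),
                           c("a", "b", "c", "d"), 16:17)
  bs <- bootstrap_distributions(det, B = 4, seqs_per_boot = 5, seed = 1)
  for (b in bs$dists) expect_equal(unname(b), unname(det$probs))
  expect_length(intersect(bs$train_idx, bs$validation_idx), 0)
  expect_setequal(c(bs$train_idx, bs$validation_idx), 1:4)
  # inclusion proportions live on the 1/seqs grid and are monotone over months
  set.seed(4)
  tab <- acquisition_table(t(apply(matrix(runif(8), 4, 2), 1, cummax)),
                           letters[1:4], 16:17)
  bs2 <- bootstrap_distributions(tab, B = 2, seqs_per_boot = 6, seed = 2)
  for (b in bs2$dists) {
    expect_true(all(abs(b * 6 - round(b * 6)) < 1e-9))
    expect_true(all(b[, 2] >= b[, 1]))
  }
})

test_that("bootstrap inclusion proportions converge to exhaustively enumerated probabilities", {
  tab <- acquisition_table(rbind(c(0.8, 0.9), c(0.4, 0.8), c(0.2, 0.6), c(0.1, 0.3)),
                           letters[1:4], 16:17)
  sch <- month_schedule(16:17, c(1L, 1L))
  exact <- enumerate_inclusion(tab, sch)
  bs <- bootstrap_distributions(tab, B = 2, seqs_per_boot = 4000,
                                schedule = sch, seed = 9)
  est <- (bs$dists[[1]] + bs$dists[[2]]) / 2
  expect_equal(unname(est), unname(exact), tolerance = 0.03)
})
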