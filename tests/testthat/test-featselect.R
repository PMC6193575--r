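test_that("exact rank-sum p-values match frozen small-sample cases", {
  # symmetric all-tied case: mid-ranks give W = 10.5 and p = 1
  wr <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(wr$W, 10.5)
  expect_equal(wr$p_value, 1)

  # complete separation of 3 vs 3: one-sided tail 1/20, two-sided 0.1
  wr2 <- wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))
  expect_equal(wr2$W, 15)
  expect_equal(wr2$p_upper, 1 / 20)
  expect_equal(wr2$p_value, 0.1)
  expect_equal(wr2$method, "exact")
})

test_that("exact mode equals brute-force enumeration for all r+s <= 10", {
  set.seed(21)
  for (n in 4:10) for (r in 1:(n - 1)) {
    s <- n - r
    # continuous values and heavily tied values
    for (vals in list(rnorm(n), sample(1:3, n, replace = TRUE))) {
      pos <- vals[seq_len(r)]; neg <- vals[(r + 1):n]
      got <- wilcoxon_rank_sum(pos, neg, method = "exact")
      want <- wr_enumeration_oracle(pos, neg)
      expect_equal(got$W, want$W)
      expect_equal(got$p_lower, want$p_lower, tolerance = 1e-12)
      expect_equal(got$p_upper, want$p_upper, tolerance = 1e-12)
      expect_equal(got$p_value, want$p_two, tolerance = 1e-12)
    }
  }
})

test_that("normal approximation agrees with exact within 0.01 at 30 vs 30", {
  set.seed(31)
  for (i in 1:10) {
    pos <- rnorm(30, mean = 0.3 * (i %% 3)); neg <- rnorm(30)
    pe <- wilcoxon_rank_sum(pos, neg, method = "exact")$p_value
    pn <- wilcoxon_rank_sum(pos, neg, method = "normal")$p_value
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("p-values agree with the base-R test where it is exact", {
  set.seed(5)
  pos <- rnorm(8); neg <- rnorm(7)  # no ties -> wilcox.test exact applies
  ours <- wilcoxon_rank_sum(pos, neg, method = "exact")$p_value
  ref <- wilcox.test(pos, neg, exact = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("p-values are invariant under monotone transforms", {
  set.seed(8)
  pos <- rexp(12); neg <- rexp(15)
  p1 <- wilcoxon_rank_sum(pos, neg)$p_value
  p2 <- wilcoxon_rank_sum(log(pos), log(neg))$p_value
  p3 <- wilcoxon_rank_sum(pos^3, neg^3)$p_value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("feature ranking is order-invariant and puts signal first", {
  set.seed(41)
  n <- 40
  labels <- rep(c("positive", "negative"), each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  x[, 4] <- ifelse(labels == "positive", 10, 0) + rnorm(n, sd = 0.1)
  rk <- rank_features(x, labels)
  expect_equal(rk$feature[1], "f4")

  perm <- sample(n)
  rk2 <- rank_features(x[perm, ], labels[perm])
  expect_equal(rk2$feature, rk$feature)
  expect_equal(rk2$p_value, rk$p_value)

  # constant matrix: all p = 1, original order preserved by the tie-break
  xc <- matrix(1, n, 5, dimnames = list(NULL, paste0("c", 1:5)))
  rkc <- rank_features(xc, labels)
  expect_true(all(rkc$p_value == 1))
  expect_equal(rkc$feature, paste0("c", 1:5))
})

test_that("selection plans retain the right counts and reorder columns", {
  f <- separable_features(n_pos = 12, n_neg = 24, seed = 3)
  labels <- attr(f, "meta")$label
  rk <- rank_features(f, labels)
  plan <- build_selection_plan(rk, c(pCKSAAP = 390, AAindex = 250))
  expect_equal(plan$encodings$pCKSAAP$top_n, 390L)
  expect_equal(plan$encodings$AAindex$top_n, 250L)
  expect_equal(plan$encodings$AAC$top_n, 20L)
  expect_equal(plan$encodings$BE$top_n, 820L)
  expect_equal(plan$encodings$PSSM$top_n, 820L)
  expect_equal(plan$n_features, 390L + 250L + 20L + 820L + 820L)

  red <- apply_selection(f, plan)
  expect_equal(ncol(red), plan$n_features)
  nm <- plan$encodings$pCKSAAP$features[5]
  expect_equal(unclass(red)[, nm], unclass(f)[, nm])

  # idempotence: applying the plan to its own output is a no-op
  red2 <- apply_selection(red, plan)
  expect_equal(unclass(red2), unclass(red))

  # identity plan at full width
  plan_full <- build_selection_plan(rk, c(pCKSAAP = 2000, AAindex = 492))
  expect_equal(ncol(apply_selection(f, plan_full)), 4152L)

  expect_error(build_selection_plan(rk, c(pCKSAAP = 9999)), "exceeds")
  expect_error(apply_selection(features_subset(f, 1:100), plan),
               "not found")
})

test_that("plans serialize to JSON and back unchanged", {
  f <- separable_features(n_pos = 10, n_neg = 20, seed = 4)
  plan <- build_selection_plan(rank_features(f),
                               c(pCKSAAP = 50, AAindex = 30))
  j <- tempfile(fileext = ".json")
  write_plan(plan, j)
  back <- read_plan(j)
  expect_equal(back$encodings$pCKSAAP$features,
               plan$encodings$pCKSAAP$features)
  expect_equal(back$n_features, plan$n_features)
})

test_that("plans are deterministic and blind to held-out labels", {
  f <- separable_features(n_pos = 12, n_neg = 24, seed = 6)
  labels <- attr(f, "meta")$label
  p1 <- build_selection_plan(rank_features(f, labels),
                             c(pCKSAAP = 100, AAindex = 60))
  p2 <- build_selection_plan(rank_features(f, labels),
                             c(pCKSAAP = 100, AAindex = 60))
  expect_identical(p1, p2)

  # leakage audit: plan built on training rows only is unchanged when the
  # held-out rows' labels are scrambled
  tr <- 1:24; te <- 25:36
  lab2 <- labels
  lab2[te] <- sample(lab2[te])
  ptr <- build_selection_plan(
    rank_features(features_subset(f, seq_len(ncol(f)), tr), labels[tr]),
    c(pCKSAAP = 100, AAindex = 60))
  ptr2 <- build_selection_plan(
    rank_features(features_subset(f, seq_len(ncol(f)), tr), lab2[tr]),
    c(pCKSAAP = 100, AAindex = 60))
  expect_identical(ptr, ptr2)
})

test_that("species top-N presets are available and validated", {
  expect_equal(top_n_preset("generic"),
               c(AAindex = 250L, pCKSAAP = 390L))
  expect_equal(top_n_preset("h_sapiens"),
               c(AAindex = 260L, pCKSAAP = 440L))
  expect_equal(top_n_preset("t_aestivum"),
               c(AAindex = 120L, pCKSAAP = 400L))
  expect_error(top_n_preset("d_melanogaster"), "unknown")
})
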