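test_that("encoder widths match the published layout", {
  w <- random_window(1)
  pw <- random_profile_window(1)
  expect_length(encode_aac(w), 20L)
  expect_length(encode_binary(w), 820L)
  expect_length(encode_aaindex(w), 492L)
  expect_length(encode_pssm(pw), 820L)
  expect_length(encode_pcksaap(pw), 2000L)
  all5 <- encode_all(w, pw)
  expect_length(all5, 4152L)
  expect_false(anyDuplicated(names(all5)) > 0)
  expect_equal(as.vector(table(attr(all5, "encoding"))[
    c("AAC", "BE", "AAindex", "PSSM", "pCKSAAP")]),
    c(20L, 820L, 492L, 820L, 2000L))
})

test_that("AAC is the centre-excluded composition of observed residues", {
  w <- paste0(strrep("A", 20), "K", strrep("A", 20))
  v <- encode_aac(w)
  expect_equal(as.vector(v["AAC:A"]), 1)
  expect_equal(sum(v), 1)
  expect_equal(as.vector(v["AAC:K"]), 0)  # centre K not counted

  # hand-counting oracle on random windows, including gapped ones
  for (seed in 1:10) {
    w <- random_window(seed, left_gaps = seed %% 4, right_gaps = seed %% 3)
    ch <- strsplit(w, "")[[1]][-21]
    obs <- ch[ch %in% aa20]
    oracle <- table(factor(obs, levels = aa20)) / length(obs)
    expect_equal(as.vector(encode_aac(w)), as.numeric(oracle))
    expect_equal(sum(encode_aac(w)), 1)
  }

  # fully gapped flanks give the zero vector
  allgap <- paste0(strrep("-", 20), "K", strrep("-", 20))
  expect_equal(as.vector(encode_aac(allgap)), rep(0, 20))
})

test_that("binary encoding is one-hot, gap-aware and invertible", {
  w <- random_window(2, left_gaps = 5)
  v <- encode_binary(w)
  expect_equal(sum(v), 36)  # ones = non-gap positions
  expect_equal(decode_binary(v), w)
  for (seed in 3:8) {
    w <- random_window(seed, left_gaps = seed)
    expect_equal(decode_binary(encode_binary(w)), w)
  }
  # replacing a residue with a gap never adds nonzero features
  w <- random_window(2, left_gaps = 5)
  w2 <- w
  substr(w2, 30, 30) <- "-"
  expect_lte(sum(encode_binary(w2) != 0), sum(encode_binary(w) != 0))
  expect_lte(sum(encode_aaindex(w2) != 0), sum(encode_aaindex(w) != 0))
})

test_that("AAindex encoding equals a nested-loop lookup oracle", {
  tab <- load_aaindex_table()
  expect_equal(dim(tab), c(20L, 12L))
  for (seed in 1:6) {
    w <- random_window(seed, right_gaps = seed)
    v <- encode_aaindex(w, tab)
    ch <- strsplit(w, "")[[1]]
    k <- 0L
    for (p in 1:41) for (j in 1:12) {
      k <- k + 1L
      want <- if (ch[p] %in% rownames(tab)) tab[ch[p], j] else 0
      expect_identical(as.vector(v[k]), want)
    }
  }
  # single all-ones index: 1 at observed positions, 0 at gaps
  one <- matrix(1, 20, 1, dimnames = list(aa20, "ONE"))
  w <- random_window(4, left_gaps = 3)
  v1 <- encode_aaindex(w, one)
  expect_equal(as.vector(v1), c(rep(0, 3), rep(1, 38)))
})

test_that("PSSM encoding is the row-major flattening", {
  pw <- random_profile_window(5)
  v <- encode_pssm(pw)
  for (probe in list(c(1, 1), c(7, 13), c(41, 20), c(21, 9))) {
    r <- probe[1]; a <- probe[2]
    expect_equal(as.vector(v[(r - 1) * 20 + a]), as.vector(pw[r, a]))
  }
  expect_equal(as.vector(v["PSSM:pos0:K"]), as.vector(pw[21, "K"]))
  expect_equal(as.vector(encode_pssm(matrix(0, 41, 20))), rep(0, 820))
})

test_that("pCKSAAP matches the naive double-loop oracle", {
  for (seed in 1:8) {
    pw <- random_profile_window(seed)
    got <- encode_pcksaap(pw)
    want <- pcksaap_oracle(pw)
    expect_equal(as.vector(got), as.vector(want), tolerance = 1e-12)
    expect_identical(names(got), names(want))
    expect_true(all(got >= 0))
    expect_lte(max(got), max(pw[pw > 0], 0))
  }
  expect_equal(as.vector(encode_pcksaap(matrix(0, 41, 20))), rep(0, 2000))
  expect_error(encode_pcksaap(random_profile_window(1), k_values = 40),
               "k must be")
})

test_that("encoders are pure: identical inputs give identical outputs", {
  w <- random_window(10); pw <- random_profile_window(10)
  expect_identical(encode_all(w, pw), encode_all(w, pw))
})

test_that("encode_all blocks equal the individual encoders", {
  w <- random_window(12, left_gaps = 2)
  pw <- random_profile_window(12)
  v <- encode_all(w, pw)
  enc <- attr(v, "encoding")
  expect_equal(as.vector(v[enc == "AAC"]), as.vector(encode_aac(w)))
  expect_equal(as.vector(v[enc == "BE"]), as.vector(encode_binary(w)))
  expect_equal(as.vector(v[enc == "PSSM"]), as.vector(encode_pssm(pw)))
  expect_equal(as.vector(v[enc == "pCKSAAP"]), as.vector(encode_pcksaap(pw)))
})

test_that("encode_dataset aligns windows with their profile slices", {
  d <- generate_synthetic(synthetic_spec(n_proteins = 4, seed = 2))
  w <- extract_windows(d$proteins, d$sites)[1:8, ]
  f <- encode_dataset(w, d$profiles)
  expect_equal(dim(f), c(8L, 4152L))
  i <- 5L
  pw <- profile_window(d$profiles[[w$protein_id[i]]], w$position[i])
  expect_equal(as.vector(unclass(f)[i, ]),
               as.vector(encode_all(w$window[i], pw)))
  expect_equal(attr(f, "meta")$label, w$label)
})
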