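# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the helpers themselves write to tempdir.

aa20 <- gpsuc::AA_ALPHABET

# A random 41-symbol window with K at the centre and optional terminal gaps.
random_window <- function(seed = 1, left_gaps = 0, right_gaps = 0) {
  set.seed(seed)
  ch <- sample(aa20, 41, replace = TRUE)
  ch[21] <- "K"
  if (left_gaps > 0) ch[seq_len(left_gaps)] <- "-"
  if (right_gaps > 0) ch[(41 - right_gaps + 1):41] <- "-"
  paste(ch, collapse = "")
}

# A random 41 x 20 profile window (values roughly in the PSSM score range).
random_profile_window <- function(seed = 1) {
  set.seed(seed)
  matrix(round(rnorm(41 * 20, sd = 3)), nrow = 41,
         dimnames = list(NULL, aa20))
}

# Write a small FASTA + sites pair to tempdir; returns the two paths.
write_tiny_dataset <- function(proteins, sites) {
  dir <- tempfile("fx")
  dir.create(dir)
  fa <- file.path(dir, "p.fasta")
  gpsuc::write_fasta(proteins, fa)
  st <- file.path(dir, "s.tsv")
  gpsuc::write_sites(sites, st)
  list(fasta = fa, sites = st, dir = dir)
}

# Naive pCKSAAP oracle: explicit double loop over pairs and positions.
pcksaap_oracle <- function(pw, k_values = 0:4) {
  L <- nrow(pw)
  out <- numeric(0)
  nms <- character(0)
  for (k in k_values) {
    for (a in seq_len(20)) for (b in seq_len(20)) {
      s <- 0
      for (r in seq_len(L - k - 1)) {
        v <- min(pw[r, a], pw[r + k + 1, b])
        if (v > 0) s <- s + v
      }
      out <- c(out, s / (L - k - 1))
      nms <- c(nms, paste0("pCKSAAP:k", k, ":", aa20[a], aa20[b]))
    }
  }
  names(out) <- nms
  out
}

# Brute-force exact Wilcoxon tails by enumerating all C(r+s, r) subsets.
wr_enumeration_oracle <- function(pos, neg) {
  r <- length(pos)
  rk <- rank(c(pos, neg))
  W <- sum(rk[seq_len(r)])
  sums <- combn(rk, r, sum)
  list(W = W,
       p_lower = mean(sums <= W + 1e-9),
       p_upper = mean(sums >= W - 1e-9),
       p_two = min(1, 2 * min(mean(sums <= W + 1e-9),
                              mean(sums >= W - 1e-9))))
}

# Feature matrix with a planted separable block, for channel/selection tests.
separable_features <- function(n_pos = 30, n_neg = 60, seed = 1) {
  d <- gpsuc::generate_synthetic(
    gpsuc::synthetic_spec(n_proteins = 40, effect_size = 1, seed = seed))
  w <- gpsuc::extract_windows(d$proteins, d$sites)
  pos <- which(w$label == "positive")[seq_len(n_pos)]
  neg <- which(w$label == "negative")[seq_len(n_neg)]
  stopifnot(!anyNA(pos), !anyNA(neg))
  gpsuc::encode_dataset(w[c(pos, neg), ], d$profiles)
}
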