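# The five window encoders: AAC, BE, AAindex, PSSM, pCKSAAP.
#
# Every encoder is a pure function of its inputs and returns a named numeric
# vector with an "encoding" attribute. Gap ('-') and unknown ('X') positions
# contribute zeros everywhere.

window_chars <- function(window) {
  if (nchar(window) != WINDOW_SIZE)
    stop("window must be exactly ", WINDOW_SIZE, " symbols")
  strsplit(window, "")[[1]]
}

as_block <- function(values, names, encoding) {
  names(values) <- names
  attr(values, "encoding") <- encoding
  values
}

#' Amino-acid composition of a window
#'
#' Frequencies of the 20 canonical residues among the 40 flanking positions;
#' the central site residue is not counted. The denominator is the number of
#' observed flank residues (gaps and `X` excluded), so the frequencies are a
#' true composition of what was seen; a window with no observed flank
#' residue yields the zero vector.
#'
#' @param window 41-character window string.
#' @return Named numeric vector of length 20 (`AAC:A` .. `AAC:Y`).
#' @export
encode_aac <- function(window) {
  ch <- window_chars(window)[-(WINDOW_FLANK + 1L)]
  obs <- ch[ch %in% AA_ALPHABET]
  counts <- table(factor(obs, levels = AA_ALPHABET))
  v <- if (length(obs)) as.numeric(counts) / length(obs) else numeric(20L)
  as_block(v, paste0("AAC:", AA_ALPHABET), "AAC")
}

#' One-hot (binary) encoding of a window
#'
#' Each of the 41 positions contributes a 20-bit one-hot block in
#' [AA_ALPHABET] order; gap and `X` positions contribute all-zero blocks.
#' Width 41 x 20 = 820.
#'
#' @param window 41-character window string.
#' @return Named numeric vector of length 820 (`BE:pos-20:A` ...).
#' @export
encode_binary <- function(window) {
  ch <- window_chars(window)
  m <- matrix(0, nrow = WINDOW_SIZE, ncol = 20L)
  hit <- match(ch, AA_ALPHABET)
  ok <- which(!is.na(hit))
  m[cbind(ok, hit[ok])] <- 1
  nm <- paste0("BE:", rep(position_labels(), each = 20L), ":",
               rep(AA_ALPHABET, WINDOW_SIZE))
  as_block(as.numeric(t(m)), nm, "BE")
}

#' Decode a one-hot block back to a window string (inverse of encode_binary)
#' @param vec Numeric vector of length 820.
#' @return 41-character window string with `-` at all-zero blocks.
#' @export
decode_binary <- function(vec) {
  m <- matrix(vec, ncol = 20L, byrow = TRUE)
  ch <- apply(m, 1, function(r) {
    i <- which(r == 1)
    if (length(i) == 1L) AA_ALPHABET[i] else GAP_CHAR
  })
  paste(ch, collapse = "")
}

#' Physicochemical-property encoding of a window
#'
#' Looks up each window residue in every property scale of `table`. Layout
#' is position-major: all scales for position -20, then all scales for
#' position -19, and so on. Gap and `X` positions contribute zeros. With the
#' default 12-scale table the width is 41 x 12 = 492.
#'
#' @param window 41-character window string.
#' @param table Property matrix from [load_aaindex_table()].
#' @return Named numeric vector (`AAindex:pos-20:TSAJ990101` ...).
#' @export
encode_aaindex <- function(window, table = load_aaindex_table()) {
  ch <- window_chars(window)
  k <- ncol(table)
  m <- matrix(0, nrow = WINDOW_SIZE, ncol = k)
  hit <- match(ch, rownames(table))
  ok <- which(!is.na(hit))
  m[ok, ] <- table[hit[ok], , drop = FALSE]
  nm <- paste0("AAindex:", rep(position_labels(), each = k), ":",
               rep(colnames(table), WINDOW_SIZE))
  as_block(as.numeric(t(m)), nm, "AAindex")
}

#' Flattened profile encoding of a window
#'
#' Row-major flattening of the 41 x 20 profile window: position -20's 20
#' scores first. Width 820.
#'
#' @param profile_window 41 x 20 matrix from [profile_window()].
#' @return Named numeric vector (`PSSM:pos-20:A` ...).
#' @export
encode_pssm <- function(profile_window) {
  stopifnot(nrow(profile_window) == WINDOW_SIZE, ncol(profile_window) == 20L)
  nm <- paste0("PSSM:", rep(position_labels(), each = 20L), ":",
               rep(AA_ALPHABET, WINDOW_SIZE))
  as_block(as.numeric(t(profile_window)), nm, "PSSM")
}

#' Profile-based composition of k-spaced amino-acid pairs
#'
#' For each gap size k and each ordered residue pair (a, b), accumulates the
#' floored minimum of the two profile scores over every position pair
#' (r, r+k+1) in the window and normalises by the number of such pairs:
#'
#'   S_ab(k) = sum_r max(min(P[r, a], P[r+k+1, b]), 0) / (L - k - 1)
#'
#' with L = 41. Only pairs where both profile scores are positive
#' contribute, so every feature is non-negative. Ordering is k-major, then
#' first-residue-major pair order (`k0:AA, k0:AC, ..., k4:YY`). Width
#' 5 x 400 = 2000 at the default k set.
#'
#' @param profile_window 41 x 20 matrix from [profile_window()].
#' @param k_values Integer gap sizes (default 0:4).
#' @return Named numeric vector (`pCKSAAP:k0:AA` ...).
#' @export
encode_pcksaap <- function(profile_window, k_values = 0:4) {
  stopifnot(nrow(profile_window) == WINDOW_SIZE, ncol(profile_window) == 20L)
  L <- WINDOW_SIZE
  if (any(k_values >= L - 1L)) stop("k must be < L - 1 = ", L - 1L)
  out <- numeric(length(k_values) * 400L)
  nm <- character(length(out))
  pos <- 0L
  pair_names <- paste0(rep(AA_ALPHABET, each = 20L), rep(AA_ALPHABET, 20L))
  for (k in k_values) {
    A <- profile_window[1:(L - k - 1L), , drop = FALSE]
    B <- profile_window[(k + 2L):L, , drop = FALSE]
    vals <- numeric(400L)
    for (i in 1:20) {
      m <- pmin(B, A[, i])       # recycles A[, i] down each column of B
      m[m < 0] <- 0
      vals[((i - 1L) * 20L + 1L):(i * 20L)] <- colSums(m)
    }
    out[pos + 1:400] <- vals / (L - k - 1L)
    nm[pos + 1:400] <- paste0("pCKSAAP:k", k, ":", pair_names)
    pos <- pos + 400L
  }
  as_block(out, nm, "pCKSAAP")
}

#' Encode one window into the full concatenated feature vector
#'
#' Concatenates the five blocks in the fixed order AAC, BE, AAindex, PSSM,
#' pCKSAAP (default width 20 + 820 + 492 + 820 + 2000 = 4152).
#'
#' @param window 41-character window string.
#' @param profile_window 41 x 20 profile matrix aligned with `window`.
#' @param table Property matrix for the AAindex block.
#' @return Named numeric vector with an `encoding` attribute giving each
#'   feature's block.
#' @export
encode_all <- function(window, profile_window, table = load_aaindex_table()) {
  blocks <- list(encode_aac(window),
                 encode_binary(window),
                 encode_aaindex(window, table),
                 encode_pssm(profile_window),
                 encode_pcksaap(profile_window))
  v <- unlist(lapply(blocks, as.numeric), use.names = FALSE)
  names(v) <- unlist(lapply(blocks, names), use.names = FALSE)
  attr(v, "encoding") <- rep(vapply(blocks, attr, "", "encoding"),
                             vapply(blocks, length, 0L))
  v
}

#' Encode a window table into a feature matrix
#'
#' Builds the n x 4152 feature matrix for a set of windows, slicing a
#' profile window for each site from the matching entry of `profiles`.
#'
#' @param windows data.frame from [extract_windows()].
#' @param profiles Named list of `pssm_profile` objects covering every
#'   protein in `windows` (see [load_profiles()]).
#' @param table Property matrix for the AAindex block.
#' @return A `gpsuc_features` object: numeric matrix with named columns and
#'   attributes `encoding` (block of each column) and `meta` (the window
#'   provenance data.frame).
#' @export
encode_dataset <- function(windows, profiles, table = load_aaindex_table()) {
  stopifnot(nrow(windows) >= 1L)
  missing <- setdiff(unique(windows$protein_id), names(profiles))
  if (length(missing))
    stop("no profile for protein(s): ", paste(missing, collapse = ", "))
  first <- encode_all(windows$window[1],
                      profile_window(profiles[[windows$protein_id[1]]],
                                     windows$position[1]), table)
  m <- matrix(0, nrow = nrow(windows), ncol = length(first),
              dimnames = list(NULL, names(first)))
  m[1, ] <- first
  if (nrow(windows) > 1L) for (i in 2:nrow(windows)) {
    pw <- profile_window(profiles[[windows$protein_id[i]]],
                         windows$position[i])
    m[i, ] <- encode_all(windows$window[i], pw, table)
  }
  structure(m,
            encoding = attr(first, "encoding"),
            meta = windows[, c("protein_id", "position", "label")],
            class = c("gpsuc_features", "matrix", "array"))
}

#' @export
print.gpsuc_features <- function(x, ...) {
  enc <- attr(x, "encoding")
  cat("Feature matrix:", nrow(x), "windows x", ncol(x), "features\n")
  print(table(factor(enc, levels = ENCODING_ORDER)))
  invisible(x)
}

# Subset a feature matrix by column names/indices, keeping attributes.
features_subset <- function(x, cols, rows = NULL) {
  enc <- attr(x, "encoding")
  meta <- attr(x, "meta")
  if (is.character(cols)) {
    idx <- match(cols, colnames(x))
    if (anyNA(idx))
      stop("feature column(s) not found: ",
           paste(cols[is.na(idx)], collapse = ", "))
  } else idx <- cols
  if (is.null(rows)) rows <- seq_len(nrow(x))
  structure(unclass(x)[rows, idx, drop = FALSE],
            encoding = enc[idx], meta = meta[rows, , drop = FALSE],
            class = c("gpsuc_features", "matrix", "array"))
}

#' Export a feature matrix to TSV
#'
#' First columns are `protein_id`, `position`, `label`, followed by the
#' named feature columns in their stable block order.
#'
#' @param features A `gpsuc_features` object.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  meta <- attr(features, "meta")
  df <- cbind(meta, as.data.frame(unclass(features), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
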