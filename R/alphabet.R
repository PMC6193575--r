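#' @keywords internal
"_PACKAGE"

#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino-acid one-letter codes in the fixed order used by
#' every encoder and profile in this package. All position-specific scoring
#' matrices are remapped to this order on ingest, whatever the column order
#' of the source file.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Window geometry: +/- 20 residues around the central lysine.
WINDOW_FLANK <- 20L
WINDOW_SIZE <- 41L
GAP_CHAR <- "-"
UNKNOWN_CHAR <- "X"

# Residues legal in an ingested protein sequence.
LEGAL_RESIDUES <- c(AA_ALPHABET, UNKNOWN_CHAR)

# Fixed channel order for score fusion: AAC, AAindex, BE, PSSM, pCKSAAP.
CHANNEL_ORDER <- c("AAC", "AAindex", "BE", "PSSM", "pCKSAAP")

# Block order in the concatenated feature vector.
ENCODING_ORDER <- c("AAC", "BE", "AAindex", "PSSM", "pCKSAAP")

#' BLOSUM62 substitution scores over the canonical alphabet
#'
#' Integer BLOSUM62 log-odds substitution scores, rows and columns in
#' [AA_ALPHABET] order. Used by [pseudo_profile()] to build a deterministic
#' sequence profile when no PSI-BLAST search profile is available.
#'
#' @format 20 x 20 integer matrix with dimnames = amino-acid letters.
#' @export
BLOSUM62_20 <- local({
  v <- c(
     4,  0, -2, -1, -2,  0, -2, -1, -1, -1, -1, -2, -1, -1, -1,  1,  0,  0, -3, -2,
     0,  9, -3, -4, -2, -3, -3, -1, -3, -1, -1, -3, -3, -3, -3, -1, -1, -1, -2, -2,
    -2, -3,  6,  2, -3, -1, -1, -3, -1, -4, -3,  1, -1,  0, -2,  0, -1, -3, -4, -3,
    -1, -4,  2,  5, -3, -2,  0, -3,  1, -3, -2,  0, -1,  2,  0,  0, -1, -2, -3, -2,
    -2, -2, -3, -3,  6, -3, -1,  0, -3,  0,  0, -3, -4, -3, -3, -2, -2, -1,  1,  3,
     0, -3, -1, -2, -3,  6, -2, -4, -2, -4, -3,  0, -2, -2, -2,  0, -2, -3, -2, -3,
    -2, -3, -1,  0, -1, -2,  8, -3, -1, -3, -2,  1, -2,  0,  0, -1, -2, -3, -2,  2,
    -1, -1, -3, -3,  0, -4, -3,  4, -3,  2,  1, -3, -3, -3, -3, -2, -1,  3, -3, -1,
    -1, -3, -1,  1, -3, -2, -1, -3,  5, -2, -1,  0, -1,  1,  2,  0, -1, -2, -3, -2,
    -1, -1, -4, -3,  0, -4, -3,  2, -2,  4,  2, -3, -3, -2, -2, -2, -1,  1, -2, -1,
    -1, -1, -3, -2,  0, -3, -2,  1, -1,  2,  5, -2, -2,  0, -1, -1, -1,  1, -1, -1,
    -2, -3,  1,  0, -3,  0,  1, -3,  0, -3, -2,  6, -2,  0,  0,  1,  0, -3, -4, -2,
    -1, -3, -1, -1, -4, -2, -2, -3, -1, -3, -2, -2,  7, -1, -2, -1, -1, -2, -4, -3,
    -1, -3,  0,  2, -3, -2,  0, -3,  1, -2,  0,  0, -1,  5,  1,  0, -1, -2, -2, -1,
    -1, -3, -2,  0, -3, -2,  0, -3,  2, -2, -1,  0, -2,  1,  5, -1, -1, -3, -3, -2,
     1, -1,  0,  0, -2,  0, -1, -2,  0, -2, -1,  1, -1,  0, -1,  4,  1, -2, -3, -2,
     0, -1, -1, -1, -2, -2, -2, -1, -1, -1, -1,  0, -1, -1, -1,  1,  5,  0, -2, -2,
     0, -1, -3, -2, -1, -3, -3,  3, -2,  1,  1, -3, -2, -2, -3, -2,  0,  4, -3, -1,
    -3, -2, -4, -3,  1, -2, -2, -3, -3, -2, -1, -4, -4, -2, -3, -3, -2, -3, 11,  2,
    -2, -2, -3, -2,  3, -3,  2, -1, -2, -1, -1, -2, -3, -1, -2, -2, -2, -1,  2,  7)
  m <- matrix(as.integer(v), nrow = 20, byrow = TRUE,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m
})

# Position labels relative to the window centre: "pos-20" .. "pos0" .. "pos+20"
position_labels <- function() {
  off <- seq_len(WINDOW_SIZE) - (WINDOW_FLANK + 1L)
  paste0("pos", ifelse(off > 0, paste0("+", off), as.character(off)))
}

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
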