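# PSI-BLAST PSSM parsing, pseudo-profiles, and profile-window slicing.

new_pssm_profile <- function(protein_id, sequence, scores, source) {
  stopifnot(nrow(scores) == nchar(sequence), ncol(scores) == 20L)
  colnames(scores) <- AA_ALPHABET
  structure(list(protein_id = protein_id, sequence = sequence,
                 scores = scores, source = source),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("PSSM profile '", x$protein_id, "': ", nrow(x$scores),
      " positions x 20 residues (source: ", x$source, ")\n", sep = "")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the text matrix written by `psiblast -out_ascii_pssm`. Only the
#' first 20 columns (position-specific log-odds scores) are used; the
#' weighted-percentage columns and the information-content trailer are
#' ignored. Columns are remapped from the file's own amino-acid order to
#' [AA_ALPHABET] order.
#'
#' @param path Path to the ASCII PSSM file.
#' @param protein_id Identifier to attach; defaults to the file basename.
#' @param sequence Optional sequence to cross-check the residue column
#'   against; a mismatch is an error naming the offending row.
#' @return A `pssm_profile` object: L x 20 numeric score matrix plus the
#'   residue string recovered from the file.
#' @export
read_psiblast_pssm <- function(path, protein_id = NULL, sequence = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(protein_id))
    protein_id <- sub("\\.pssm$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*A\\s+R\\s+N|^\\s*[A-Z](\\s+[A-Z]){19,}", lines)[1]
  if (is.na(hdr)) stop("no column-header line found in PSSM file: ", path)
  letters20 <- strsplit(trimws(lines[hdr]), "\\s+")[[1]][1:20]
  if (!setequal(letters20, AA_ALPHABET))
    stop("unrecognised amino-acid column order in ", path)
  body <- lines[-seq_len(hdr)]
  row_re <- "^\\s*\\d+\\s+[A-Z*]\\s+-?\\d"
  body <- body[grepl(row_re, body)]
  if (length(body) == 0L) stop("truncated PSSM file (no data rows): ", path)
  scores <- matrix(NA_real_, nrow = length(body), ncol = 20L)
  residues <- character(length(body))
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 22L)
      stop("truncated PSSM row ", i, " in ", path)
    idx <- suppressWarnings(as.integer(tok[1]))
    if (is.na(idx) || idx != i)
      stop("unexpected row numbering at data row ", i, " in ", path)
    residues[i] <- tok[2]
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals)) stop("non-numeric score cell at row ", i, " in ", path)
    scores[i, ] <- vals
  }
  colnames(scores) <- letters20
  scores <- scores[, AA_ALPHABET, drop = FALSE]
  seq_from_file <- paste(residues, collapse = "")
  if (!is.null(sequence)) {
    if (nchar(sequence) != length(residues))
      stop("PSSM has ", length(residues), " rows but sequence has ",
           nchar(sequence), " residues (", protein_id, ")")
    sv <- strsplit(sequence, "")[[1]]
    bad <- which(residues != sv & residues != "X" & sv != "X")
    if (length(bad))
      stop("PSSM residue column disagrees with sequence at row ", bad[1],
           ": file has '", residues[bad[1]], "', sequence has '",
           sv[bad[1]], "'")
    seq_from_file <- sequence
  }
  new_pssm_profile(protein_id, seq_from_file, scores, "psiblast")
}

#' Write a profile in PSI-BLAST ASCII PSSM layout
#'
#' Emits the log-odds block in the same dialect [read_psiblast_pssm()]
#' accepts, so written profiles round-trip. Percentage columns are written
#' as zeros.
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @export
write_pssm <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("            ",
                    paste(sprintf("%3s", c(AA_ALPHABET, AA_ALPHABET)),
                          collapse = "")), con)
  sv <- strsplit(profile$sequence, "")[[1]]
  for (i in seq_len(nrow(profile$scores))) {
    writeLines(paste0(sprintf("%5d %s ", i, sv[i]),
                      paste(sprintf("%3d", round(profile$scores[i, ])),
                            collapse = ""),
                      paste(rep("   0", 20), collapse = "")), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Deterministic pseudo-profile from a substitution table
#'
#' Builds an L x 20 profile without running any database search: row r is
#' the BLOSUM62 substitution-score row of the residue at position r, so the
#' profile carries residue identity and coarse exchangeability information.
#' Rows at unknown residues (`X`) are all zero.
#'
#' @param sequence Amino-acid sequence string.
#' @param protein_id Identifier to attach.
#' @return A `pssm_profile` with `source = "pseudo"`.
#' @export
pseudo_profile <- function(sequence, protein_id = "unnamed") {
  sv <- strsplit(sequence, "")[[1]]
  scores <- matrix(0, nrow = length(sv), ncol = 20L,
                   dimnames = list(NULL, AA_ALPHABET))
  known <- sv %in% AA_ALPHABET
  scores[known, ] <- BLOSUM62_20[sv[known], , drop = FALSE]
  new_pssm_profile(protein_id, sequence, scores, "pseudo")
}

#' Slice a 41-row profile window around a site
#'
#' Rows outside the protein (terminal padding) and rows at unknown (`X`)
#' residues are all-zero, mirroring the gap convention of the sequence
#' window.
#'
#' @param profile A `pssm_profile`.
#' @param position 1-based central position.
#' @return 41 x 20 numeric matrix, columns in [AA_ALPHABET] order.
#' @export
profile_window <- function(profile, position) {
  L <- nrow(profile$scores)
  if (position < 1L || position > L)
    stop("position ", position, " out of profile range [1, ", L, "]")
  out <- matrix(0, nrow = WINDOW_SIZE, ncol = 20L,
                dimnames = list(position_labels(), AA_ALPHABET))
  lo <- position - WINDOW_FLANK
  hi <- position + WINDOW_FLANK
  src <- max(1L, lo):min(L, hi)
  out[src - lo + 1L, ] <- profile$scores[src, , drop = FALSE]
  sv <- strsplit(profile$sequence, "")[[1]]
  unk <- src[sv[src] == UNKNOWN_CHAR]
  if (length(unk)) out[unk - lo + 1L, ] <- 0
  out
}

#' Load per-protein PSSM files from a directory
#'
#' Follows the one-file-per-protein convention `<dir>/<protein_id>.pssm`.
#' Proteins without a file fall back to [pseudo_profile()].
#'
#' @param proteins Named character vector of sequences.
#' @param dir Directory of `.pssm` files, or `NULL` to use pseudo-profiles
#'   throughout.
#' @return Named list of `pssm_profile` objects.
#' @export
load_profiles <- function(proteins, dir = NULL) {
  out <- vector("list", length(proteins))
  names(out) <- names(proteins)
  for (id in names(proteins)) {
    f <- if (is.null(dir)) "" else file.path(dir, paste0(id, ".pssm"))
    out[[id]] <- if (nzchar(f) && file.exists(f))
      read_psiblast_pssm(f, id, proteins[[id]])
    else pseudo_profile(proteins[[id]], id)
  }
  out
}
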