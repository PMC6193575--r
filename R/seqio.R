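# Sequence and site-annotation input, window extraction, training-set assembly.

#' Read protein sequences from a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file into a named
#' character vector of uppercase sequences. The record identifier is the
#' first whitespace-delimited token of the header line. Trailing stop
#' symbols (`*`) are stripped; any other character outside the 20 canonical
#' amino-acid letters and `X` is rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: names are record ids, values are
#'   uppercase amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) stop("empty sequence for record '", ids[i], "'")
    bad <- setdiff(strsplit(seqs[i], "")[[1]], LEGAL_RESIDUES)
    if (length(bad))
      stop("illegal residue character(s) in record '", ids[i], "': ",
           paste(unique(bad), collapse = " "))
  }
  names(seqs) <- ids
  seqs
}

#' Read site annotations from a TSV file
#'
#' Expects a header line and three tab-separated columns: `protein_id`,
#' `position` (1-based) and `label`. Label tokens `positive`/`1`/`+1` map to
#' positive, `negative`/`-1` to negative. When `proteins` is supplied, each
#' site is validated: the position must be in range and the residue there
#' must be lysine (K).
#'
#' @param path Path to the TSV file.
#' @param proteins Optional named character vector of sequences (as returned
#'   by [read_fasta()]) used to validate positions.
#' @return data.frame with columns `protein_id` (character), `position`
#'   (integer) and `label` (character, "positive"/"negative").
#' @export
read_sites <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("sites file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(df)))
    stop("sites TSV must have columns: ", paste(need, collapse = ", "))
  pos <- suppressWarnings(as.integer(df$position))
  if (anyNA(pos)) stop("non-integer position in sites file (row ",
                       which(is.na(pos))[1], ")")
  lab <- normalize_labels(df$label)
  sites <- data.frame(protein_id = df$protein_id, position = pos,
                      label = lab, stringsAsFactors = FALSE)
  if (any(sites$position < 1L))
    stop("positions are 1-based; found position ",
         min(sites$position), " (row ", which(sites$position < 1L)[1], ")")
  if (!is.null(proteins)) validate_sites(sites, proteins)
  sites
}

normalize_labels <- function(x) {
  out <- rep(NA_character_, length(x))
  out[x %in% c("positive", "1", "+1")] <- "positive"
  out[x %in% c("negative", "-1")] <- "negative"
  if (anyNA(out))
    stop("unknown label token(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

validate_sites <- function(sites, proteins) {
  missing <- setdiff(sites$protein_id, names(proteins))
  if (length(missing))
    stop("site(s) refer to unknown protein(s): ",
         paste(unique(missing), collapse = ", "))
  for (i in seq_len(nrow(sites))) {
    s <- proteins[[sites$protein_id[i]]]
    p <- sites$position[i]
    if (p > nchar(s))
      stop("site position ", p, " out of range for protein '",
           sites$protein_id[i], "' (length ", nchar(s), ")")
    res <- substr(s, p, p)
    if (res != "K")
      stop("residue at ", sites$protein_id[i], ":", p,
           " is '", res, "', not 'K'")
  }
  invisible(sites)
}

#' Enumerate lysine positions in a sequence
#'
#' @param sequence A single amino-acid sequence string.
#' @return Ascending integer vector of 1-based positions holding `K`.
#' @export
enumerate_lysines <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  which(strsplit(sequence, "")[[1]] == "K")
}

#' Extract a 41-residue window centred on a lysine
#'
#' Returns the +/- 20 residue fragment around `position`, padding flanks
#' that run past either terminus with `-` so the window is always exactly
#' 41 symbols with the site residue at the centre.
#'
#' @param sequence Amino-acid sequence string.
#' @param position 1-based position of the central lysine.
#' @return Character scalar of length 41.
#' @export
extract_window <- function(sequence, position) {
  n <- nchar(sequence)
  if (position < 1L || position > n)
    stop("position ", position, " out of range [1, ", n, "]")
  if (substr(sequence, position, position) != "K")
    stop("residue at position ", position, " is '",
         substr(sequence, position, position), "', not 'K'")
  lo <- position - WINDOW_FLANK
  hi <- position + WINDOW_FLANK
  left_pad <- max(0L, 1L - lo)
  right_pad <- max(0L, hi - n)
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep(GAP_CHAR, left_pad), core, strrep(GAP_CHAR, right_pad))
}

#' Extract windows for a table of sites
#'
#' @param proteins Named character vector of sequences.
#' @param sites data.frame as returned by [read_sites()]; a `label` column
#'   is carried through when present.
#' @return data.frame with columns `protein_id`, `position`, `label`
#'   (NA when absent) and `window` (41-character string).
#' @export
extract_windows <- function(proteins, sites) {
  validate_sites(sites, proteins)
  win <- character(nrow(sites))
  for (i in seq_len(nrow(sites)))
    win[i] <- extract_window(proteins[[sites$protein_id[i]]], sites$position[i])
  data.frame(protein_id = sites$protein_id,
             position = sites$position,
             label = if ("label" %in% names(sites)) sites$label else NA_character_,
             window = win, stringsAsFactors = FALSE)
}

#' Assemble a training set at a 1:2 positive:negative ratio
#'
#' Keeps every positive window and draws negatives without replacement down
#' to twice the positive count. When fewer than `2 * n_pos` negatives exist,
#' all of them are used and a warning is emitted.
#'
#' @param windows data.frame from [extract_windows()] with a `label` column.
#' @param seed Integer seed making the subsample reproducible.
#' @param ratio Negatives retained per positive (default 2).
#' @return data.frame of the retained windows (positives first).
#' @export
sample_training_set <- function(windows, seed, ratio = 2) {
  pos <- windows[windows$label == "positive", , drop = FALSE]
  neg <- windows[windows$label == "negative", , drop = FALSE]
  if (nrow(pos) == 0L) stop("no positive windows")
  want <- as.integer(round(ratio * nrow(pos)))
  if (nrow(neg) < want) {
    warning("only ", nrow(neg), " negatives available for ", nrow(pos),
            " positives (wanted ", want, "); using all negatives")
    keep <- neg
  } else {
    idx <- with_seed(seed, sample.int(nrow(neg), want))
    keep <- neg[sort(idx), , drop = FALSE]
  }
  out <- rbind(pos, keep)
  rownames(out) <- NULL
  out
}

#' Write sequences to FASTA
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(proteins)) {
    writeLines(paste0(">", id), con)
    s <- proteins[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write site annotations to TSV
#' @param sites data.frame with protein_id, position, label.
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites[, c("protein_id", "position", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
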