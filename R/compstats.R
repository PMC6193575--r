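# Compositional-bias analyses around succinylation sites: positional
# amino-acid frequencies (AAF), mean profile values (MPV), mean
# physicochemical-property values (MPP) and their significance tests.

#' Positional amino-acid frequencies (AAF)
#'
#' Frequency of each canonical residue at each window position, computed
#' over the observed (non-gap, non-X) residues at that position.
#'
#' @param windows Character vector of 41-symbol windows, or a data.frame
#'   with a `window` column.
#' @return 41 x 20 numeric matrix (rows `pos-20`..`pos+20`, columns
#'   residues); rows with no observation are all zero.
#' @export
positional_aaf <- function(windows) {
  windows <- as_window_vector(windows)
  ch <- window_char_matrix(windows)
  out <- matrix(0, nrow = WINDOW_SIZE, ncol = 20L,
                dimnames = list(position_labels(), AA_ALPHABET))
  for (p in seq_len(WINDOW_SIZE)) {
    obs <- ch[, p][ch[, p] %in% AA_ALPHABET]
    if (length(obs))
      out[p, ] <- as.numeric(table(factor(obs, levels = AA_ALPHABET))) /
        length(obs)
  }
  out
}

as_window_vector <- function(windows) {
  if (is.data.frame(windows)) windows <- windows$window
  stopifnot(is.character(windows), length(windows) >= 1L,
            all(nchar(windows) == WINDOW_SIZE))
  windows
}

# n x 41 character matrix of window symbols
window_char_matrix <- function(windows) {
  m <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
              ncol = WINDOW_SIZE, byrow = TRUE)
  colnames(m) <- position_labels()
  m
}

#' Per-window, per-position profile values
#'
#' For each window and each position, the profile window entry for the
#' residue observed there; NA at gaps and unknowns. These are the raw
#' inputs for the MPV summary and its positional test.
#'
#' @param windows data.frame from [extract_windows()].
#' @param profiles Named list of `pssm_profile` objects.
#' @return n x 41 numeric matrix.
#' @export
window_profile_values <- function(windows, profiles) {
  ch <- window_char_matrix(windows$window)
  out <- matrix(NA_real_, nrow = nrow(windows), ncol = WINDOW_SIZE,
                dimnames = list(NULL, position_labels()))
  for (i in seq_len(nrow(windows))) {
    pw <- profile_window(profiles[[windows$protein_id[i]]],
                         windows$position[i])
    hit <- match(ch[i, ], AA_ALPHABET)
    ok <- which(!is.na(hit))
    out[i, ok] <- pw[cbind(ok, hit[ok])]
  }
  out
}

#' Per-window, per-position property values
#'
#' The value of one property scale for the residue observed at each window
#' position; NA at gaps and unknowns. Raw inputs for the MPP summary.
#'
#' @param windows Character vector of windows or data.frame with `window`.
#' @param index_id Scale accession (default NAKH920108, the amino-acid
#'   composition of multi-spanning membrane proteins).
#' @param table Property matrix from [load_aaindex_table()].
#' @return n x 41 numeric matrix.
#' @export
window_property_values <- function(windows, index_id = "NAKH920108",
                                   table = load_aaindex_table()) {
  if (!index_id %in% colnames(table))
    stop("unknown property scale '", index_id, "'")
  ch <- window_char_matrix(as_window_vector(windows))
  vals <- table[, index_id]
  m <- matrix(vals[match(ch, names(vals))], nrow = nrow(ch))
  colnames(m) <- position_labels()
  m
}

#' Mean profile value (MPV) per window position
#'
#' @inheritParams window_profile_values
#' @return Named numeric vector of length 41 (NaN where every window has a
#'   gap at that position).
#' @export
mean_profile_value <- function(windows, profiles) {
  colMeans(window_profile_values(windows, profiles), na.rm = TRUE)
}

#' Mean physicochemical-property value (MPP) per window position
#'
#' @inheritParams window_property_values
#' @return Named numeric vector of length 41 (NaN at gap-only positions).
#' @export
mean_property_value <- function(windows, index_id = "NAKH920108",
                                table = load_aaindex_table()) {
  colMeans(window_property_values(windows, index_id, table), na.rm = TRUE)
}

#' Positional significance tests between site groups
#'
#' `test = "kruskal_wallis"`: per window position, a two-group
#' Kruskal-Wallis test of the supplied per-window values (positive vs
#' negative windows), which for two groups is the Wilcoxon rank-sum test
#' and is computed by [wilcoxon_rank_sum()]. Inputs are n x 41 value
#' matrices (see [window_profile_values()] / [window_property_values()]).
#'
#' `test = "chi_square"`: per (position, residue) within `positions`
#' (default -5..+5), a 2 x 2 chi-square test of residue occurrence counts
#' (residue vs other) between the groups; inputs are window vectors.
#' Expected counts below 5 trigger the continuity-corrected statistic with
#' a warning.
#'
#' Raw p-values are Bonferroni-adjusted by the number of tests actually
#' performed, reported in the `m` attribute and column.
#'
#' @param pos_inputs,neg_inputs Value matrices (kruskal_wallis) or window
#'   vectors/data.frames (chi_square) for the two groups.
#' @param test "kruskal_wallis" or "chi_square".
#' @param positions Integer window offsets tested by the chi-square branch.
#' @param alpha Significance level for the `significant` flag.
#' @return data.frame with `position` (offset), `residue` (chi-square
#'   only), `p`, `p_adj` (min(1, m * p)), `m`, `significant`.
#' @export
positional_test <- function(pos_inputs, neg_inputs,
                            test = c("kruskal_wallis", "chi_square"),
                            positions = -5:5, alpha = 0.05) {
  test <- match.arg(test)
  if (test == "kruskal_wallis") {
    stopifnot(is.matrix(pos_inputs), is.matrix(neg_inputs),
              ncol(pos_inputs) == WINDOW_SIZE,
              ncol(neg_inputs) == WINDOW_SIZE)
    p <- numeric(WINDOW_SIZE)
    for (j in seq_len(WINDOW_SIZE)) {
      a <- pos_inputs[, j]; a <- a[!is.na(a)]
      b <- neg_inputs[, j]; b <- b[!is.na(b)]
      p[j] <- if (length(a) && length(b) &&
                  !all(c(a, b) == c(a, b)[1]))
        wilcoxon_rank_sum(a, b)$p_value else 1
    }
    out <- data.frame(position = seq_len(WINDOW_SIZE) - (WINDOW_FLANK + 1L),
                      p = p)
  } else {
    cp <- window_char_matrix(as_window_vector(pos_inputs))
    cn <- window_char_matrix(as_window_vector(neg_inputs))
    cols <- positions + WINDOW_FLANK + 1L
    stopifnot(all(cols >= 1L & cols <= WINDOW_SIZE))
    rows <- list()
    n_degenerate <- 0L
    for (k in seq_along(cols)) {
      a <- cp[, cols[k]]; a <- a[a %in% AA_ALPHABET]
      b <- cn[, cols[k]]; b <- b[b %in% AA_ALPHABET]
      for (res in AA_ALPHABET) {
        tab <- matrix(c(sum(a == res), length(a) - sum(a == res),
                        sum(b == res), length(b) - sum(b == res)),
                      nrow = 2)
        pv <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
          n_degenerate <- n_degenerate + 1L
          1
        } else {
          low <- any(suppressWarnings(
            stats::chisq.test(tab, correct = FALSE))$expected < 5)
          suppressWarnings(stats::chisq.test(tab, correct = low)$p.value)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(position = positions[k], residue = res, p = pv)
      }
    }
    out <- do.call(rbind, rows)
    if (n_degenerate > 0L)
      warning(n_degenerate, " (position, residue) table(s) had an empty ",
              "margin (e.g. the invariant central K); their p was set to 1")
  }
  m <- nrow(out)
  out$p_adj <- pmin(1, m * out$p)
  out$m <- m
  out$significant <- out$p_adj < alpha
  attr(out, "m") <- m
  out
}

#' Per-position residue enrichment/depletion differences
#'
#' Difference of the positional amino-acid frequency tables of the two
#' groups; positive values mean the residue is enriched around the
#' modified (positive) sites. These are the per-position frequency
#' differences a two-sample logo renders.
#'
#' @param windows_pos,windows_neg Window vectors or data.frames for the
#'   positive and negative groups.
#' @return 41 x 20 signed difference matrix.
#' @export
enrichment_depletion <- function(windows_pos, windows_neg) {
  positional_aaf(windows_pos) - positional_aaf(windows_neg)
}

#' Export a positional table to TSV
#' @param x Matrix or data.frame (positional table or test report).
#' @param path Output path.
#' @export
write_positional_table <- function(x, path) {
  if (is.matrix(x))
    x <- data.frame(position = rownames(x), x, check.names = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
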