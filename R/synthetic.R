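# Self-contained synthetic data: proteins, site labels and pseudo-profiles
# with a tunable positional motif signal around positive sites.

# Swiss-Prot-like background residue frequencies (percent, canonical order).
SWISSPROT_FREQ <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86,
                    G = 7.07, H = 2.27, I = 5.91, K = 5.80, L = 9.65,
                    M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.53,
                    S = 6.64, T = 5.35, V = 6.86, W = 1.10, Y = 2.92)

#' Specification for a synthetic succinylation dataset
#'
#' Describes the generative model: background sequences with lysines as
#' candidate sites, a fraction of which are labelled positive; flanking
#' residues of positive sites are rewritten towards a charged-residue motif
#' (E/R/D at offsets -5..-1 and +1..+5 by default, mirroring the enrichment
#' of charged residues observed around real succinylation sites) with
#' probability `effect_size` per motif position. Planting never creates or
#' destroys a lysine: K is excluded from the motif alphabet (a planted K
#' would be a new candidate site whose window near-duplicates the positive
#' signal under a negative label) and existing lysines are never
#' overwritten, so the candidate-site set is determined by the background
#' draw alone. `effect_size = 0` is the null model: labels carry no signal.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Min/max protein length (uniform).
#' @param positive_fraction Probability a lysine is a positive site. The
#'   default 0.30 leaves enough negatives for the 1:2 positive:negative
#'   training assembly to subsample rather than exhaust them.
#' @param effect_size Motif strength in [0, 1].
#' @param motif_offsets Window offsets (relative to the site) carrying the
#'   motif.
#' @param motif_residues Residues enriched at motif offsets.
#' @param background "uniform" or "swissprot" residue composition.
#' @param seed Integer seed; generation is fully reproducible.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 100, length_range = c(150, 250),
                           positive_fraction = 0.30, effect_size = 1,
                           motif_offsets = c(-5:-1, 1:5),
                           motif_residues = c("E", "R", "D"),
                           background = c("uniform", "swissprot"),
                           seed = 1) {
  background <- match.arg(background)
  stopifnot(effect_size >= 0, effect_size <= 1,
            positive_fraction > 0, positive_fraction < 1,
            length_range[1] >= WINDOW_SIZE / 2)
  structure(list(n_proteins = n_proteins, length_range = length_range,
                 positive_fraction = positive_fraction,
                 effect_size = effect_size, motif_offsets = motif_offsets,
                 motif_residues = motif_residues, background = background,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset
#'
#' @param spec A `synthetic_spec`.
#' @return List: `proteins` (named character vector), `sites` (data.frame
#'   protein_id/position/label), `profiles` (named list of pseudo
#'   `pssm_profile`s), `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  freq <- if (spec$background == "swissprot")
    SWISSPROT_FREQ[AA_ALPHABET] / sum(SWISSPROT_FREQ) else
      stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  out <- with_seed(spec$seed, {
    proteins <- character(spec$n_proteins)
    names(proteins) <- sprintf("SYN%04d", seq_len(spec$n_proteins))
    site_rows <- list()
    for (i in seq_len(spec$n_proteins)) {
      L <- sample(spec$length_range[1]:spec$length_range[2], 1L)
      sv <- sample(AA_ALPHABET, L, replace = TRUE, prob = freq)
      lys <- which(sv == "K")
      pos_sites <- lys[stats::runif(length(lys)) < spec$positive_fraction]
      # plant the motif around positive sites; lysines are never
      # overwritten, so the candidate-site set is fixed by the background
      for (p in pos_sites) {
        for (off in spec$motif_offsets) {
          q <- p + off
          if (q >= 1L && q <= L && sv[q] != "K" &&
              stats::runif(1) < spec$effect_size)
            sv[q] <- sample(spec$motif_residues, 1L)
        }
      }
      proteins[i] <- paste(sv, collapse = "")
      neg_sites <- setdiff(lys, pos_sites)
      if (length(pos_sites) || length(neg_sites))
        site_rows[[i]] <- data.frame(
          protein_id = names(proteins)[i],
          position = c(pos_sites, neg_sites),
          label = rep(c("positive", "negative"),
                      c(length(pos_sites), length(neg_sites))),
          stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, site_rows)
    if (is.null(sites) || !any(sites$label == "positive"))
      stop("infeasible spec: no positive lysine sites were generated")
    rownames(sites) <- NULL
    list(proteins = proteins, sites = sites)
  })
  profiles <- lapply(names(out$proteins),
                     function(id) pseudo_profile(out$proteins[[id]], id))
  names(profiles) <- names(out$proteins)
  list(proteins = out$proteins, sites = out$sites, profiles = profiles,
       spec = spec)
}

#' Simulate channel scores from known fusion coefficients
#'
#' Draws five uniform channel scores per sample and labels each sample
#' from the logistic model `P = plogis(sum beta_n S_n + alpha)`. Used for
#' fusion parameter-recovery checks.
#'
#' @param beta Length-5 coefficient vector (channel order AAC, AAindex,
#'   BE, PSSM, pCKSAAP).
#' @param alpha Intercept.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return List: `scores` (n x 5 matrix), `labels`
#'   ("positive"/"negative"), `prob` (generating probabilities).
#' @export
generate_channel_scores <- function(beta, alpha = 0, n = 2000, seed = 1) {
  stopifnot(length(beta) == 5L)
  with_seed(seed, {
    s <- matrix(stats::runif(n * 5L), ncol = 5L,
                dimnames = list(NULL, CHANNEL_ORDER))
    p <- as.numeric(stats::plogis(s %*% beta + alpha))
    y <- ifelse(stats::runif(n) < p, "positive", "negative")
    list(scores = s, labels = y, prob = p)
  })
}
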