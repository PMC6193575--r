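# Wilcoxon rank-sum feature screening.
#
# The test statistic W is the sum of the (mid-)ranks of the positive group
# in the pooled sample. The exact null distribution is computed by dynamic
# programming over all C(r+s, r) equally likely rank assignments (ties
# handled by enumerating the mid-rank multiset), so exact p-values are
# available for tied data where the classical no-ties tables do not apply.
# For larger groups a normal approximation with tie correction and
# continuity correction is used.

# Exact null distribution of the scaled rank-sum by subset-sum counting.
# ranks2: integer vector (2 * mid-ranks); r: positive-group size.
# Returns function(w2) -> c(P_lower, P_upper) for scaled statistic w2.
exact_ranksum_tail <- function(ranks2, r) {
  n <- length(ranks2)
  S <- sum(ranks2)
  # f[j + 1, s + 1] = number of j-subsets with scaled sum s
  f <- matrix(0, nrow = r + 1L, ncol = S + 1L)
  f[1L, 1L] <- 1
  for (t in ranks2) {
    jmax <- min(r, n)  # rows updated top-down, descending j
    for (j in seq(jmax, 1L)) {
      if (t < S + 1L)
        f[j + 1L, (t + 1L):(S + 1L)] <-
          f[j + 1L, (t + 1L):(S + 1L)] + f[j, 1L:(S - t + 1L)]
    }
  }
  counts <- f[r + 1L, ]
  total <- sum(counts)
  cum <- cumsum(counts)
  function(w2) {
    i <- min(max(1L, floor(w2 + 1e-9) + 1L), S + 1L)
    p_lower <- cum[i] / total
    j <- min(max(1L, ceiling(w2 - 1e-9) + 1L), S + 1L)
    p_upper <- (total - if (j > 1L) cum[j - 1L] else 0) / total
    c(lower = p_lower, upper = p_upper)
  }
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Mid-ranks are used for ties. With `method = "auto"`, the exact null
#' distribution is used whenever `choose(r + s, r) <= 2e5`, otherwise a
#' normal approximation with tie and continuity corrections. The two-sided
#' p-value is `min(1, 2 * min(P_lower, P_upper))` where the one-sided tails
#' are inclusive of the observed rank-sum.
#'
#' @param pos_values Numeric values of the positive group (size r >= 1).
#' @param neg_values Numeric values of the negative group (size s >= 1).
#' @param method "auto", "exact" or "normal". "exact" works at any size via
#'   dynamic programming over the rank-sum distribution.
#' @return List of class `wr_test`: `W` (positive-group rank-sum), `r`, `s`,
#'   `p_value` (two-sided), `p_lower`, `p_upper`, `method`.
#' @export
wilcoxon_rank_sum <- function(pos_values, neg_values,
                              method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  r <- length(pos_values); s <- length(neg_values)
  if (r < 1L || s < 1L) stop("both groups must be non-empty")
  pooled <- c(pos_values, neg_values)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(r)])
  n <- r + s
  if (method == "auto")
    method <- if (choose(n, r) <= 2e5) "exact" else "normal"
  if (method == "exact") {
    tail_fn <- exact_ranksum_tail(as.integer(round(2 * rk)), r)
    tails <- tail_fn(2 * W)
  } else {
    mu <- r * (n + 1) / 2
    ties <- table(pooled)
    v <- r * s / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (v <= 0) {
      tails <- c(lower = 1, upper = 1)
    } else {
      sd <- sqrt(v)
      tails <- c(lower = stats::pnorm((W + 0.5 - mu) / sd),
                 upper = stats::pnorm((W - 0.5 - mu) / sd,
                                      lower.tail = FALSE))
    }
  }
  structure(list(W = W, r = r, s = s,
                 p_value = min(1, 2 * min(tails)),
                 p_lower = unname(tails["lower"]),
                 p_upper = unname(tails["upper"]),
                 method = method),
            class = "wr_test")
}

#' @export
print.wr_test <- function(x, ...) {
  cat("Wilcoxon rank-sum: W =", x$W, " (r =", x$r, ", s =", x$s,
      "), two-sided p =", signif(x$p_value, 4), "[", x$method, "]\n")
  invisible(x)
}

#' Rank every feature column by Wilcoxon rank-sum p-value
#'
#' Applies [wilcoxon_rank_sum()] to each column of a feature matrix,
#' positive rows vs negative rows, and orders features from most to least
#' discriminative (ascending p, ties broken by original column index).
#' Constant columns get p = 1 and sort last.
#'
#' @param features Numeric matrix with named columns (a `gpsuc_features`
#'   object keeps its per-column encoding in the result).
#' @param labels Character vector "positive"/"negative" per row, or `NULL`
#'   to use the matrix's own `meta` labels.
#' @param method Passed to [wilcoxon_rank_sum()].
#' @return data.frame with columns `feature`, `encoding`, `column`
#'   (original index), `W`, `p_value`, `method`, sorted ascending by p.
#' @export
rank_features <- function(features, labels = NULL,
                          method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (is.null(labels)) labels <- attr(features, "meta")$label
  stopifnot(length(labels) == nrow(features))
  pos <- labels == "positive"
  if (!any(pos) || all(pos)) stop("need at least one row of each class")
  enc <- attr(features, "encoding")
  if (is.null(enc)) enc <- rep(NA_character_, ncol(features))
  x <- unclass(features)
  res_p <- numeric(ncol(x)); res_W <- numeric(ncol(x))
  res_m <- character(ncol(x))
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    if (all(col == col[1])) {          # constant column: uninformative
      res_p[j] <- 1
      res_W[j] <- sum(rank(col)[pos])
      res_m[j] <- "constant"
    } else {
      wr <- wilcoxon_rank_sum(col[pos], col[!pos], method)
      res_p[j] <- wr$p_value; res_W[j] <- wr$W; res_m[j] <- wr$method
    }
  }
  out <- data.frame(feature = colnames(x), encoding = enc,
                    column = seq_len(ncol(x)), W = res_W,
                    p_value = res_p, method = res_m,
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$column), , drop = FALSE]
}

#' Build a per-encoding feature-selection plan
#'
#' Retains the `top_n` best-ranked features of each encoding named in
#' `top_n` and every feature of the remaining encodings, each block ordered
#' from most to least discriminative. The shipped defaults reduce pCKSAAP
#' to 390 and AAindex to 250 features (the generic preset); see
#' [top_n_preset()] for the nine species-specific presets.
#'
#' @param rankings data.frame from [rank_features()] (must carry `encoding`).
#' @param top_n Named integer vector, e.g. `c(pCKSAAP = 390, AAindex = 250)`.
#' @return A `selection_plan`: per-encoding list of retained feature names,
#'   p-values and the top_n applied.
#' @export
build_selection_plan <- function(rankings,
                                 top_n = c(pCKSAAP = 390, AAindex = 250)) {
  stopifnot(!anyNA(rankings$encoding))
  encodings <- intersect(ENCODING_ORDER, unique(rankings$encoding))
  plan <- list()
  for (enc in encodings) {
    sub <- rankings[rankings$encoding == enc, , drop = FALSE]
    keep <- if (enc %in% names(top_n)) {
      n <- as.integer(top_n[[enc]])
      if (n > nrow(sub))
        stop("top_n = ", n, " exceeds the ", nrow(sub),
             " available ", enc, " features")
      n
    } else nrow(sub)
    plan[[enc]] <- list(top_n = keep,
                        features = sub$feature[seq_len(keep)],
                        p_values = sub$p_value[seq_len(keep)])
  }
  structure(list(encodings = plan,
                 n_features = sum(vapply(plan, function(e) e$top_n, 0L))),
            class = "selection_plan")
}

#' @export
print.selection_plan <- function(x, ...) {
  cat("Selection plan:", x$n_features, "features retained\n")
  for (enc in names(x$encodings))
    cat("  ", enc, ": ", x$encodings[[enc]]$top_n, "\n", sep = "")
  invisible(x)
}

#' Apply a selection plan to a feature matrix
#'
#' Restricts and reorders columns per the plan; row order is unchanged.
#'
#' @param features A `gpsuc_features` matrix containing every planned column.
#' @param plan A `selection_plan`.
#' @return Reduced `gpsuc_features` matrix.
#' @export
apply_selection <- function(features, plan) {
  cols <- unlist(lapply(plan$encodings, function(e) e$features),
                 use.names = FALSE)
  features_subset(features, cols)
}

#' Serialize / read a selection plan as JSON
#' @param plan A `selection_plan`.
#' @param path Output path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(plan$encodings, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  enc <- lapply(enc, function(e)
    list(top_n = as.integer(e$top_n), features = as.character(e$features),
         p_values = as.numeric(e$p_values)))
  structure(list(encodings = enc,
                 n_features = sum(vapply(enc, function(e) e$top_n, 0L))),
            class = "selection_plan")
}

#' Per-encoding top-N presets
#'
#' Retained-feature counts for the AAindex and pCKSAAP blocks, for the
#' generic model and the nine species-specific models.
#'
#' @param species One of "generic", "h_sapiens", "h_capsulatum",
#'   "m_musculus", "e_coli", "m_tuberculosis", "s_cerevisiae", "t_gondii",
#'   "s_lycopersicum", "t_aestivum".
#' @return Named integer vector `c(AAindex = ..., pCKSAAP = ...)`.
#' @export
top_n_preset <- function(species = "generic") {
  presets <- list(
    generic        = c(AAindex = 250L, pCKSAAP = 390L),
    h_sapiens      = c(AAindex = 260L, pCKSAAP = 440L),
    h_capsulatum   = c(AAindex = 200L, pCKSAAP = 340L),
    m_musculus     = c(AAindex = 150L, pCKSAAP = 390L),
    e_coli         = c(AAindex = 200L, pCKSAAP = 350L),
    m_tuberculosis = c(AAindex = 240L, pCKSAAP = 350L),
    s_cerevisiae   = c(AAindex = 220L, pCKSAAP = 450L),
    t_gondii       = c(AAindex = 150L, pCKSAAP = 290L),
    s_lycopersicum = c(AAindex = 250L, pCKSAAP = 450L),
    t_aestivum     = c(AAindex = 120L, pCKSAAP = 400L))
  if (!species %in% names(presets))
    stop("unknown species preset '", species, "'")
  presets[[species]]
}
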