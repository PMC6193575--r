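# Per-encoding random-forest channels, logistic-regression score fusion,
# full-model training, prediction and persistence.

MODEL_FORMAT_VERSION <- "1"

label_factor <- function(labels) {
  factor(labels, levels = c("negative", "positive"))
}

#' Train one random-forest channel on a single encoding block
#'
#' Fits a probability forest (default 500 trees, sqrt(p) candidate features
#' per split) on the columns of one encoding. The channel score of a window
#' is the fraction of trees voting for the positive class.
#'
#' @param x Numeric matrix: rows = windows, columns = the encoding's
#'   (selected) features.
#' @param labels "positive"/"negative" per row.
#' @param encoding Block name stored with the model.
#' @param num_trees Number of trees.
#' @param seed Integer seed; fixed seed + single thread give bitwise
#'   reproducible forests.
#' @return A `gpsuc_channel` object.
#' @export
train_channel <- function(x, labels, encoding = "unknown",
                          num_trees = 500, seed = 1) {
  y <- label_factor(labels)
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class")
  forest <- ranger::ranger(x = unclass(x), y = y, probability = TRUE,
                           num.trees = num_trees, seed = seed,
                           num.threads = 1)
  structure(list(encoding = encoding, forest = forest,
                 n_trees = num_trees, seed = seed,
                 features = colnames(x)),
            class = "gpsuc_channel")
}

#' Score windows with a trained channel
#' @param channel A `gpsuc_channel`.
#' @param x Matrix containing (at least) the channel's feature columns.
#' @return Numeric vector in [0, 1]: positive-class vote fraction per row.
#' @export
score_channel <- function(channel, x) {
  x <- unclass(x)[, channel$features, drop = FALSE]
  stats::predict(channel$forest, data = x,
                 num.threads = 1)$predictions[, "positive"]
}

# Out-of-bag positive-class scores of the channel's own training rows.
oob_scores <- function(channel) channel$forest$predictions[, "positive"]

#' Stratified fold assignment
#' @param labels Class labels per row.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
make_folds <- function(labels, k = 10, seed = 1) {
  fold <- integer(length(labels))
  with_seed(seed, for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class '", cl, "' has fewer samples (", length(idx),
           ") than folds (", k, ")")
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  })
  fold
}

#' Out-of-fold channel scores
#'
#' Stratified k-fold loop in which each fold's windows are scored by
#' channels trained only on the other folds; the selection plan is rebuilt
#' inside each training fold so held-out labels never influence feature
#' selection.
#'
#' @param features Full `gpsuc_features` matrix.
#' @param labels "positive"/"negative" per row (default: the matrix meta).
#' @param folds Number of folds.
#' @param seed Integer seed (fold assignment and forests).
#' @param top_n Per-encoding retention passed to [build_selection_plan()].
#' @param num_trees Trees per channel.
#' @return List: `scores` (n x 5 matrix, columns in AAC, AAindex, BE, PSSM,
#'   pCKSAAP order), `fold` (assignment vector).
#' @export
out_of_fold_scores <- function(features, labels = NULL, folds = 10, seed = 1,
                               top_n = c(pCKSAAP = 390, AAindex = 250),
                               num_trees = 500) {
  if (is.null(labels)) labels <- attr(features, "meta")$label
  fold <- make_folds(labels, folds, seed)
  scores <- matrix(NA_real_, nrow = nrow(features), ncol = 5L,
                   dimnames = list(NULL, CHANNEL_ORDER))
  for (f in seq_len(folds)) {
    tr <- fold != f
    tr_feat <- features_subset(features, seq_len(ncol(features)), which(tr))
    plan <- build_selection_plan(rank_features(tr_feat, labels[tr]), top_n)
    for (enc in names(plan$encodings)) {
      cols <- plan$encodings[[enc]]$features
      ch <- train_channel(features_subset(features, cols, which(tr)),
                          labels[tr], enc, num_trees, seed + f)
      scores[!tr, enc] <- score_channel(ch,
                                        features_subset(features, cols,
                                                        which(!tr)))
    }
  }
  list(scores = scores, fold = fold)
}

#' Fit the logistic-regression fusion of five channel scores
#'
#' Maximum-likelihood logistic regression of the class label on the five
#' channel scores: `log(P / (1 - P)) = sum_n beta_n S_n + alpha`. By
#' default the intercept alpha is fixed at zero. Under (near-)perfect
#' separation the ML fit diverges; a mild ridge penalty is applied instead
#' and a warning emitted.
#'
#' @param scores n x 5 matrix of channel scores, columns named as in
#'   `CHANNEL_ORDER`.
#' @param labels "positive"/"negative" per row.
#' @param fix_alpha_zero Clamp the intercept to 0 (default TRUE).
#' @return A `fusion_model`: `beta` (named length-5), `alpha`, `cutoff`
#'   (initialised to 0.5; see [choose_cutoff()]).
#' @export
fit_fusion <- function(scores, labels, fix_alpha_zero = TRUE) {
  stopifnot(ncol(scores) == 5L)
  scores <- scores[, CHANNEL_ORDER, drop = FALSE]
  y <- as.integer(labels == "positive")
  df <- as.data.frame(scores)
  names(df) <- paste0("S", 1:5)
  form <- if (fix_alpha_zero) y ~ 0 + S1 + S2 + S3 + S4 + S5
          else y ~ S1 + S2 + S3 + S4 + S5
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = cbind(y = y, df), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # channel scores live in [0, 1]; coefficients far outside the plausible
  # odds range signal (near-)separation or collinearity degeneracy
  if (sep || any(abs(stats::coef(fit)) > 25)) {
    warning("(near-)separation in fusion fit; applying a mild ridge penalty")
    # the channels all score the same orientation, so negative fusion
    # weights are non-identifiable collinearity artifacts; constrain >= 0
    # as in stacked-model fitting
    gfit <- glmnet::glmnet(as.matrix(df), y, family = "binomial",
                           alpha = 0, lambda = 1e-2, lower.limits = 0,
                           intercept = !fix_alpha_zero)
    beta <- as.numeric(gfit$beta)
    alpha <- if (fix_alpha_zero) 0 else as.numeric(gfit$a0)
  } else {
    co <- stats::coef(fit)
    if (fix_alpha_zero) {
      beta <- unname(co); alpha <- 0
    } else {
      beta <- unname(co[-1]); alpha <- unname(co[1])
    }
  }
  names(beta) <- CHANNEL_ORDER
  structure(list(beta = beta, alpha = alpha, cutoff = 0.5,
                 fix_alpha_zero = fix_alpha_zero),
            class = "fusion_model")
}

#' Fuse channel scores into a probability
#'
#' Applies `P = 1 / (1 + exp(-(sum beta_n S_n + alpha)))`.
#'
#' @param fusion A `fusion_model` (fitted or preset).
#' @param scores n x 5 matrix of channel scores (columns matched by name
#'   when named, positional otherwise).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
fusion_predict <- function(fusion, scores) {
  scores <- as.matrix(scores)
  if (!is.null(colnames(scores)))
    scores <- scores[, CHANNEL_ORDER, drop = FALSE]
  as.numeric(stats::plogis(scores %*% fusion$beta + fusion$alpha))
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("LR fusion: logit(P) =",
      paste(sprintf("%.3f*%s", x$beta, names(x$beta)), collapse = " + "),
      sprintf("+ %.3f", x$alpha), "\n  cutoff:", x$cutoff, "\n")
  invisible(x)
}

#' Published per-species fusion coefficient presets
#'
#' Logistic-regression coefficients (channel order AAC, AAindex, BE, PSSM,
#' pCKSAAP; intercept 0) published for eight species-specific models. No
#' complete coefficient set was published for `m_musculus` (only four of
#' the five values appear in print), so requesting it is an error.
#'
#' @param species Species key, e.g. "h_sapiens".
#' @param cutoff Decision threshold stored with the preset.
#' @return A `fusion_model`.
#' @export
fusion_preset <- function(species = "h_sapiens", cutoff = 0.5) {
  presets <- list(
    h_sapiens      = c(0.142, 1.566, 0.665, 0.342, 0.667),
    h_capsulatum   = c(0.102, 0.466, 0.462, 0.242, 1.367),
    e_coli         = c(0.121, 0.473, 0.763, 0.230, 1.214),
    m_tuberculosis = c(0.127, 0.358, 0.404, 0.109, 1.066),
    s_cerevisiae   = c(0.320, 0.391, 0.553, 0.182, 1.122),
    t_gondii       = c(0.117, 0.331, 0.734, 0.139, 1.014),
    s_lycopersicum = c(0.113, 0.417, 0.818, 0.103, 1.172),
    t_aestivum     = c(0.112, 0.462, 0.723, 0.164, 1.299))
  if (species == "m_musculus")
    stop("no complete published coefficient set exists for m_musculus ",
         "(only four of five values appear in print); fit your own fusion")
  if (!species %in% names(presets))
    stop("unknown fusion preset '", species, "'")
  beta <- presets[[species]]
  names(beta) <- CHANNEL_ORDER
  structure(list(beta = beta, alpha = 0, cutoff = cutoff,
                 fix_alpha_zero = TRUE),
            class = "fusion_model")
}

#' Choose a decision cutoff on fused scores
#'
#' Mode "specificity" returns the smallest cutoff whose specificity on the
#' supplied scores reaches `target` (default 0.90); the returned value is
#' the midpoint between that score and the next lower observed score, so a
#' cleanly separated score set yields the midpoint of the gap. Mode "fixed"
#' returns `value` unchanged.
#'
#' @param scores Fused probabilities.
#' @param labels "positive"/"negative" per score.
#' @param mode "specificity" or "fixed".
#' @param target Specificity target for mode "specificity".
#' @param value Cutoff for mode "fixed".
#' @return Cutoff in (0, 1).
#' @export
choose_cutoff <- function(scores, labels, mode = c("specificity", "fixed"),
                          target = 0.90, value = 0.5) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(value)
  if (target > 1) stop("specificity target ", target, " is unreachable")
  neg <- scores[labels == "negative"]
  if (length(neg) == 0L) stop("no negative samples to estimate specificity")
  cand <- sort(unique(scores))
  sp <- vapply(cand, function(ct) mean(neg < ct), 0)  # calls are score >= ct
  i <- which(sp >= target)[1]
  if (is.na(i)) {
    hi <- max(scores)
    return(min((hi + 1) / 2, 1 - 1e-9))  # call everything negative
  }
  lo <- if (i == 1L) 0 else cand[i - 1L]
  (lo + cand[i]) / 2
}

#' Train the full five-channel predictor
#'
#' Runs the complete training workflow on an encoded dataset: Wilcoxon
#' feature selection, one random-forest channel per encoding, logistic
#' fusion of the five channel scores, and cutoff selection. Fusion is
#' fitted on validation-style channel scores, never on resubstitution
#' scores: `fusion_scores = "oof"` (default) uses stratified out-of-fold
#' scores with selection rebuilt per fold; `"oob"` uses the forests'
#' out-of-bag votes (cheaper, no extra fits).
#'
#' @param features `gpsuc_features` matrix with labelled meta.
#' @param top_n Per-encoding retention (see [top_n_preset()]).
#' @param num_trees Trees per channel.
#' @param folds Folds used for out-of-fold fusion scores.
#' @param seed Integer seed.
#' @param fix_alpha_zero Clamp the fusion intercept at 0.
#' @param fusion_scores "oof" or "oob".
#' @param cutoff_mode,cutoff_target,cutoff_value Passed to [choose_cutoff()].
#' @param table Property matrix the features were encoded with (stored for
#'   prediction).
#' @return A `gpsuc_model`.
#' @export
train_model <- function(features,
                        top_n = c(pCKSAAP = 390, AAindex = 250),
                        num_trees = 500, folds = 10, seed = 1,
                        fix_alpha_zero = TRUE,
                        fusion_scores = c("oof", "oob"),
                        cutoff_mode = "specificity", cutoff_target = 0.90,
                        cutoff_value = 0.5,
                        table = load_aaindex_table()) {
  fusion_scores <- match.arg(fusion_scores)
  labels <- attr(features, "meta")$label
  plan <- build_selection_plan(rank_features(features, labels), top_n)
  channels <- list()
  for (enc in names(plan$encodings)) {
    cols <- plan$encodings[[enc]]$features
    channels[[enc]] <- train_channel(features_subset(features, cols),
                                     labels, enc, num_trees, seed)
  }
  val <- if (fusion_scores == "oof") {
    out_of_fold_scores(features, labels, folds, seed, top_n,
                       num_trees)$scores
  } else {
    s <- vapply(channels[CHANNEL_ORDER], oob_scores,
                numeric(nrow(features)))
    colnames(s) <- CHANNEL_ORDER
    s
  }
  fusion <- fit_fusion(val, labels, fix_alpha_zero)
  fusion$cutoff <- choose_cutoff(fusion_predict(fusion, val), labels,
                                 cutoff_mode, cutoff_target, cutoff_value)
  manifest <- list(format = MODEL_FORMAT_VERSION,
                   package_version = as.character(
                     utils::packageVersion("gpsuc")),
                   alphabet = paste(AA_ALPHABET, collapse = ""),
                   window_size = WINDOW_SIZE,
                   num_trees = num_trees, seed = seed, folds = folds,
                   fusion_scores = fusion_scores,
                   n_windows = nrow(features),
                   n_positive = sum(labels == "positive"),
                   n_negative = sum(labels == "negative"))
  structure(list(plan = plan, channels = channels, fusion = fusion,
                 table = table, manifest = manifest),
            class = "gpsuc_model")
}

#' @export
print.gpsuc_model <- function(x, ...) {
  m <- x$manifest
  cat("Succinylation-site predictor:", m$n_windows, "training windows (",
      m$n_positive, "positive /", m$n_negative, "negative ),",
      m$num_trees, "trees per channel\n")
  print(x$plan); print(x$fusion)
  invisible(x)
}

#' Predict succinylation probability for candidate sites
#'
#' Encodes the supplied windows with the model's own property table and
#' selection plan, scores them with the five channels and fuses the scores.
#'
#' @param object A `gpsuc_model`.
#' @param windows data.frame from [extract_windows()].
#' @param profiles Named list of `pssm_profile` objects.
#' @param ... Unused.
#' @return data.frame: `protein_id`, `position`, `probability`, `call`
#'   (logical, probability >= cutoff), plus the five channel scores.
#' @export
predict.gpsuc_model <- function(object, windows, profiles, ...) {
  features <- encode_dataset(windows, profiles, object$table)
  scores <- matrix(NA_real_, nrow = nrow(features), ncol = 5L,
                   dimnames = list(NULL, CHANNEL_ORDER))
  for (enc in CHANNEL_ORDER)
    scores[, enc] <- score_channel(object$channels[[enc]], features)
  p <- fusion_predict(object$fusion, scores)
  cbind(data.frame(protein_id = windows$protein_id,
                   position = windows$position,
                   probability = p,
                   call = p >= object$fusion$cutoff,
                   stringsAsFactors = FALSE),
        as.data.frame(scores))
}

fusion_to_list <- function(f)
  list(beta = as.list(f$beta), alpha = f$alpha, cutoff = f$cutoff,
       fix_alpha_zero = f$fix_alpha_zero)

#' Save / load a trained model archive
#'
#' The archive is a directory holding `manifest.json`, `plan.json`,
#' `fusion.json`, the property table and one serialized forest per channel.
#' The manifest records md5 checksums of the JSON members and the package
#' version; [load_model()] validates both.
#'
#' @param model A `gpsuc_model`.
#' @param path Archive directory (created if needed).
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_plan(model$plan, file.path(path, "plan.json"))
  jsonlite::write_json(fusion_to_list(model$fusion),
                       file.path(path, "fusion.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(data.frame(aa = rownames(model$table), model$table,
                                check.names = FALSE),
                     file.path(path, "aaindex.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (enc in names(model$channels))
    saveRDS(model$channels[[enc]],
            file.path(path, paste0("channel_", enc, ".rds")))
  manifest <- model$manifest
  manifest$channels <- names(model$channels)
  manifest$md5 <- as.list(tools::md5sum(
    file.path(path, c("plan.json", "fusion.json"))))
  names(manifest$md5) <- c("plan.json", "fusion.json")
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a model archive (no manifest.json): ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.character(manifest$format), MODEL_FORMAT_VERSION))
    stop("model archive format '", manifest$format,
         "' not supported by this package version (expected ",
         MODEL_FORMAT_VERSION, ")")
  for (member in names(manifest$md5)) {
    got <- unname(tools::md5sum(file.path(path, member)))
    if (!identical(got, manifest$md5[[member]]))
      stop("checksum mismatch for ", member, " (corrupt archive?)")
  }
  channels <- list()
  for (enc in manifest$channels) {
    f <- file.path(path, paste0("channel_", enc, ".rds"))
    if (!file.exists(f)) stop("model archive missing channel: ", enc)
    channels[[enc]] <- readRDS(f)
  }
  if (!setequal(manifest$channels, ENCODING_ORDER))
    stop("model archive channel set incomplete: ",
         paste(manifest$channels, collapse = ", "))
  fj <- jsonlite::read_json(file.path(path, "fusion.json"),
                            simplifyVector = TRUE)
  fusion <- structure(list(beta = unlist(fj$beta)[CHANNEL_ORDER],
                           alpha = fj$alpha, cutoff = fj$cutoff,
                           fix_alpha_zero = fj$fix_alpha_zero),
                      class = "fusion_model")
  tab <- load_aaindex_table(file.path(path, "aaindex.tsv"))
  manifest$md5 <- NULL; manifest$channels <- NULL
  structure(list(plan = read_plan(file.path(path, "plan.json")),
                 channels = channels, fusion = fusion, table = tab,
                 manifest = manifest),
            class = "gpsuc_model")
}
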