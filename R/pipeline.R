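# High-level workflow commands: simulate, encode, train, predict, evaluate,
# analyze. These are the programmatic equivalents of the shipped `gpsuc`
# command-line script (inst/cli/gpsuc) and each writes a JSON manifest
# (configuration, package version, input checksums) next to its output.

write_manifest <- function(out_path, command, config, inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(command = command,
                   package = "gpsuc",
                   package_version = as.character(
                     utils::packageVersion("gpsuc")),
                   config = config,
                   input_md5 = as.list(tools::md5sum(inputs)))
  path <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a synthetic dataset to disk
#'
#' Writes `proteins.fasta`, `sites.tsv` and a `pssm/` directory of
#' pseudo-profiles under `out_dir`.
#'
#' @param out_dir Output directory (created).
#' @param ... Passed to [synthetic_spec()].
#' @return Invisibly, the generated dataset list.
#' @export
run_simulate <- function(out_dir, ...) {
  spec <- synthetic_spec(...)
  data <- generate_synthetic(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(data$proteins, file.path(out_dir, "proteins.fasta"))
  write_sites(data$sites, file.path(out_dir, "sites.tsv"))
  pd <- file.path(out_dir, "pssm")
  dir.create(pd, showWarnings = FALSE)
  for (id in names(data$profiles))
    write_pssm(data$profiles[[id]], file.path(pd, paste0(id, ".pssm")))
  write_manifest(file.path(out_dir, "dataset"), "simulate",
                 unclass(spec))
  invisible(data)
}

load_dataset <- function(fasta, sites, pssm_dir = NULL) {
  proteins <- read_fasta(fasta)
  site_df <- read_sites(sites, proteins)
  profiles <- load_profiles(proteins, pssm_dir)
  list(proteins = proteins, sites = site_df, profiles = profiles)
}

#' Encode a dataset to a feature TSV
#'
#' @param fasta,sites Paths to the FASTA and site-annotation TSV.
#' @param out Output feature TSV path.
#' @param pssm_dir Optional directory of `<id>.pssm` files; proteins
#'   without one get a pseudo-profile.
#' @param table_path Optional property-table TSV (default: packaged
#'   12-scale table).
#' @return Invisibly, the `gpsuc_features` matrix.
#' @export
run_encode <- function(fasta, sites, out, pssm_dir = NULL,
                       table_path = NULL) {
  d <- load_dataset(fasta, sites, pssm_dir)
  windows <- extract_windows(d$proteins, d$sites)
  features <- encode_dataset(windows, d$profiles,
                             load_aaindex_table(table_path))
  write_features(features, out)
  write_manifest(out, "encode",
                 list(fasta = fasta, sites = sites, pssm_dir = pssm_dir),
                 c(fasta, sites))
  invisible(features)
}

#' Train a predictor from FASTA + sites
#'
#' Assembles the training set at a 1:2 positive:negative ratio (all
#' positives kept, negatives subsampled), encodes it, trains the
#' five-channel model and saves the archive to `model_dir`. When
#' `cv = TRUE` a 10-fold cross-validated performance report is also
#' written (`cv_report.tsv`).
#'
#' @param fasta,sites,pssm_dir Input paths (see [run_encode()]).
#' @param model_dir Output model archive directory.
#' @param species Preset key for the per-encoding retention counts
#'   (default "generic": 250 AAindex + 390 pCKSAAP features).
#' @param seed Integer seed covering subsampling, folds and forests.
#' @param cv Also run and write a cross-validated report.
#' @param ... Passed to [train_model()].
#' @return Invisibly, the trained `gpsuc_model`.
#' @export
run_train <- function(fasta, sites, model_dir, pssm_dir = NULL,
                      species = "generic", top_n = top_n_preset(species),
                      seed = 1, cv = FALSE, ...) {
  d <- load_dataset(fasta, sites, pssm_dir)
  windows <- extract_windows(d$proteins, d$sites)
  training <- sample_training_set(windows, seed)
  features <- encode_dataset(training, d$profiles)
  model <- train_model(features, top_n = top_n, seed = seed, ...)
  save_model(model, model_dir)
  if (cv) {
    rep <- cross_validated_report(features, seed = seed, top_n = top_n, ...)
    utils::write.table(rep$per_fold, file.path(model_dir, "cv_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(file.path(model_dir, "model"), "train",
                 list(fasta = fasta, sites = sites, pssm_dir = pssm_dir,
                      species = species, seed = seed),
                 c(fasta, sites))
  invisible(model)
}

#' Predict succinylation sites for every lysine of the input proteins
#'
#' @param fasta Input FASTA path.
#' @param model_dir Model archive from [run_train()]/[save_model()].
#' @param out Output prediction TSV.
#' @param pssm_dir Optional PSSM directory.
#' @return Invisibly, the prediction data.frame (`protein_id`, `position`,
#'   `residue`, `probability`, `call`).
#' @export
run_predict <- function(fasta, model_dir, out, pssm_dir = NULL) {
  proteins <- read_fasta(fasta)
  model <- load_model(model_dir)
  profiles <- load_profiles(proteins, pssm_dir)
  rows <- list()
  for (id in names(proteins)) {
    pos <- enumerate_lysines(proteins[[id]])
    if (length(pos))
      rows[[id]] <- data.frame(protein_id = id, position = pos,
                               stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no lysine residues in the input proteins")
  sites <- do.call(rbind, rows)
  windows <- extract_windows(proteins, sites)
  pred <- predict(model, windows, profiles)
  pred <- cbind(pred[, c("protein_id", "position")],
                residue = "K",
                pred[, c("probability", "call", CHANNEL_ORDER)])
  utils::write.table(pred, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(out, "predict",
                 list(fasta = fasta, model_dir = model_dir,
                      pssm_dir = pssm_dir), fasta)
  invisible(pred)
}

#' Evaluate predictions against labelled sites
#'
#' Joins a prediction TSV with a labelled sites TSV and reports Ac, Sp,
#' Sn, MCC at the cutoff plus ROC AUC.
#'
#' @param predictions Prediction TSV from [run_predict()].
#' @param sites Labelled sites TSV.
#' @param out Output metrics JSON.
#' @param cutoff Decision threshold (default 0.5).
#' @return Invisibly, the metrics list.
#' @export
run_evaluate <- function(predictions, sites, out, cutoff = 0.5) {
  pred <- utils::read.delim(predictions)
  lab <- read_sites(sites)
  key <- function(d) paste(d$protein_id, d$position)
  idx <- match(key(lab), key(pred))
  if (anyNA(idx))
    stop("prediction file lacks ", sum(is.na(idx)), " labelled site(s)")
  scores <- pred$probability[idx]
  m <- metrics(confusion_at_cutoff(scores, lab$label, cutoff))
  roc <- roc_auc(scores, lab$label)
  report <- list(Ac = m$Ac, Sp = m$Sp, Sn = m$Sn, MCC = m$MCC,
                 auc = roc$auc, cutoff = cutoff, n = length(scores))
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_manifest(out, "evaluate",
                 list(predictions = predictions, sites = sites,
                      cutoff = cutoff), c(predictions, sites))
  invisible(report)
}

#' Compositional-bias analysis tables
#'
#' Writes positional AAF tables per group, their enrichment/depletion
#' difference, MPV and MPP summaries, and the positional significance
#' tests (Kruskal-Wallis on MPV and MPP inputs across all 41 positions;
#' chi-square on residue counts at positions -5..+5), all as TSV under
#' `out_dir`.
#'
#' @param fasta,sites,pssm_dir Input paths.
#' @param out_dir Output directory.
#' @param index_id Property scale for the MPP analysis.
#' @return Invisibly, a list of the computed tables.
#' @export
run_analyze <- function(fasta, sites, out_dir, pssm_dir = NULL,
                        index_id = "NAKH920108") {
  d <- load_dataset(fasta, sites, pssm_dir)
  windows <- extract_windows(d$proteins, d$sites)
  wp <- windows[windows$label == "positive", , drop = FALSE]
  wn <- windows[windows$label == "negative", , drop = FALSE]
  if (!nrow(wp) || !nrow(wn)) stop("need both positive and negative sites")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(
    aaf_positive = positional_aaf(wp),
    aaf_negative = positional_aaf(wn),
    enrichment = enrichment_depletion(wp, wn))
  mpv <- rbind(positive = mean_profile_value(wp, d$profiles),
               negative = mean_profile_value(wn, d$profiles))
  mpp <- rbind(positive = mean_property_value(wp, index_id),
               negative = mean_property_value(wn, index_id))
  tests <- list(
    mpv_test = positional_test(window_profile_values(wp, d$profiles),
                               window_profile_values(wn, d$profiles)),
    mpp_test = positional_test(window_property_values(wp, index_id),
                               window_property_values(wn, index_id)),
    chi_square = positional_test(wp, wn, test = "chi_square"))
  for (nm in names(tabs))
    write_positional_table(tabs[[nm]], file.path(out_dir,
                                                 paste0(nm, ".tsv")))
  write_positional_table(t(mpv), file.path(out_dir, "mpv.tsv"))
  write_positional_table(t(mpp), file.path(out_dir, "mpp.tsv"))
  for (nm in names(tests))
    write_positional_table(tests[[nm]], file.path(out_dir,
                                                  paste0(nm, ".tsv")))
  write_manifest(file.path(out_dir, "analyze"), "analyze",
                 list(fasta = fasta, sites = sites, pssm_dir = pssm_dir,
                      index_id = index_id), c(fasta, sites))
  invisible(c(tabs, list(mpv = mpv, mpp = mpp), tests))
}
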