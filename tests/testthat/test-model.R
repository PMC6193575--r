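test_that("a channel separates a strongly separable block and is seeded", {
  f <- separable_features(n_pos = 25, n_neg = 50, seed = 7)
  labels <- attr(f, "meta")$label
  enc <- attr(f, "encoding")
  block <- features_block <- unclass(f)[, enc == "BE"]
  ch <- train_channel(block, labels, "BE", num_trees = 200, seed = 1)
  s <- score_channel(ch, block)
  expect_gte(roc_auc(s, labels)$auc, 0.99)
  expect_true(all(s >= 0 & s <= 1))

  # determinism: same seed, same scores on a probe set
  ch2 <- train_channel(block, labels, "BE", num_trees = 200, seed = 1)
  expect_identical(score_channel(ch2, block), s)

  expect_error(train_channel(block, rep("positive", nrow(block))),
               "single class")
})

test_that("label-shuffled data scores near chance", {
  # one window per protein so shuffled labels cannot leak through
  # overlapping near-duplicate windows
  d <- generate_synthetic(synthetic_spec(n_proteins = 90, seed = 8))
  first <- d$sites[!duplicated(d$sites$protein_id), ]
  w <- extract_windows(d$proteins, first)
  f <- encode_dataset(w, d$profiles)
  set.seed(99)
  shuffled <- sample(rep(c("positive", "negative"), length.out = nrow(w)))
  enc <- attr(f, "encoding")
  block <- unclass(f)[, enc == "AAC"]
  oof <- rep(NA_real_, nrow(block))
  fold <- make_folds(shuffled, 5, seed = 2)
  for (k in 1:5) {
    ch <- train_channel(block[fold != k, ], shuffled[fold != k], "AAC",
                        num_trees = 200, seed = k)
    oof[fold == k] <- score_channel(ch, block[fold == k, , drop = FALSE])
  }
  expect_lt(abs(roc_auc(oof, shuffled)$auc - 0.5), 0.15)
})

test_that("stratified folds balance classes within one sample", {
  labels <- rep(c("positive", "negative"), c(33, 77))
  fold <- make_folds(labels, 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  pos_per_fold <- tapply(labels == "positive", fold, sum)
  expect_lte(diff(range(pos_per_fold)), 1)
  neg_per_fold <- tapply(labels == "negative", fold, sum)
  expect_lte(diff(range(neg_per_fold)), 1)
  expect_error(make_folds(rep(c("positive", "negative"), c(5, 50)), 10),
               "fewer samples")
})

test_that("out-of-fold scores cover every sample once per channel", {
  f <- separable_features(n_pos = 15, n_neg = 30, seed = 9)
  oof <- out_of_fold_scores(f, folds = 3, seed = 1,
                            top_n = c(pCKSAAP = 50, AAindex = 30),
                            num_trees = 100)
  expect_equal(dim(oof$scores), c(45L, 5L))
  expect_false(anyNA(oof$scores))
  expect_equal(colnames(oof$scores),
               c("AAC", "AAindex", "BE", "PSSM", "pCKSAAP"))
  expect_true(all(oof$scores >= 0 & oof$scores <= 1))
})

test_that("fusion arithmetic follows the logistic model exactly", {
  zero <- structure(list(beta = setNames(rep(0, 5),
                                         c("AAC", "AAindex", "BE", "PSSM",
                                           "pCKSAAP")),
                         alpha = 0, cutoff = 0.5, fix_alpha_zero = TRUE),
                    class = "fusion_model")
  s <- matrix(runif(10 * 5), 10, 5)
  expect_equal(fusion_predict(zero, s), rep(0.5, 10))

  hs <- fusion_preset("h_sapiens")
  expect_equal(unname(hs$beta), c(0.142, 1.566, 0.665, 0.342, 0.667))
  expect_equal(hs$alpha, 0)
  ones <- matrix(1, 1, 5)
  expect_equal(fusion_predict(hs, ones), 1 / (1 + exp(-3.382)))

  expect_error(fusion_preset("m_musculus"), "no complete published")
  expect_error(fusion_preset("x_files"), "unknown")
})

test_that("fusion fitting recovers planted coefficients within 2 SE", {
  beta <- fusion_preset("h_sapiens")$beta
  sim <- generate_channel_scores(beta, alpha = 0, n = 2000, seed = 42)
  fit <- fit_fusion(sim$scores, sim$labels, fix_alpha_zero = TRUE)
  # standard errors from the ML fit
  y <- as.integer(sim$labels == "positive")
  df <- as.data.frame(sim$scores); names(df) <- paste0("S", 1:5)
  ref <- glm(y ~ 0 + ., data = cbind(y = y, df), family = binomial())
  se <- summary(ref)$coefficients[, "Std. Error"]
  expect_true(all(abs(fit$beta - beta) <= 2 * se))
})

test_that("monotonicity: with nonneg coefficients P never decreases", {
  hs <- fusion_preset("h_sapiens")
  s <- matrix(runif(5), 1, 5)
  p0 <- fusion_predict(hs, s)
  for (j in 1:5) {
    s2 <- s; s2[j] <- s2[j] + 0.2
    expect_gte(fusion_predict(hs, s2), p0)
  }
})

test_that("near-separated fusion falls back to a penalised fit", {
  set.seed(4)
  y <- rep(c("positive", "negative"), each = 50)
  s <- matrix(runif(100 * 5), 100, 5,
              dimnames = list(NULL, c("AAC", "AAindex", "BE", "PSSM",
                                      "pCKSAAP")))
  s[y == "positive", 1] <- s[y == "positive", 1] + 10
  expect_warning(fit <- fit_fusion(s, y), "ridge")
  expect_true(all(is.finite(fit$beta)))
})

test_that("cutoff selection reaches the specificity target", {
  set.seed(6)
  labels <- rep(c("positive", "negative"), each = 100)
  scores <- c(runif(100, 0.4, 1), runif(100, 0, 0.6))
  ct <- choose_cutoff(scores, labels, mode = "specificity", target = 0.90)
  cm <- confusion_at_cutoff(scores, labels, ct)
  expect_gte(metrics(cm)$Sp, 0.90)
  # smallest such cutoff: nudging down violates the target
  below <- max(scores[scores < ct])
  expect_lt(metrics(confusion_at_cutoff(scores, labels, below))$Sp, 0.90)

  # separated scores: midpoint of the gap
  sep_scores <- c(rep(0.9, 5), rep(0.1, 10))
  sep_labels <- rep(c("positive", "negative"), c(5, 10))
  expect_equal(choose_cutoff(sep_scores, sep_labels, "specificity"), 0.5)

  expect_equal(choose_cutoff(scores, labels, mode = "fixed", value = 0.5),
               0.5)
  expect_error(choose_cutoff(scores, labels, target = 1.5), "unreachable")
})

test_that("the full model trains, predicts and round-trips to disk", {
  d <- generate_synthetic(synthetic_spec(n_proteins = 30, seed = 11))
  w <- extract_windows(d$proteins, d$sites)
  tr <- sample_training_set(w, seed = 1)
  f <- encode_dataset(tr, d$profiles)
  model <- train_model(f, top_n = c(pCKSAAP = 80, AAindex = 50),
                       num_trees = 100, folds = 3, seed = 1,
                       fusion_scores = "oob")
  pred <- predict(model, tr, d$profiles)
  expect_true(all(pred$probability > 0 & pred$probability < 1))
  # separable training data: resubstitution calls are nearly all correct
  acc <- mean(pred$call == (tr$label == "positive"))
  expect_gte(acc, 0.95)

  dir <- tempfile("model")
  save_model(model, dir)
  back <- load_model(dir)
  pred2 <- predict(back, tr, d$profiles)
  expect_equal(pred2$probability, pred$probability)
  expect_equal(back$fusion$beta, model$fusion$beta)

  # corrupting a JSON member breaks the checksum
  fj <- file.path(dir, "fusion.json")
  writeLines(sub("}$", " }", readLines(fj)), fj)
  expect_error(load_model(dir), "checksum")

  # missing channel is detected
  dir2 <- tempfile("model")
  save_model(model, dir2)
  unlink(file.path(dir2, "channel_PSSM.rds"))
  expect_error(load_model(dir2), "missing channel")

  # foreign-format manifest is rejected
  mf <- file.path(dir2, "manifest.json")
  j <- jsonlite::read_json(mf)
  j$format <- "99"
  jsonlite::write_json(j, mf, auto_unbox = TRUE)
  expect_error(load_model(dir2), "format")
})
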