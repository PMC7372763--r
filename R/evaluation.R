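# Evaluation: confusion counts, the five classification metrics, the
# repeated-split protocol, the coverage-robustness sweep and the
# signed-versus-unsigned ablation.

#' Confusion counts from binary label vectors
#' @param truth,predicted 0/1 vectors of equal length.
#' @return list with TP, TN, FP, FN.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  stopifnot(all(truth %in% 0:1), all(predicted %in% 0:1))
  list(TP = sum(truth == 1 & predicted == 1),
       TN = sum(truth == 0 & predicted == 0),
       FP = sum(truth == 0 & predicted == 1),
       FN = sum(truth == 1 & predicted == 0))
}

#' Accuracy, sensitivity, specificity, precision and F-score
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); Sensitivity = TP/(TP+FN);
#' Specificity = TN/(TN+FP); Precision = TP/(TP+FP);
#' F-score = 2 Precision Sensitivity / (Precision + Sensitivity).
#' A metric with a zero denominator is reported as NA and flagged in the
#' `undefined` field rather than coerced to 0.
#'
#' @param cc confusion counts from [confusion()].
#' @return list with the five metrics, `n`, and `undefined` (character
#'   vector naming any undefined metrics).
#' @export
ppi_metrics <- function(cc) {
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  if (n == 0) stop("empty confusion table", call. = FALSE)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- (cc$TP + cc$TN) / n
  sens <- safe(cc$TP, cc$TP + cc$FN)
  spec <- safe(cc$TN, cc$TN + cc$FP)
  prec <- safe(cc$TP, cc$TP + cc$FP)
  f <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
       else 2 * prec * sens / (prec + sens)
  out <- list(accuracy = acc, sensitivity = sens, specificity = spec,
              precision = prec, f_score = f, n = n)
  out$undefined <- names(out)[vapply(out, function(v) length(v) == 1 &&
                                       is.na(v), logical(1))]
  out
}

#' Area under the ROC curve (rank statistic)
#' @param truth 0/1 labels.
#' @param score numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(truth, score) {
  stopifnot(length(truth) == length(score))
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Run the full pipeline once on a given split
#'
#' Trains the S-VGAE on the graph with test pairs hidden (both from the
#' adjacency matrix and from the confidence mask), builds pair features from
#' the posterior means, trains the classifier on the training pairs and
#' evaluates on the test pairs.
#'
#' @param X feature matrix (rows = proteins, in `ids` order).
#' @param ids ordered protein ids.
#' @param train,test edge lists.
#' @param config run configuration from [run_config()].
#' @param seed seed for this run (drives encoder and classifier streams).
#' @param cv_epoch optional classifier epoch count selected upstream; NULL
#'   uses `config$classifier$epochs`.
#' @param unsign drop the negative signs from the propagation matrix (the
#'   ablation arm); the confidence mask and targets are unchanged.
#' @return list with `metrics`, `auc`, `fit`, `model`, `predictions`.
#' @export
run_pipeline_once <- function(X, ids, train, test, config = run_config(),
                              seed = 1L, cv_epoch = NULL, unsign = FALSE) {
  adj <- build_signed_adjacency(ids, rbind(train, test))
  adj <- mask_edges(adj, test)
  # unsigned arm: propagation and reconstruction both see |A|; the mask is
  # identical, so the two arms differ only in sign content
  if (unsign) adj$matrix <- abs(adj$matrix)
  enc_cfg <- config$encoder
  enc_cfg$seed <- derive_seed(seed, 1L)
  fit <- train_svgae(X, adj, enc_cfg)
  emb <- fit$embeddings$mu
  cls_cfg <- config$classifier
  cls_cfg$seed <- derive_seed(seed, 2L)
  if (!is.null(cv_epoch)) cls_cfg$epochs <- cv_epoch
  tr_feat <- pair_features(emb, train, symmetrize = config$symmetrize)
  model <- train_classifier(tr_feat, cls_cfg)
  te_feat <- pair_features(emb, test, symmetrize = config$symmetrize)
  preds <- predict_pairs(model, te_feat, threshold = config$threshold)
  truth <- as.numeric(test$label == "positive")
  mets <- ppi_metrics(confusion(truth, preds$label))
  list(metrics = mets, auc = roc_auc(truth, preds$probability),
       fit = fit, model = model, predictions = preds)
}

#' Full run configuration
#'
#' Bundles the encoder and classifier settings with the evaluation-protocol
#' parameters (80/20 split repeated five times, 5-fold cross-validation on
#' the training pairs, two-order symmetrized pair features, 0.5 decision
#' threshold).
#'
#' @param encoder from [svgae_config()].
#' @param classifier from [classifier_config()].
#' @param test_fraction held-out proportion.
#' @param n_repeats number of random splits.
#' @param n_folds cross-validation folds used for checkpoint (epoch)
#'   selection; 0 disables the selection and trains at the configured epoch
#'   count.
#' @param symmetrize train on both concatenation orders and average scores.
#' @param threshold decision threshold on the interaction probability.
#' @param seed master seed.
#' @return config list.
#' @export
run_config <- function(encoder = svgae_config(),
                       classifier = classifier_config(),
                       test_fraction = 0.2, n_repeats = 5L, n_folds = 5L,
                       symmetrize = TRUE, threshold = 0.5, seed = 1L) {
  list(encoder = encoder, classifier = classifier,
       test_fraction = test_fraction, n_repeats = as.integer(n_repeats),
       n_folds = as.integer(n_folds), symmetrize = symmetrize,
       threshold = threshold, seed = as.integer(seed))
}

# Pick the classifier epoch with the best mean validation accuracy across
# folds (checkpoint selection).
select_epoch_cv <- function(emb, train, fold, config, seed) {
  n_folds <- max(fold)
  acc <- matrix(NA_real_, config$classifier$epochs, n_folds)
  for (k in seq_len(n_folds)) {
    tr <- train[fold != k, , drop = FALSE]
    va <- train[fold == k, , drop = FALSE]
    cfg <- config$classifier
    cfg$seed <- derive_seed(seed, 40L + k)
    m <- train_classifier(pair_features(emb, tr, config$symmetrize), cfg,
                          validation = pair_features(emb, va,
                                                     config$symmetrize))
    acc[, k] <- m$val_history
  }
  which.max(rowMeans(acc))
}

#' Repeated-split evaluation protocol
#'
#' For each repeat: stratified 80/20 split; S-VGAE trained on the graph with
#' test pairs hidden; classifier epoch chosen by stratified k-fold
#' cross-validation on the training pairs; final classifier retrained on all
#' training pairs; the five metrics computed on the untouched hold-out.
#' Reports mean and standard deviation over repeats.
#'
#' @param X feature matrix.
#' @param ids ordered protein ids (rows of `X`).
#' @param edges labeled edge list.
#' @param config from [run_config()].
#' @return list with `summary` (data frame metric/mean/sd/n_repeats) and
#'   `repeats` (per-repeat metric lists).
#' @export
run_protocol <- function(X, ids, edges, config = run_config()) {
  splits <- split_edges(edges, config$test_fraction, config$n_repeats,
                        max(config$n_folds, 2L), config$seed)
  per <- lapply(seq_along(splits), function(r) {
    sp <- splits[[r]]
    rseed <- derive_seed(config$seed, 1000L + r)
    cv_epoch <- NULL
    if (config$n_folds >= 2L) {
      adj <- build_signed_adjacency(ids, rbind(sp$train, sp$test))
      adj <- mask_edges(adj, sp$test)
      enc_cfg <- config$encoder
      enc_cfg$seed <- derive_seed(rseed, 1L)
      fit <- train_svgae(X, adj, enc_cfg)
      cv_epoch <- select_epoch_cv(fit$embeddings$mu, sp$train, sp$fold,
                                  config, rseed)
    }
    run_pipeline_once(X, ids, sp$train, sp$test, config, seed = rseed,
                      cv_epoch = cv_epoch)
  })
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    "f_score")
  vals <- sapply(per, function(p) unlist(p$metrics[metric_names]))
  summary <- data.frame(
    metric = metric_names,
    mean = rowMeans(vals),
    sd = apply(vals, 1L, stats::sd),
    n_repeats = length(per)
  )
  list(summary = summary, repeats = lapply(per, `[[`, "metrics"),
       auc = vapply(per, `[[`, numeric(1), "auc"))
}

#' Coverage-robustness sweep
#'
#' Fixes one stratified split, then for each coverage level sparsifies the
#' training edges per protein (see [coverage_sample()]), retrains the whole
#' pipeline from scratch and evaluates on the fixed test set.
#'
#' @param X feature matrix.
#' @param ids ordered protein ids.
#' @param edges labeled edge list.
#' @param coverages coverage levels in (0, 1].
#' @param config from [run_config()].
#' @return data frame: coverage, accuracy, sensitivity, specificity,
#'   precision, f_score.
#' @export
coverage_sweep <- function(X, ids, edges, coverages = c(0.1, 0.4, 0.7, 1.0),
                           config = run_config()) {
  stopifnot(all(coverages > 0), all(coverages <= 1))
  sp <- split_edges(edges, config$test_fraction, 1L, 2L, config$seed)[[1L]]
  rows <- lapply(coverages, function(cv) {
    kept <- coverage_sample(sp$train, cv, derive_seed(config$seed, 7L))
    res <- run_pipeline_once(X, ids, kept, sp$test, config,
                             seed = derive_seed(config$seed, 9L))
    data.frame(coverage = cv,
               accuracy = res$metrics$accuracy,
               sensitivity = res$metrics$sensitivity,
               specificity = res$metrics$specificity,
               precision = res$metrics$precision,
               f_score = res$metrics$f_score)
  })
  do.call(rbind, rows)
}

#' Signed-versus-unsigned adjacency ablation
#'
#' Runs the full pipeline twice per seed with identical splits, masks and
#' derived seeds: once with the signed adjacency and once with every edge
#' set to +1 (the confidence mask unchanged). The arms differ only in the
#' sign content of the adjacency matrix.
#'
#' @param X feature matrix.
#' @param ids ordered protein ids.
#' @param edges labeled edge list.
#' @param config from [run_config()].
#' @param seeds seeds, one pipeline pair per seed.
#' @return data frame with one row per seed and arm.
#' @export
signed_ablation <- function(X, ids, edges, config = run_config(),
                            seeds = 1:5) {
  rows <- lapply(seeds, function(s) {
    sp <- split_edges(edges, config$test_fraction, 1L, 2L, s)[[1L]]
    arms <- lapply(c(signed = FALSE, unsigned = TRUE), function(u) {
      run_pipeline_once(X, ids, sp$train, sp$test, config, seed = s,
                        unsign = u)
    })
    do.call(rbind, lapply(names(arms), function(nm) {
      m <- arms[[nm]]$metrics
      data.frame(seed = s, arm = nm, accuracy = m$accuracy,
                 f_score = m$f_score, auc = arms[[nm]]$auc)
    }))
  })
  do.call(rbind, rows)
}

#' Write a metrics summary as CSV (`metric,mean,sd,n`)
#' @param summary data frame from [run_protocol()]`$summary`.
#' @param path output path.
#' @export
write_metrics_csv <- function(summary, path) {
  out <- data.frame(metric = summary$metric, mean = summary$mean,
                    sd = summary$sd, n = summary$n_repeats)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
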