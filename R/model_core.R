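# Integrated predictor: ten per-channel 7-layer scoring networks, an
# integration network over the 10-dimensional score vector
# V = (D1, ..., D10), specificity-anchored thresholds, and transfer-learning
# fine-tuning with hidden layers frozen.

#' Train one per-feature scoring network
#'
#' Standardises the feature matrix (stored centre/scale are reused at
#' prediction time) and trains a 7-layer ReLU network with a sigmoid output
#' on the binary labels.
#'
#' @param X Feature matrix (rows = windows).
#' @param y 0/1 labels.
#' @param feature_name Channel name (metadata).
#' @param hidden Hidden-layer widths (five values).
#' @param seed Integer seed.
#' @param ... Passed to [mlp_train()] (epochs, batch_size, lr, ...).
#' @return A `feature_scorer` (network + scaling + name).
#' @export
train_feature_scorer <- function(X, y, feature_name = "feature",
                                 hidden = c(256L, 128L, 64L, 32L, 16L),
                                 seed = 1L, ...) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr, `-`), 2L, scl, `/`)
  net <- mlp_new(ncol(X), hidden = hidden, seed = seed)
  net <- mlp_train(net, Xs, y, seed = seed, ...)
  structure(list(net = net, center = ctr, scale = scl,
                 feature_name = feature_name, seed = seed),
            class = "feature_scorer")
}

#' Score windows with a feature scorer
#'
#' @param scorer A `feature_scorer`.
#' @param X Feature matrix on the scorer's channel.
#' @return Numeric vector of scores in (0, 1).
#' @export
scorer_predict <- function(scorer, X) {
  Xs <- sweep(sweep(as.matrix(X), 2L, scorer$center, `-`), 2L,
              scorer$scale, `/`)
  mlp_predict(scorer$net, Xs)
}

# Encode all ten channels for a peptide vector, given the model's encoders.
encode_all_channels <- function(model, peptides, keys = NULL) {
  self_index <- NULL
  exclude <- FALSE
  if (!is.null(keys) && !is.null(model$gps_keys)) {
    self_index <- match(keys, model$gps_keys)
    exclude <- any(!is.na(self_index))
  }
  feats <- encode_sequence_features(
    peptides, model$encoder_config,
    gps_positives = model$gps_positives,
    gps_exclude_self = exclude, gps_self_index = self_index,
    sub_matrix = model$sub_matrix)
  feats$TRANSFORMER <- transformer_forward(model$transformer, peptides)$features
  feats$PLM <- plm_embed(peptides, model$plm_provider)
  feats[FEATURE_CHANNELS]
}

#' Integration score vector V = (D1, ..., D10)
#'
#' Encodes each window on all ten channels and scores every channel with its
#' trained network, in the fixed registry order APAAC, CKSAAP, CTDC, DDE,
#' DistancePair, EAAC, PAAC, GPS, TRANSFORMER, PLM.
#'
#' @param model A `phospho_model`.
#' @param peptides Character vector of windows.
#' @param keys Optional `protein_id:position` keys enabling leave-one-out GPS
#'   encoding for windows that are in the model's positive set.
#' @return `B x 10` matrix of per-channel scores in (0, 1).
#' @export
integrate_scores <- function(model, peptides, keys = NULL) {
  feats <- encode_all_channels(model, peptides, keys = keys)
  D <- vapply(FEATURE_CHANNELS,
              function(ch) scorer_predict(model$scorers[[ch]], feats[[ch]]),
              numeric(length(peptides)))
  if (length(peptides) == 1L) D <- matrix(D, nrow = 1L,
                                          dimnames = list(NULL,
                                                          FEATURE_CHANNELS))
  D
}

#' Integrated phospho-score for peptide windows
#'
#' @inheritParams integrate_scores
#' @return Numeric vector of integrated scores in (0, 1).
#' @export
score_windows <- function(model, peptides, keys = NULL) {
  D <- integrate_scores(model, peptides, keys = keys)
  mlp_predict(model$integration, D)
}

check_residue_class <- function(windows, class) {
  allowed <- if (class == "O") O_RESIDUES else N_RESIDUES
  bad <- setdiff(unique(windows$residue), allowed)
  if (length(bad)) {
    stop("dataset contains ", paste(bad, collapse = ","),
         " sites; the ", class, "-phosphorylation model accepts only {",
         paste(allowed, collapse = ","), "}")
  }
  allowed
}

#' Pretrain a general O- or N-phosphorylation model
#'
#' Trains the contextual transformer encoder on the training windows, the ten
#' per-channel scoring networks, and the integration network over the
#' 10-dimensional score vectors; thresholds are then calibrated on a held-out
#' calibration split (negatives only) so that High/Medium/Low correspond to
#' specificities of about 95/90/85%.  Class imbalance is handled with
#' inverse-frequency sample weights (optionally, negatives can be subsampled
#' to a fixed ratio instead).  All randomness derives from `seed`.
#'
#' @param dataset A `phospho_dataset` whose residues match `class`
#'   (O = S/T/Y, N = H/R/K).
#' @param class `"O"` or `"N"`.
#' @param seed Integer seed.
#' @param encoder_config An [encoder_config()].
#' @param tf_config A [transformer_config()] (flank must match the dataset).
#' @param hidden,integration_hidden Widths of the scorer / integration
#'   networks (five hidden layers each).
#' @param epochs,batch_size,lr Scorer and integration training settings.
#' @param tf_epochs,tf_max_windows Transformer training settings.
#' @param calibration_frac Fraction of windows held out (stratified) for
#'   threshold calibration.
#' @param negative_ratio Optional negatives-per-positive subsampling ratio
#'   for scorer training (`NULL` = keep all negatives, weight classes).
#' @param cv_folds If >= 2, run stratified cross-validation of the full
#'   pipeline on the fit split and attach per-fold AUCs (costly; 4 is the
#'   published protocol).
#' @param sub_matrix Substitution matrix for the GPS channel.
#' @return A `phospho_model`.
#' @export
pretrain_general <- function(dataset, class = c("O", "N"), seed = 1L,
                             encoder_config = prokphos::encoder_config(),
                             tf_config = NULL,
                             hidden = c(256L, 128L, 64L, 32L, 16L),
                             integration_hidden = c(32L, 16L, 16L, 8L, 8L),
                             epochs = 12L, batch_size = 256L, lr = 1e-3,
                             tf_epochs = 8L, tf_max_windows = 2000L,
                             calibration_frac = 0.15,
                             negative_ratio = NULL,
                             cv_folds = 0L,
                             sub_matrix = NULL) {
  class <- match.arg(class)
  w <- dataset$windows
  check_residue_class(w, class)
  y_all <- as.numeric(w$label == "positive")
  if (length(unique(y_all)) < 2L) stop("dataset must contain both labels")
  if (is.null(sub_matrix)) sub_matrix <- default_substitution_matrix()
  if (is.null(tf_config)) tf_config <- transformer_config(dataset$flank_n)
  if (tf_config$flank_n != dataset$flank_n) {
    stop("transformer flank_n does not match the dataset")
  }

  # calibration split (held out from every training stage)
  set.seed(seed)
  cal_idx <- integer(0)
  if (calibration_frac > 0) {
    pos <- which(y_all == 1); neg <- which(y_all == 0)
    cal_idx <- c(sample(pos, floor(length(pos) * calibration_frac)),
                 sample(neg, floor(length(neg) * calibration_frac)))
  }
  fit_idx <- setdiff(seq_len(nrow(w)), cal_idx)
  fit <- w[fit_idx, , drop = FALSE]
  y <- y_all[fit_idx]

  if (!is.null(negative_ratio)) {
    set.seed(seed + 1L)
    pos <- which(y == 1); neg <- which(y == 0)
    keep_neg <- sample(neg, min(length(neg),
                                ceiling(length(pos) * negative_ratio)))
    sel <- sort(c(pos, keep_neg))
    fit <- fit[sel, , drop = FALSE]
    y <- y[sel]
  }

  tf_model <- train_transformer(fit$peptide, y, config = tf_config,
                                seed = seed + 2L, epochs = tf_epochs,
                                max_windows = tf_max_windows)

  gps_positives <- fit$peptide[y == 1]
  gps_keys <- paste0(fit$protein_id, ":", fit$position)[y == 1]

  model <- structure(list(
    scope = paste0(class, "-general"),
    class = class,
    residue_set = dataset$residue_set,
    flank_n = dataset$flank_n,
    encoder_config = encoder_config,
    tf_config = tf_config,
    transformer = tf_model,
    plm_provider = plm_provider_stub(dataset$flank_n,
                                     embed_dim = encoder_config$plm_dim,
                                     seed = encoder_config$plm_seed),
    gps_positives = gps_positives,
    gps_keys = gps_keys,
    sub_matrix = sub_matrix,
    seed = seed,
    parent = NULL), class = "phospho_model")

  keys <- paste0(fit$protein_id, ":", fit$position)
  feats <- encode_all_channels(model, fit$peptide, keys = keys)

  scorers <- vector("list", length(FEATURE_CHANNELS))
  names(scorers) <- FEATURE_CHANNELS
  for (i in seq_along(FEATURE_CHANNELS)) {
    ch <- FEATURE_CHANNELS[i]
    scorers[[ch]] <- train_feature_scorer(
      feats[[ch]], y, feature_name = ch, hidden = hidden,
      seed = seed + 10L + i, epochs = epochs, batch_size = batch_size,
      lr = lr)
  }
  model$scorers <- scorers

  D <- vapply(FEATURE_CHANNELS,
              function(ch) scorer_predict(scorers[[ch]], feats[[ch]]),
              numeric(nrow(fit)))
  integ <- mlp_new(length(FEATURE_CHANNELS), hidden = integration_hidden,
                   seed = seed + 50L)
  integ <- mlp_train(integ, D, y, seed = seed + 50L, epochs = 4L * epochs,
                     batch_size = batch_size, lr = lr)
  model$integration <- integ
  model$hidden <- hidden
  model$integration_hidden <- integration_hidden

  # specificity-anchored thresholds on held-out calibration negatives
  if (length(cal_idx)) {
    cal <- w[cal_idx, , drop = FALSE]
    cal_scores <- score_windows(model, cal$peptide)
    model$thresholds <- calibrate_thresholds(cal_scores[cal$label == "negative"])
    model$calibration <- list(n_negatives = sum(cal$label == "negative"),
                              n_positives = sum(cal$label == "positive"))
  } else {
    model$thresholds <- NULL
  }

  if (cv_folds >= 2L) {
    fit_ds <- new_dataset(fit, dataset$flank_n, dataset$residue_set,
                          dataset$provenance)
    model$cv <- kfold_cv(
      fit_ds, k = cv_folds,
      trainer = function(tr) pretrain_general(
        tr, class = class, seed = seed + 1000L,
        encoder_config = encoder_config, tf_config = tf_config,
        hidden = hidden, integration_hidden = integration_hidden,
        epochs = epochs, batch_size = batch_size, lr = lr,
        tf_epochs = tf_epochs, tf_max_windows = tf_max_windows,
        calibration_frac = 0, cv_folds = 0L, sub_matrix = sub_matrix),
      scorer = function(m, te) score_windows(m, te$windows$peptide),
      seed = seed + 500L)
  }
  model
}

#' @export
print.phospho_model <- function(x, ...) {
  cat("phospho_model <", x$scope, ">: PSP(", x$flank_n, ",", x$flank_n,
      "), residues {", paste(x$residue_set, collapse = ","),
      "}, 10 channels + integration network\n", sep = "")
  if (!is.null(x$thresholds)) {
    print(as.data.frame(x$thresholds), row.names = FALSE)
  }
  invisible(x)
}

#' Fine-tune a pretrained model on a data subset
#'
#' Transfer learning: the child copies the parent; during training the
#' hidden-layer weights of every per-channel scorer and of the integration
#' network are held fixed, and only the input- and output-layer weights (the
#' first and last weight matrices, with their biases) are updated on the
#' subset.  The transformer encoder and feature scalings are inherited
#' unchanged from the parent; the group-based GPS channel, by default,
#' scores similarity against the subset's own positives (`gps = "parent"`
#' keeps the parent's group).  Thresholds are recalibrated on a held-out
#' calibration split of the subset.
#'
#' @param parent A pretrained `phospho_model`.
#' @param subset A `phospho_dataset` (e.g. one residue type or one species);
#'   species-scoped fine-tuning requires at least 4 positives.
#' @param scope Scope label, e.g. `"residue:S"` or `"species:Ecoli"`.
#' @param seed Integer seed.
#' @param epochs,batch_size,lr Training settings for the unfrozen layers.
#' @param calibration_frac Calibration split fraction (0 keeps the parent's
#'   thresholds).
#' @param gps Positive group for the GPS channel: the subset's positives
#'   (default) or the parent's.
#' @return A fine-tuned `phospho_model` recording its parent scope.
#' @export
finetune_model <- function(parent, subset, scope, seed = 1L,
                           epochs = 8L, batch_size = 128L, lr = 1e-3,
                           calibration_frac = 0.15,
                           gps = c("subset", "parent")) {
  gps <- match.arg(gps)
  w <- subset$windows
  if (nrow(w) == 0L) stop("empty fine-tuning subset")
  y_all <- as.numeric(w$label == "positive")
  if (startsWith(scope, "species:") && sum(y_all == 1) < 4L) {
    stop("species-specific fine-tuning requires at least 4 positive samples")
  }
  if (length(unique(y_all)) < 2L) stop("subset must contain both labels")

  model <- parent
  model$scope <- scope
  model$parent <- parent$scope
  model$seed <- seed

  # the GPS channel is group-based: a residue- or species-specific predictor
  # scores similarity against its own positive group, not the parent's
  if (gps == "subset" && sum(y_all == 1) >= 4L) {
    model$gps_positives <- w$peptide[y_all == 1]
    model$gps_keys <- paste0(w$protein_id, ":", w$position)[y_all == 1]
  }

  set.seed(seed)
  cal_idx <- integer(0)
  if (calibration_frac > 0) {
    pos <- which(y_all == 1); neg <- which(y_all == 0)
    cal_idx <- c(sample(pos, floor(length(pos) * calibration_frac)),
                 sample(neg, floor(length(neg) * calibration_frac)))
  }
  fit_idx <- setdiff(seq_len(nrow(w)), cal_idx)
  fit <- w[fit_idx, , drop = FALSE]
  y <- y_all[fit_idx]

  keys <- paste0(fit$protein_id, ":", fit$position)
  feats <- encode_all_channels(model, fit$peptide, keys = keys)

  io_layers <- c(1L, length(parent$scorers[[1]]$net$W))
  if (epochs > 0L) {
    for (i in seq_along(FEATURE_CHANNELS)) {
      ch <- FEATURE_CHANNELS[i]
      sc <- model$scorers[[ch]]
      Xs <- sweep(sweep(as.matrix(feats[[ch]]), 2L, sc$center, `-`), 2L,
                  sc$scale, `/`)
      sc$net <- mlp_train(sc$net, Xs, y, seed = seed + 10L + i,
                          epochs = epochs, batch_size = batch_size, lr = lr,
                          trainable = io_layers)
      model$scorers[[ch]] <- sc
    }
    D <- vapply(FEATURE_CHANNELS,
                function(ch) scorer_predict(model$scorers[[ch]], feats[[ch]]),
                numeric(nrow(fit)))
    model$integration <- mlp_train(model$integration, D, y,
                                   seed = seed + 50L, epochs = 4L * epochs,
                                   batch_size = batch_size, lr = lr,
                                   trainable = io_layers)
  }

  if (length(cal_idx)) {
    cal <- w[cal_idx, , drop = FALSE]
    if (any(cal$label == "negative")) {
      cal_scores <- score_windows(model, cal$peptide)
      model$thresholds <-
        calibrate_thresholds(cal_scores[cal$label == "negative"])
    }
  }
  model
}

#' Predict phosphorylation sites in proteins
#'
#' Scores every candidate residue of the model's residue set (or the supplied
#' positions) and reports the columns `ID`, `Position`, `Code`, `Peptide`,
#' `Score`, `Cutoff`, `Passes`, `Source`.  With `threshold = "All"` every
#' candidate is returned; otherwise only rows at or above the level's cutoff.
#'
#' @param model A `phospho_model` with calibrated thresholds.
#' @param proteins data.frame with `id`, `sequence` columns.
#' @param threshold `"High"`, `"Medium"`, `"Low"` or `"All"`.
#' @param positions Optional data.frame (`protein_id`, `position`) restricting
#'   the candidates; positions whose residue is outside the model scope are
#'   skipped with a warning.
#' @param known_sites Optional site table; matching rows are marked
#'   `Source = "Exp"` (otherwise `"Pred"`).
#' @return data.frame of predictions, sorted by protein and position.
#' @export
predict_sites <- function(model, proteins,
                          threshold = c("All", "High", "Medium", "Low"),
                          positions = NULL, known_sites = NULL) {
  threshold <- match.arg(threshold)
  if (threshold != "All" && is.null(model$thresholds)) {
    stop("model has no calibrated thresholds; use threshold = 'All' or ",
         "recalibrate")
  }
  cand <- list()
  for (i in seq_len(nrow(proteins))) {
    chars <- strsplit(proteins$sequence[i], "", fixed = TRUE)[[1]]
    pos <- which(chars %in% model$residue_set)
    if (!is.null(positions)) {
      req <- positions$position[positions$protein_id == proteins$id[i]]
      skip <- setdiff(req, pos)
      if (length(skip)) {
        warning("skipping position(s) ", paste(skip, collapse = ","),
                " of ", proteins$id[i],
                ": residue outside the model scope {",
                paste(model$residue_set, collapse = ","), "}")
      }
      pos <- intersect(req, pos)
    }
    if (!length(pos)) next
    cand[[length(cand) + 1L]] <- data.frame(
      ID = proteins$id[i], Position = pos, Code = chars[pos],
      Peptide = vapply(pos, function(p)
        extract_window(proteins$sequence[i], p, model$flank_n), character(1)),
      stringsAsFactors = FALSE)
  }
  if (!length(cand)) {
    return(data.frame(ID = character(), Position = integer(),
                      Code = character(), Peptide = character(),
                      Score = numeric(), Cutoff = numeric(),
                      Passes = logical(), Source = character()))
  }
  out <- do.call(rbind, cand)
  out$Score <- score_windows(model, out$Peptide)
  cutoff <- if (threshold == "All") 0 else {
    model$thresholds$cutoff[model$thresholds$level == threshold]
  }
  out$Cutoff <- cutoff
  out$Passes <- out$Score >= cutoff
  out$Source <- "Pred"
  if (!is.null(known_sites)) {
    key <- paste0(out$ID, ":", out$Position)
    exp_key <- paste0(known_sites$protein_id, ":", known_sites$position)
    out$Source[key %in% exp_key] <- "Exp"
  }
  if (threshold != "All") out <- out[out$Passes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ablation-based feature-channel contributions
#'
#' The contribution of channel i is the mean absolute change of the
#' integrated score when D_i is replaced by its dataset mean — a simple
#' sensitivity measure of the integration network to each channel.
#'
#' @param model A `phospho_model`.
#' @param peptides Character vector of windows to evaluate on.
#' @return data.frame (`channel`, `contribution`), sorted decreasing.
#' @export
feature_contribution <- function(model, peptides) {
  D <- integrate_scores(model, peptides)
  base <- mlp_predict(model$integration, D)
  contrib <- vapply(seq_along(FEATURE_CHANNELS), function(i) {
    D2 <- D
    D2[, i] <- mean(D[, i])
    mean(abs(mlp_predict(model$integration, D2) - base))
  }, numeric(1))
  out <- data.frame(channel = FEATURE_CHANNELS, contribution = contrib)
  out[order(-out$contribution), , drop = FALSE]
}
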