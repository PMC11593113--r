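# End-to-end synthetic benchmark: simulate a planted-motif phosphoproteome,
# train the integrated model on the pre-cutoff windows, and measure held-out
# discrimination and threshold specificity.  Used by the package's own
# acceptance checks and reproducible from the command line.

#' Run the planted-motif recovery benchmark
#'
#' Simulates a phosphoproteome under the default planted-motif conditions,
#' splits it by timestamp, pretrains the general O-phosphorylation model on
#' the training windows, and evaluates on held-out data: ROC/AUC over the
#' post-cutoff windows plus a freshly simulated evaluation batch, and the
#' specificity achieved by each calibrated threshold on the held-out
#' negatives.
#'
#' @param seed Integer seed driving simulation, training and splits.
#' @param n_proteins Proteins in the training simulation.
#' @param n_eval_proteins Proteins in the held-out evaluation batch
#'   (sized so the benchmark scores well over 2,000 held-out negatives).
#' @param ... Further arguments passed to [pretrain_general()].
#' @return List: `model`, `train`/`test` datasets, `auc`, `achieved_sp`
#'   (named fraction of held-out negatives under each cutoff), `scores`,
#'   `labels`, `config`.
#' @export
run_recovery_benchmark <- function(seed, n_proteins = 2000L,
                                   n_eval_proteins = 600L, ...) {
  cfg <- sim_config(n_proteins = n_proteins, seed = seed)
  sim <- simulate_phosphoproteome(cfg)
  ds <- build_dataset(sim$proteins, sim$sites, n = cfg$flank_n,
                      residue_set = cfg$residue_set,
                      provenance = "synthetic planted-motif benchmark")
  parts <- split_by_timestamp(ds, cfg$cutoff_date)
  model <- pretrain_general(parts$train, class = "O", seed = seed + 1L, ...)

  eval_cfg <- sim_config(n_proteins = n_eval_proteins, seed = seed + 7L)
  eval_sim <- simulate_phosphoproteome(eval_cfg)
  eval_ds <- build_dataset(eval_sim$proteins, eval_sim$sites,
                           n = cfg$flank_n, residue_set = cfg$residue_set)

  held <- rbind(parts$test$windows, eval_ds$windows)
  scores <- score_windows(model, held$peptide)
  labels <- as.numeric(held$label == "positive")
  roc <- roc_auc(scores, labels)

  neg_scores <- scores[labels == 0]
  thr <- model$thresholds
  achieved <- vapply(c("High", "Medium", "Low"), function(lv)
    mean(neg_scores < thr$cutoff[thr$level == lv]), numeric(1))

  list(model = model, train = parts$train, test = parts$test,
       eval_dataset = eval_ds, scores = scores, labels = labels,
       auc = roc$auc, roc = roc$roc, achieved_sp = achieved,
       n_held_out_negatives = sum(labels == 0), config = cfg)
}

#' Label-shuffle control for the recovery benchmark
#'
#' Retrains the full pipeline on the same training windows with labels
#' randomly permuted, then scores the held-out windows against their true
#' labels; the resulting AUC should sit near 0.5.  The training set is
#' subsampled (stratified by the shuffled labels) to keep the control cheap.
#'
#' @param benchmark Result of [run_recovery_benchmark()].
#' @param seed Integer seed for the permutation and retraining.
#' @param max_windows Training-subsample cap for the control.
#' @return List with `auc` and the control `model`.
#' @export
run_shuffle_control <- function(benchmark, seed, max_windows = 3000L) {
  w <- benchmark$train$windows
  set.seed(seed)
  w$label <- sample(w$label)
  if (nrow(w) > max_windows) {
    w <- w[sort(sample(nrow(w), max_windows)), , drop = FALSE]
  }
  shuffled <- new_dataset(w, benchmark$train$flank_n,
                          benchmark$train$residue_set, "label-shuffle control")
  model <- pretrain_general(shuffled, class = "O", seed = seed + 1L)
  held <- rbind(benchmark$test$windows, benchmark$eval_dataset$windows)
  scores <- score_windows(model, held$peptide)
  labels <- as.numeric(held$label == "positive")
  list(auc = roc_auc(scores, labels)$auc, model = model)
}

#' Two-species transfer-learning benchmark
#'
#' Builds the two-species fixture (disjoint planted motifs), pretrains a
#' general model on the combined pre-cutoff data, fine-tunes one
#' species-specific model per species, and scores each species' held-out
#' positives with both fine-tuned models.
#'
#' @param seed Integer seed.
#' @param n_proteins Proteins per species.
#' @param ... Passed to [pretrain_general()].
#' @return List with the parent and per-species models and a `medians`
#'   matrix: rows = scoring model (A, B), columns = positive set scored.
#' @export
run_transfer_benchmark <- function(seed, n_proteins = 220L, ...) {
  fx <- two_species_fixture(seed, n_proteins = n_proteins)
  ds <- build_dataset(fx$proteins, fx$sites, n = 10L,
                      residue_set = c("S", "T"),
                      provenance = "two-species fixture")
  parts <- split_by_timestamp(ds, as.Date("2022-10-01"))
  parent <- pretrain_general(parts$train, class = "O", seed = seed + 1L, ...)

  train_w <- parts$train$windows
  test_w <- parts$test$windows
  models <- list()
  for (sp in c("A", "B")) {
    sub <- new_dataset(train_w[train_w$species == sp, , drop = FALSE],
                       ds$flank_n, ds$residue_set, paste("species", sp))
    models[[sp]] <- finetune_model(parent, sub,
                                   scope = paste0("species:", sp),
                                   seed = seed + 10L + match(sp, c("A", "B")))
  }
  pos_sets <- lapply(c(A = "A", B = "B"), function(sp)
    test_w$peptide[test_w$species == sp & test_w$label == "positive"])
  medians <- sapply(c(A = "A", B = "B"), function(msp)
    sapply(pos_sets, function(pp)
      stats::median(score_windows(models[[msp]], pp))))
  # medians[set, model]: transpose to model x set
  list(parent = parent, models = models, medians = t(medians),
       test = parts$test)
}
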