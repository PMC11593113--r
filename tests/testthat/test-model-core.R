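test_that("feature scorers learn separable data and stay in (0,1)", {
  set.seed(51)
  X <- matrix(c(rnorm(60, 3), rnorm(60, -3)), ncol = 1)
  y <- rep(c(1, 0), each = 60)
  sc <- train_feature_scorer(X, y, "toy", seed = 3, epochs = 40,
                             batch_size = 16)
  p <- scorer_predict(sc, X)
  expect_true(all(p > 0 & p < 1))
  expect_gte(mean((p > 0.5) == (y == 1)), 0.95)

  # shuffled labels carry no signal
  set.seed(52)
  ysh <- sample(y)
  Xh <- matrix(rnorm(240), ncol = 2)
  sch <- train_feature_scorer(Xh[1:80, , drop = FALSE], ysh[1:80], "null",
                              seed = 4, epochs = 15)
  auc <- roc_auc(scorer_predict(sch, Xh[81:120, , drop = FALSE]),
                 ysh[81:120])$auc
  expect_gt(auc, 0.2)
  expect_lt(auc, 0.8)

  expect_warning(train_feature_scorer(matrix(1, 40, 2), rep(c(0, 1), 20),
                                      seed = 5, epochs = 2), "constant")
  expect_error(train_feature_scorer(Xh, rep(1, 120), seed = 6), "single class")
})

test_that("the integration vector has 10 channel scores in registry order", {
  fx <- mini_model()
  peps <- fx$test$windows$peptide[1:8]
  D <- integrate_scores(fx$model, peps)
  expect_equal(dim(D), c(8L, 10L))
  expect_equal(colnames(D), c("APAAC", "CKSAAP", "CTDC", "DDE",
                              "DistancePair", "EAAC", "PAAC", "GPS",
                              "TRANSFORMER", "PLM"))
  expect_true(all(D > 0 & D < 1))

  # composition: D_i equals calling each scorer on its own channel
  feats <- prokphos:::encode_all_channels(fx$model, peps)
  for (ch in colnames(D)) {
    expect_equal(unname(D[, ch]),
                 scorer_predict(fx$model$scorers[[ch]], feats[[ch]]))
  }
})

test_that("the O model refuses N-class sites", {
  prot <- data.frame(id = "p1", sequence = strrep("AH", 30), species = "x",
                     timestamp = as.Date("2020-01-01"))
  sites <- data.frame(protein_id = "p1", position = 2L, residue = "H")
  ds <- build_dataset(prot, sites, n = 10L, residue_set = "H")
  expect_error(pretrain_general(ds, class = "O", seed = 1),
               "O-phosphorylation model accepts only")
})

test_that("pretraining is bitwise reproducible for a fixed seed", {
  ds <- small_sim()$dataset
  parts <- split_by_timestamp(ds, as.Date("2022-10-01"))
  sub <- prokphos:::new_dataset(parts$train$windows[1:150, ],
                                ds$flank_n, ds$residue_set)
  m1 <- suppressWarnings(pretrain_general(sub, "O", seed = 99,
                                          tf_epochs = 1L, epochs = 2L,
                                          tf_max_windows = 150L))
  m2 <- suppressWarnings(pretrain_general(sub, "O", seed = 99,
                                          tf_epochs = 1L, epochs = 2L,
                                          tf_max_windows = 150L))
  expect_identical(m1$transformer$par, m2$transformer$par)
  for (ch in names(m1$scorers)) {
    expect_identical(m1$scorers[[ch]]$net$W, m2$scorers[[ch]]$net$W)
  }
  expect_identical(m1$integration$W, m2$integration$W)
  expect_identical(score_windows(m1, parts$test$windows$peptide[1:5]),
                   score_windows(m2, parts$test$windows$peptide[1:5]))
})

test_that("fine-tuning freezes hidden layers exactly and needs 4 positives", {
  fx <- mini_model()
  train_w <- fx$train$windows
  sub <- prokphos:::new_dataset(train_w[seq_len(min(250, nrow(train_w))), ],
                                fx$train$flank_n, fx$train$residue_set)
  child <- suppressWarnings(
    finetune_model(fx$model, sub, scope = "residue:S", seed = 5, epochs = 2))
  expect_equal(child$parent, fx$model$scope)
  for (ch in names(child$scorers)) {
    for (l in 2:5) {
      expect_identical(child$scorers[[ch]]$net$W[[l]],
                       fx$model$scorers[[ch]]$net$W[[l]])
      expect_identical(child$scorers[[ch]]$net$b[[l]],
                       fx$model$scorers[[ch]]$net$b[[l]])
    }
  }
  for (l in 2:5) {
    expect_identical(child$integration$W[[l]], fx$model$integration$W[[l]])
  }

  # zero-epoch fine-tuning keeps the parent's weights entirely
  same <- suppressWarnings(
    finetune_model(fx$model, sub, scope = "residue:S", seed = 5, epochs = 0,
                   gps = "parent"))
  peps <- fx$test$windows$peptide[1:5]
  expect_identical(score_windows(same, peps), score_windows(fx$model, peps))

  # species scope demands at least 4 positives
  few <- sub$windows[sub$windows$label == "negative", ][1:30, ]
  few$label[1:2] <- "positive"
  few_ds <- prokphos:::new_dataset(few, sub$flank_n, sub$residue_set)
  expect_error(finetune_model(fx$model, few_ds, scope = "species:X",
                              seed = 1), "at least 4")
})

test_that("prediction respects thresholds, batching and scope", {
  fx <- mini_model()
  proteins <- small_sim()$sim$proteins[1:6, ]
  all_tab <- predict_sites(fx$model, proteins, threshold = "All")
  n_cand <- sum(vapply(strsplit(proteins$sequence, ""),
                       function(ch) sum(ch %in% c("S", "T", "Y")),
                       integer(1)))
  expect_equal(nrow(all_tab), n_cand)
  expect_equal(names(all_tab), c("ID", "Position", "Code", "Peptide",
                                 "Score", "Cutoff", "Passes", "Source"))

  key <- function(t) paste0(t$ID, ":", t$Position)
  hi <- predict_sites(fx$model, proteins, threshold = "High")
  me <- predict_sites(fx$model, proteins, threshold = "Medium")
  lo <- predict_sites(fx$model, proteins, threshold = "Low")
  expect_true(all(key(hi) %in% key(me)))
  expect_true(all(key(me) %in% key(lo)))

  # batch invariance of scores
  single <- vapply(all_tab$Peptide[1:5], function(p)
    score_windows(fx$model, p), numeric(1))
  expect_equal(unname(single), all_tab$Score[1:5], tolerance = 1e-10)

  # out-of-scope positions are skipped with a warning
  chars <- strsplit(proteins$sequence[1], "")[[1]]
  bad_pos <- which(!(chars %in% c("S", "T", "Y")))[1]
  expect_warning(
    predict_sites(fx$model, proteins[1, ],
                  positions = data.frame(protein_id = proteins$id[1],
                                         position = bad_pos)),
    "outside the model scope")
})

test_that("ablation contributions are non-negative and zero for flat channels", {
  fx <- mini_model()
  peps <- fx$test$windows$peptide[1:40]
  fc <- feature_contribution(fx$model, peps)
  expect_setequal(fc$channel, colnames(integrate_scores(fx$model, peps[1])))
  expect_true(all(fc$contribution >= 0))

  # a constant-output scorer contributes exactly 0
  flat <- fx$model
  for (l in seq_along(flat$scorers$APAAC$net$W)) {
    flat$scorers$APAAC$net$W[[l]][] <- 0
    flat$scorers$APAAC$net$b[[l]][] <- 0
  }
  fc0 <- feature_contribution(flat, peps)
  expect_equal(fc0$contribution[fc0$channel == "APAAC"], 0)
})

test_that("model bundles round-trip through save/load", {
  fx <- mini_model()
  dir <- withr::local_tempdir()
  model_save(fx$model, dir)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  back <- model_load(dir)
  peps <- fx$test$windows$peptide[1:3]
  expect_identical(score_windows(back, peps), score_windows(fx$model, peps))
})
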