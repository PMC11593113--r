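# Minimal feed-forward network engine: 7-layer (input + 5 hidden + output)
# ReLU networks with a sigmoid output unit, trained by Adam on a weighted
# binary cross-entropy.  Written in plain matrix algebra so layer freezing
# (transfer learning) and bitwise-reproducible seeding are explicit.

relu <- function(x) (x + abs(x)) / 2
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Create a feature-scoring network
#'
#' @param input_dim Number of input features.
#' @param hidden Widths of the five hidden layers.
#' @param seed Integer seed for the He-style initialisation.
#' @return An `mlp` object (list of weight matrices `W`, biases `b`).
#' @export
mlp_new <- function(input_dim, hidden = c(256L, 128L, 64L, 32L, 16L),
                    seed = 1L) {
  stopifnot(length(hidden) == 5L)  # input + 5 hidden + output = 7 layers
  dims <- c(input_dim, hidden, 1L)
  set.seed(seed)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                  sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  structure(list(W = W, b = b, dims = dims, seed = seed), class = "mlp")
}

# Forward pass; returns activations for backprop when `keep = TRUE`.
mlp_forward <- function(net, X, keep = FALSE) {
  nl <- length(net$W)
  A <- vector("list", nl + 1L)
  A[[1L]] <- X
  for (l in seq_len(nl)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], `+`)
    A[[l + 1L]] <- if (l < nl) relu(Z) else sigmoid(Z)
  }
  if (keep) A else as.vector(A[[nl + 1L]])
}

#' Score samples with a trained network
#'
#' @param net An `mlp`.
#' @param X Numeric matrix (rows = samples).
#' @return Numeric vector of sigmoid scores in (0, 1).
#' @export
mlp_predict <- function(net, X) mlp_forward(net, as.matrix(X))

# One Adam step over the listed trainable layers (weights + biases).
adam_step <- function(net, grads, state, lr, trainable,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (l in trainable) {
    for (p in c("W", "b")) {
      g <- grads[[p]][[l]]
      state$m[[p]][[l]] <- beta1 * state$m[[p]][[l]] + (1 - beta1) * g
      state$v[[p]][[l]] <- beta2 * state$v[[p]][[l]] + (1 - beta2) * g^2
      net[[p]][[l]] <- net[[p]][[l]] - lr * (state$m[[p]][[l]] / corr1) /
        (sqrt(state$v[[p]][[l]] / corr2) + eps)
    }
  }
  list(net = net, state = state)
}

bce_loss <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

#' Train a feature-scoring network
#'
#' Minimises a weighted binary cross-entropy with Adam.  A stratified
#' validation split drives early stopping; the best-validation weights are
#' returned.  `trainable` restricts updates to a subset of the 6 weight
#' matrices — transfer learning freezes the hidden layers by passing
#' `trainable = c(1, 6)` (first/input and last/output matrices only).
#'
#' @param net An `mlp` from [mlp_new()].
#' @param X Numeric matrix of training samples.
#' @param y 0/1 labels.
#' @param sample_weight Per-sample weights (default: inverse class frequency).
#' @param epochs,batch_size,lr Optimisation settings.
#' @param val_frac Fraction held out for early stopping (0 disables).
#' @param patience Epochs without validation improvement before stopping.
#' @param trainable Indices of trainable weight matrices (default all 6).
#' @param seed Integer seed controlling shuffling and the validation split.
#' @return The trained `mlp`, with a `history` element (per-epoch losses).
#' @export
mlp_train <- function(net, X, y, sample_weight = NULL,
                      epochs = 12L, batch_size = 256L, lr = 1e-3,
                      val_frac = 0.15, patience = 3L,
                      trainable = seq_along(net$W), seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (is.null(sample_weight)) {
    freq <- mean(y)
    sample_weight <- ifelse(y == 1, 0.5 / freq, 0.5 / (1 - freq))
  }
  if (stats::var(as.vector(X)) == 0) {
    warning("constant feature matrix; the scorer will learn the base rate only")
  }
  set.seed(seed)
  n <- nrow(X)
  val_idx <- integer(0)
  if (val_frac > 0 && n >= 20L) {
    pos <- which(y == 1); neg <- which(y == 0)
    val_idx <- c(sample(pos, max(1L, floor(length(pos) * val_frac))),
                 sample(neg, max(1L, floor(length(neg) * val_frac))))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  state <- list(t = 0L,
                m = list(W = lapply(net$W, function(w) w * 0),
                         b = lapply(net$b, function(b) b * 0)),
                v = list(W = lapply(net$W, function(w) w * 0),
                         b = lapply(net$b, function(b) b * 0)))
  best <- list(loss = Inf, W = net$W, b = net$b)
  bad_epochs <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  nl <- length(net$W)

  for (epoch in seq_len(epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; ep_w <- 0
    for (s in seq(1L, length(ord), by = batch_size)) {
      bi <- ord[s:min(length(ord), s + batch_size - 1L)]
      Xb <- X[bi, , drop = FALSE]
      yb <- y[bi]
      wb <- sample_weight[bi]
      A <- mlp_forward(net, Xb, keep = TRUE)
      p <- as.vector(A[[nl + 1L]])
      ep_loss <- ep_loss + bce_loss(p, yb, wb) * sum(wb)
      ep_w <- ep_w + sum(wb)
      # backprop
      gW <- vector("list", nl); gb <- vector("list", nl)
      dZ <- matrix(wb * (p - yb) / sum(wb), ncol = 1L)
      for (l in rev(seq_len(nl))) {
        gW[[l]] <- crossprod(A[[l]], dZ)
        gb[[l]] <- colSums(dZ)
        if (l > 1L) {
          dA <- dZ %*% t(net$W[[l]])
          dZ <- dA * (A[[l]] > 0)
        }
      }
      upd <- adam_step(net, list(W = gW, b = gb), state, lr, trainable)
      net <- upd$net; state <- upd$state
    }
    val_loss <- NA_real_
    if (length(val_idx)) {
      pv <- mlp_forward(net, X[val_idx, , drop = FALSE])
      val_loss <- bce_loss(pv, y[val_idx], sample_weight[val_idx])
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, W = net$W, b = net$b)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / ep_w,
                                         val_loss = val_loss))
    if (length(val_idx) && bad_epochs >= patience) break
  }
  if (length(val_idx) && is.finite(best$loss)) {
    net$W <- best$W; net$b <- best$b
  }
  net$history <- history
  net
}
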