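# Small transformer encoder for peptide windows.
#
# Architecture: learned token + position embeddings over the 21-symbol
# vocabulary (20 amino acids + "*"), followed by `n_blocks` post-norm
# residual blocks, each a multi-head self-attention layer (softmax(QK'/
# sqrt(d_k)) V per head, heads concatenated and projected by Wo) plus a
# two-layer ReLU feed-forward network, and a sigmoid classifier head on the
# flattened last-block hidden states.  Forward and backward passes are
# written out in matrix algebra; training uses Adam on a weighted binary
# cross-entropy and is deterministic for a fixed seed.

#' Transformer configuration
#'
#' Defaults: 3 blocks of 4 heads (12 attention matrices per window),
#' 64-dimensional embeddings, 128-dimensional feed-forward layer.
#'
#' @param flank_n Flank size of the peptide windows (window length
#'   `2 * flank_n + 1`).
#' @param d_model Embedding width (divisible by `n_heads`).
#' @param n_heads Attention heads per block.
#' @param n_blocks Encoder blocks.
#' @param d_ffn Feed-forward hidden width.
#' @return A list of class `transformer_config`.
#' @export
transformer_config <- function(flank_n = 10L, d_model = 64L, n_heads = 4L,
                               n_blocks = 3L, d_ffn = 128L) {
  if (d_model %% n_heads != 0L) stop("d_model must be divisible by n_heads")
  structure(list(flank_n = as.integer(flank_n),
                 L = 2L * as.integer(flank_n) + 1L,
                 vocab = 21L,
                 d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads),
                 n_blocks = as.integer(n_blocks),
                 d_ffn = as.integer(d_ffn),
                 d_k = as.integer(d_model / n_heads)),
            class = "transformer_config")
}

# Flat parameter list; block parameters are named "b<k>.<name>".
transformer_init <- function(config, seed = 1L) {
  set.seed(seed)
  d <- config$d_model
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  par <- list(tok = rn(config$vocab, d, 1 / sqrt(d)),
              pos = rn(config$L, d, 1 / sqrt(d)))
  for (k in seq_len(config$n_blocks)) {
    pre <- paste0("b", k, ".")
    par[[paste0(pre, "Wq")]] <- rn(d, d, 1 / sqrt(d))
    par[[paste0(pre, "Wk")]] <- rn(d, d, 1 / sqrt(d))
    par[[paste0(pre, "Wv")]] <- rn(d, d, 1 / sqrt(d))
    par[[paste0(pre, "Wo")]] <- rn(d, d, 1 / sqrt(d))
    par[[paste0(pre, "ln1g")]] <- rep(1, d)
    par[[paste0(pre, "ln1b")]] <- rep(0, d)
    par[[paste0(pre, "W1")]] <- rn(d, config$d_ffn, sqrt(2 / d))
    par[[paste0(pre, "b1")]] <- rep(0, config$d_ffn)
    par[[paste0(pre, "W2")]] <- rn(config$d_ffn, d, sqrt(2 / config$d_ffn))
    par[[paste0(pre, "b2")]] <- rep(0, d)
    par[[paste0(pre, "ln2g")]] <- rep(1, d)
    par[[paste0(pre, "ln2b")]] <- rep(0, d)
  }
  par$cls_W <- rn(config$L, d, 1e-2)
  par$cls_b <- 0
  structure(list(config = config, par = par, seed = seed),
            class = "phos_transformer")
}

ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`), xhat = xhat, inv = inv)
}

ln_backward <- function(dy, g, cache) {
  dxhat <- sweep(dy, 2L, g, `*`)
  xhat <- cache$xhat
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

#' Embed a peptide window
#'
#' `E = Embedding_token + Embedding_pos`: each position's vector is the sum
#' of its symbol's token embedding and its position embedding.
#'
#' @param model A `phos_transformer`.
#' @param peptide A single window string of the configured length.
#' @return `(2n+1) x d_model` numeric matrix.
#' @export
transformer_embed <- function(model, peptide) {
  cfg <- model$config
  idx <- peptides_to_matrix(peptide)[1L, ]
  if (length(idx) != cfg$L) stop("window length does not match the model")
  model$par$tok[idx, , drop = FALSE] + model$par$pos
}

#' Single attention head
#'
#' `A = softmax(Q K' / sqrt(d_k))` row-wise, output `A V`, with
#' `Q = E Wq`, `K = E Wk`, `V = E Wv`.
#'
#' @param E Position-wise input matrix (`L x d`).
#' @param Wq,Wk,Wv Projection matrices (`d x d_k`).
#' @return List with `output` (`L x d_k`) and `attention` (`L x L`,
#'   row-stochastic).
#' @export
attention_head <- function(E, Wq, Wk, Wv) {
  Q <- E %*% Wq
  K <- E %*% Wk
  V <- E %*% Wv
  A <- softmax_rows(tcrossprod(Q, K) / sqrt(ncol(K)))
  list(output = A %*% V, attention = A)
}

#' One encoder block applied to an embedded window
#'
#' Concatenates the head outputs, projects by `Wo`, applies the post-norm
#' residual, then the ReLU feed-forward network and its post-norm residual.
#'
#' @param E Position-wise input (`L x d_model`).
#' @param model A `phos_transformer`.
#' @param block Block index (1-based).
#' @return List with `output` (`L x d_model`) and `attention`
#'   (list of `n_heads` `L x L` matrices).
#' @export
multihead <- function(E, model, block = 1L) {
  cfg <- model$config
  p <- model$par
  pre <- paste0("b", block, ".")
  dk <- cfg$d_k
  heads <- lapply(seq_len(cfg$n_heads), function(h) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    attention_head(E, p[[paste0(pre, "Wq")]][, cols, drop = FALSE],
                   p[[paste0(pre, "Wk")]][, cols, drop = FALSE],
                   p[[paste0(pre, "Wv")]][, cols, drop = FALSE])
  })
  M <- do.call(cbind, lapply(heads, `[[`, "output")) %*% p[[paste0(pre, "Wo")]]
  X1 <- ln_forward(E + M, p[[paste0(pre, "ln1g")]], p[[paste0(pre, "ln1b")]])$y
  FF <- relu(sweep(X1 %*% p[[paste0(pre, "W1")]], 2L,
                   p[[paste0(pre, "b1")]], `+`)) %*% p[[paste0(pre, "W2")]]
  FF <- sweep(FF, 2L, p[[paste0(pre, "b2")]], `+`)
  X2 <- ln_forward(X1 + FF, p[[paste0(pre, "ln2g")]], p[[paste0(pre, "ln2b")]])$y
  list(output = X2, attention = lapply(heads, `[[`, "attention"))
}

# Batched forward pass over an integer window matrix (B x L).  Rows of the
# internal state matrices are ordered (window 1 pos 1..L, window 2 pos 1..L,
# ...).  Returns caches for backprop when keep = TRUE and per-window
# attention arrays when attention = TRUE.
tf_forward <- function(model, pm, keep = FALSE, attention = FALSE) {
  cfg <- model$config
  p <- model$par
  B <- nrow(pm); L <- cfg$L; d <- cfg$d_model; dk <- cfg$d_k
  tokidx <- as.vector(t(pm))
  X <- p$tok[tokidx, , drop = FALSE] + p$pos[rep(seq_len(L), B), , drop = FALSE]
  caches <- vector("list", cfg$n_blocks)
  attn <- if (attention) vector("list", cfg$n_blocks) else NULL
  rows_of <- function(w) ((w - 1L) * L + 1L):(w * L)

  for (k in seq_len(cfg$n_blocks)) {
    pre <- paste0("b", k, ".")
    Q <- X %*% p[[paste0(pre, "Wq")]]
    K <- X %*% p[[paste0(pre, "Wk")]]
    V <- X %*% p[[paste0(pre, "Wv")]]
    Hcat <- matrix(0, B * L, d)
    A_store <- array(0, c(L, L, cfg$n_heads, B))
    for (w in seq_len(B)) {
      rw <- rows_of(w)
      for (h in seq_len(cfg$n_heads)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        Qh <- Q[rw, cols, drop = FALSE]
        Kh <- K[rw, cols, drop = FALSE]
        A <- softmax_rows(tcrossprod(Qh, Kh) / sqrt(dk))
        A_store[, , h, w] <- A
        Hcat[rw, cols] <- A %*% V[rw, cols, drop = FALSE]
      }
    }
    M <- Hcat %*% p[[paste0(pre, "Wo")]]
    l1 <- ln_forward(X + M, p[[paste0(pre, "ln1g")]], p[[paste0(pre, "ln1b")]])
    X1 <- l1$y
    Z1 <- sweep(X1 %*% p[[paste0(pre, "W1")]], 2L, p[[paste0(pre, "b1")]], `+`)
    H1 <- relu(Z1)
    FF <- sweep(H1 %*% p[[paste0(pre, "W2")]], 2L, p[[paste0(pre, "b2")]], `+`)
    l2 <- ln_forward(X1 + FF, p[[paste0(pre, "ln2g")]], p[[paste0(pre, "ln2b")]])
    if (keep) {
      caches[[k]] <- list(Xin = X, Q = Q, K = K, V = V, A = A_store,
                          Hcat = Hcat, l1 = l1, X1 = X1, Z1 = Z1, H1 = H1,
                          l2 = l2)
    }
    if (attention) attn[[k]] <- A_store
    X <- l2$y
  }
  # classifier on flattened last-block states
  grp_w <- rep(seq_len(B), each = L)
  cls_rep <- p$cls_W[rep(seq_len(L), B), , drop = FALSE]
  z <- as.vector(rowsum(rowSums(X * cls_rep), grp_w)) + p$cls_b
  list(Xout = X, z = z, score = sigmoid(z), tokidx = tokidx,
       caches = if (keep) caches else NULL, attn = attn, B = B)
}

# Backward pass: gradient of the weighted BCE wrt all parameters.
tf_backward <- function(model, fwd, y, w) {
  cfg <- model$config
  p <- model$par
  B <- fwd$B; L <- cfg$L; d <- cfg$d_model; dk <- cfg$d_k
  grads <- lapply(p, function(x) if (is.matrix(x)) x * 0 else x * 0)
  dz <- w * (fwd$score - y) / sum(w)
  grp_w <- rep(seq_len(B), each = L)
  grp_pos <- rep(seq_len(L), B)
  dz_exp <- dz[grp_w]
  cls_rep <- p$cls_W[grp_pos, , drop = FALSE]
  grads$cls_W <- rowsum(fwd$Xout * dz_exp, grp_pos)
  grads$cls_b <- sum(dz)
  dX <- cls_rep * dz_exp

  rows_of <- function(wi) ((wi - 1L) * L + 1L):(wi * L)
  for (k in rev(seq_len(cfg$n_blocks))) {
    pre <- paste0("b", k, ".")
    cc <- fwd$caches[[k]]
    l2b <- ln_backward(dX, p[[paste0(pre, "ln2g")]], cc$l2)
    grads[[paste0(pre, "ln2g")]] <- l2b$dg
    grads[[paste0(pre, "ln2b")]] <- l2b$db
    dR2 <- l2b$dx
    # FFN
    dFF <- dR2
    grads[[paste0(pre, "W2")]] <- crossprod(cc$H1, dFF)
    grads[[paste0(pre, "b2")]] <- colSums(dFF)
    dZ1 <- (dFF %*% t(p[[paste0(pre, "W2")]])) * (cc$Z1 > 0)
    grads[[paste0(pre, "W1")]] <- crossprod(cc$X1, dZ1)
    grads[[paste0(pre, "b1")]] <- colSums(dZ1)
    dX1 <- dR2 + dZ1 %*% t(p[[paste0(pre, "W1")]])
    l1b <- ln_backward(dX1, p[[paste0(pre, "ln1g")]], cc$l1)
    grads[[paste0(pre, "ln1g")]] <- l1b$dg
    grads[[paste0(pre, "ln1b")]] <- l1b$db
    dR1 <- l1b$dx
    # attention
    dM <- dR1
    grads[[paste0(pre, "Wo")]] <- crossprod(cc$Hcat, dM)
    dHcat <- dM %*% t(p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, B * L, d); dK <- dQ; dV <- dQ
    for (wi in seq_len(B)) {
      rw <- rows_of(wi)
      for (h in seq_len(cfg$n_heads)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        A <- cc$A[, , h, wi]
        dHh <- dHcat[rw, cols, drop = FALSE]
        Vh <- cc$V[rw, cols, drop = FALSE]
        dA <- tcrossprod(dHh, Vh)
        dV[rw, cols] <- crossprod(A, dHh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rw, cols] <- dS %*% cc$K[rw, cols, drop = FALSE] / sqrt(dk)
        dK[rw, cols] <- crossprod(dS, cc$Q[rw, cols, drop = FALSE]) / sqrt(dk)
      }
    }
    grads[[paste0(pre, "Wq")]] <- crossprod(cc$Xin, dQ)
    grads[[paste0(pre, "Wk")]] <- crossprod(cc$Xin, dK)
    grads[[paste0(pre, "Wv")]] <- crossprod(cc$Xin, dV)
    dX <- dR1 + dQ %*% t(p[[paste0(pre, "Wq")]]) +
      dK %*% t(p[[paste0(pre, "Wk")]]) + dV %*% t(p[[paste0(pre, "Wv")]])
  }
  dtok <- rowsum(dX, group = fwd$tokidx)
  grads$tok[as.integer(rownames(dtok)), ] <- dtok
  grads$pos <- rowsum(dX, group = grp_pos)
  grads
}

#' Train the transformer encoder
#'
#' Minimises a class-weighted binary cross-entropy of the sigmoid classifier
#' with Adam.  When the dataset exceeds `max_windows`, a balanced seeded
#' subsample is used (the encoder is a feature extractor; the downstream
#' scorers see every window).
#'
#' @param dataset A `phospho_dataset` with both labels, or a character vector
#'   of peptides combined with `labels`.
#' @param labels 0/1 vector when `dataset` is a peptide vector.
#' @param config A [transformer_config()].
#' @param seed Integer seed (initialisation, subsampling, batching).
#' @param epochs,batch_size,lr Optimisation settings.
#' @param max_windows Training-subsample cap.
#' @return A trained `phos_transformer` with a `history` data.frame (per-epoch
#'   training loss).
#' @export
train_transformer <- function(dataset, labels = NULL,
                              config = transformer_config(),
                              seed = 1L, epochs = 10L, batch_size = 64L,
                              lr = 1e-3, max_windows = 2000L) {
  if (inherits(dataset, "phospho_dataset")) {
    peptides <- dataset$windows$peptide
    labels <- as.numeric(dataset$windows$label == "positive")
  } else {
    peptides <- dataset
    labels <- as.numeric(labels)
  }
  if (length(unique(labels)) < 2L) {
    stop("transformer training requires both classes")
  }
  model <- transformer_init(config, seed = seed)
  set.seed(seed + 1L)
  if (length(peptides) > max_windows) {
    pos <- which(labels == 1); neg <- which(labels == 0)
    npos <- min(length(pos), floor(max_windows / 2))
    keep <- c(sample(pos, npos), sample(neg, min(length(neg),
                                                 max_windows - npos)))
    peptides <- peptides[keep]; labels <- labels[keep]
  }
  pm <- peptides_to_matrix(peptides)
  freq <- mean(labels)
  wts <- ifelse(labels == 1, 0.5 / freq, 0.5 / (1 - freq))

  state <- list(t = 0L,
                m = lapply(model$par, function(x) x * 0),
                v = lapply(model$par, function(x) x * 0))
  history <- data.frame(epoch = integer(), train_loss = numeric())
  n <- nrow(pm)
  for (epoch in seq_len(epochs)) {
    ord <- sample(n)
    ep_loss <- 0; ep_w <- 0
    for (s in seq(1L, n, by = batch_size)) {
      bi <- ord[s:min(n, s + batch_size - 1L)]
      fwd <- tf_forward(model, pm[bi, , drop = FALSE], keep = TRUE)
      ep_loss <- ep_loss + bce_loss(fwd$score, labels[bi], wts[bi]) * sum(wts[bi])
      ep_w <- ep_w + sum(wts[bi])
      grads <- tf_backward(model, fwd, labels[bi], wts[bi])
      state$t <- state$t + 1L
      corr1 <- 1 - 0.9^state$t
      corr2 <- 1 - 0.999^state$t
      for (nm in names(model$par)) {
        g <- grads[[nm]]
        state$m[[nm]] <- 0.9 * state$m[[nm]] + 0.1 * g
        state$v[[nm]] <- 0.999 * state$v[[nm]] + 0.001 * g^2
        model$par[[nm]] <- model$par[[nm]] -
          lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + 1e-8)
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss / ep_w))
  }
  model$history <- history
  model
}

#' Contextual features, scores and attention for peptide windows
#'
#' Runs the trained encoder and returns the flattened last-block hidden
#' states (the contextual feature channel), the sigmoid phospho-score, and —
#' optionally — the `n_blocks * n_heads` attention matrices per window.
#'
#' @param model A trained `phos_transformer`.
#' @param peptides Character vector of windows.
#' @param return_attention Also return per-window attention arrays
#'   (`L x L x n_heads x B` per block); memory-heavy for large batches.
#' @param batch_size Windows per internal batch.
#' @return List with `features` (`B x (L * d_model)` matrix), `score`
#'   (vector in (0,1)), and `attention` (list over blocks, or `NULL`).
#' @export
transformer_forward <- function(model, peptides, return_attention = FALSE,
                                batch_size = 512L) {
  cfg <- model$config
  pm <- peptides_to_matrix(peptides)
  if (ncol(pm) != cfg$L) stop("window length does not match the model")
  B <- nrow(pm)
  L <- cfg$L; d <- cfg$d_model
  feats <- matrix(0, B, L * d)
  score <- numeric(B)
  attn <- if (return_attention) {
    lapply(seq_len(cfg$n_blocks), function(k) array(0, c(L, L, cfg$n_heads, B)))
  } else NULL
  for (s in seq(1L, B, by = batch_size)) {
    bi <- s:min(B, s + batch_size - 1L)
    fwd <- tf_forward(model, pm[bi, , drop = FALSE],
                      attention = return_attention)
    for (i in seq_len(L)) {
      feats[bi, ((i - 1L) * d + 1L):(i * d)] <-
        fwd$Xout[seq(i, length(bi) * L, by = L), , drop = FALSE]
    }
    score[bi] <- fwd$score
    if (return_attention) {
      for (k in seq_len(cfg$n_blocks)) attn[[k]][, , , bi] <- fwd$attn[[k]]
    }
  }
  colnames(feats) <- paste0("p", rep(seq_len(L), each = d), ".d",
                            rep(seq_len(d), L))
  list(features = feats, score = score, attention = attn)
}
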