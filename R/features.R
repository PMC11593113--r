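#' Encoder configuration for the feature channels
#'
#' Bundles the hyperparameters of the eight sequence descriptors and the GPS
#' similarity channel.  The descriptor definitions fix the dimensionalities;
#' the values here are the conventional defaults for each descriptor family
#' and are recorded in trained-model metadata.
#'
#' @param eaac_window Sliding sub-window size for EAAC.
#' @param cksaap_kmax Largest spacing `k` for CKSAAP (blocks `k = 0..kmax`).
#' @param apaac_lambda,apaac_weight Sequence-order depth and weight for APAAC.
#' @param paac_lambda,paac_weight Sequence-order depth and weight for PAAC.
#' @param distpair_max_distance Largest pair distance for DistancePair.
#' @param distpair_alphabet Alphabet for DistancePair; only `"full20"` is
#'   implemented.
#' @param gps_floor_at_zero Floor each per-peptide similarity at 0 before
#'   averaging in the GPS score.
#' @param plm_dim Embedding width of the stub protein-language-model provider.
#' @param plm_seed Seed of the stub provider's random projection.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(eaac_window = 5L, cksaap_kmax = 3L,
                           apaac_lambda = 4L, apaac_weight = 0.05,
                           paac_lambda = 4L, paac_weight = 0.05,
                           distpair_max_distance = 2L,
                           distpair_alphabet = "full20",
                           gps_floor_at_zero = TRUE,
                           plm_dim = 128L, plm_seed = 1L) {
  stopifnot(eaac_window >= 1L, cksaap_kmax >= 0L,
            apaac_lambda >= 1L, paac_lambda >= 1L,
            distpair_max_distance >= 0L)
  if (!identical(distpair_alphabet, "full20")) {
    stop("only the full 20-letter DistancePair alphabet is implemented")
  }
  structure(list(eaac_window = as.integer(eaac_window),
                 cksaap_kmax = as.integer(cksaap_kmax),
                 apaac_lambda = as.integer(apaac_lambda),
                 apaac_weight = apaac_weight,
                 paac_lambda = as.integer(paac_lambda),
                 paac_weight = paac_weight,
                 distpair_max_distance = as.integer(distpair_max_distance),
                 distpair_alphabet = distpair_alphabet,
                 gps_floor_at_zero = gps_floor_at_zero,
                 plm_dim = as.integer(plm_dim),
                 plm_seed = as.integer(plm_seed)),
            class = "encoder_config")
}

# Dimensions of every channel for a given window length, without encoding.
#' Feature-channel dimensions
#'
#' @param config An [encoder_config()].
#' @param flank_n Flank size per side of the peptide window.
#' @param transformer_dim,plm_dim Widths of the two contextual channels
#'   (flattened transformer hidden states; PLM embedding).
#' @return Named integer vector over the fixed channel registry order.
#' @export
feature_dims <- function(config = encoder_config(), flank_n = 10L,
                         transformer_dim = NA_integer_,
                         plm_dim = config$plm_dim) {
  L <- 2L * flank_n + 1L
  c(APAAC = 20L + 2L * config$apaac_lambda,
    CKSAAP = 400L * (config$cksaap_kmax + 1L),
    CTDC = 39L,
    DDE = 400L,
    DistancePair = 20L + 400L * config$distpair_max_distance,
    EAAC = (L - config$eaac_window + 1L) * 20L,
    PAAC = 20L + config$paac_lambda,
    GPS = 1L,
    TRANSFORMER = as.integer(transformer_dim),
    PLM = as.integer(plm_dim))
}

aa_pair_names <- function(prefix) {
  as.vector(t(outer(AA_ALPHABET, AA_ALPHABET,
                    function(a, b) paste0(prefix, a, b))))
}

# Per-row frequency table of ordered residue pairs (left col i, right col
# i + gap + 1), normalised by the number of valid (non-"*") pairs in the row.
pair_block <- function(pm, gap) {
  L <- ncol(pm)
  B <- nrow(pm)
  li <- seq_len(L - gap - 1L)
  a <- pm[, li, drop = FALSE]
  b <- pm[, li + gap + 1L, drop = FALSE]
  valid <- a <= 20L & b <= 20L
  code <- (a - 1L) * 20L + b
  code[!valid] <- NA_integer_
  out <- matrix(0, B, 400L)
  for (r in seq_len(B)) {
    v <- code[r, ]
    v <- v[!is.na(v)]
    if (length(v)) out[r, ] <- tabulate(v, 400L) / length(v)
  }
  out
}

#' Enhanced amino-acid composition (EAAC)
#'
#' Frequencies of the 20 amino acids inside every sliding sub-window of size
#' `eaac_window`; `"*"` counts as nothing, and the denominator is the
#' sub-window size, so padded sub-windows sum to less than 1.
#'
#' @param peptides Character vector of equal-length peptide windows.
#' @param config An [encoder_config()].
#' @return Numeric matrix, one row per peptide, `(L - w + 1) * 20` columns.
#' @export
encode_eaac <- function(peptides, config = encoder_config()) {
  pm <- peptides_to_matrix(peptides)
  L <- ncol(pm)
  w <- config$eaac_window
  if (w > L) stop("eaac_window exceeds the window length")
  nwin <- L - w + 1L
  # banded 0/1 matrix summing w consecutive positions
  band <- matrix(0, L, nwin)
  for (s in seq_len(nwin)) band[s:(s + w - 1L), s] <- 1
  out <- matrix(0, nrow(pm), nwin * 20L)
  for (a in seq_len(20L)) {
    cnt <- (pm == a) %*% band / w
    out[, (seq_len(nwin) - 1L) * 20L + a] <- cnt
  }
  colnames(out) <- as.vector(t(outer(seq_len(nwin), AA_ALPHABET,
                                     function(s, aa) sprintf("w%02d.%s", s, aa))))
  out
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each spacing `k = 0..kmax`, frequencies of the 400 ordered residue
#' pairs separated by exactly `k` positions; pairs touching `"*"` are skipped
#' and each k-block is normalised by its count of valid pairs.
#'
#' @inheritParams encode_eaac
#' @return Numeric matrix with `400 * (kmax + 1)` columns.
#' @export
encode_cksaap <- function(peptides, config = encoder_config()) {
  pm <- peptides_to_matrix(peptides)
  kmax <- config$cksaap_kmax
  if (kmax >= ncol(pm) - 1L) stop("cksaap_kmax too large for the window")
  blocks <- lapply(0:kmax, function(k) pair_block(pm, k))
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(0:kmax, function(k)
    aa_pair_names(paste0("k", k, "."))))
  out
}

#' Composition descriptor of the C/T/D family (CTDC)
#'
#' For each of 13 physicochemical partitions of the 20 amino acids into 3
#' classes, the fraction of non-`"*"` residues in each class (39 values).
#'
#' @inheritParams encode_eaac
#' @return Numeric matrix with 39 columns; each attribute's 3 fractions sum
#'   to 1.
#' @export
encode_ctdc <- function(peptides, config = encoder_config()) {
  pm <- peptides_to_matrix(peptides)
  n_res <- rowSums(pm <= 20L)
  out <- matrix(0, nrow(pm), 39L)
  cn <- character(39L)
  for (t in seq_along(CTDC_GROUPS)) {
    groups <- CTDC_GROUPS[[t]]
    map <- rep(NA_integer_, 21L)
    for (g in 1:3) {
      map[match(strsplit(groups[g], "")[[1]], AA_ALPHABET)] <- g
    }
    cls <- matrix(map[pm], nrow(pm))
    for (g in 1:3) {
      out[, (t - 1L) * 3L + g] <- rowSums(cls == g, na.rm = TRUE) / n_res
      cn[(t - 1L) * 3L + g] <- paste0(names(CTDC_GROUPS)[t], ".g", g)
    }
  }
  colnames(out) <- cn
  out
}

#' Dipeptide deviation from expected mean (DDE)
#'
#' For each of the 400 dipeptides, the deviation of its observed frequency
#' among valid adjacent pairs from the theoretical mean implied by codon
#' multiplicities, standardised by the theoretical variance:
#' `DDE = (Dc - Tm) / sqrt(Tm (1 - Tm) / P)` with
#' `Tm = (C_i / 61)(C_j / 61)` and `P` the number of valid adjacent pairs.
#'
#' @inheritParams encode_eaac
#' @return Numeric matrix with 400 columns.
#' @export
encode_dde <- function(peptides, config = encoder_config()) {
  pm <- peptides_to_matrix(peptides)
  a <- pm[, -ncol(pm), drop = FALSE]
  b <- pm[, -1L, drop = FALSE]
  valid <- a <= 20L & b <= 20L
  P <- rowSums(valid)
  if (any(P == 0L)) stop("window has no valid adjacent residue pair")
  dc <- pair_block(pm, 0L)
  cf <- AA_CODON_COUNT[AA_ALPHABET] / 61
  tm <- as.vector(t(outer(cf, cf)))        # ordered (i, j), row-major in i
  tv <- outer(1 / P, tm * (1 - tm))        # B x 400
  out <- (dc - matrix(tm, nrow(pm), 400L, byrow = TRUE)) / sqrt(tv)
  colnames(out) <- aa_pair_names("")
  out
}

# Shared core of APAAC/PAAC: composition terms + weighted sequence-order
# terms, normalised so all components sum to 1.  `tau_fun(chars_idx)` returns
# the sequence-order terms for one compressed (non-"*") residue index vector.
pseaac_core <- function(peptides, lambda, weight, tau_fun, tau_names) {
  pm <- peptides_to_matrix(peptides)
  B <- nrow(pm)
  out <- matrix(0, B, 20L + length(tau_names))
  for (r in seq_len(B)) {
    idx <- pm[r, ]
    idx <- idx[idx <= 20L]
    if (length(idx) <= lambda) {
      stop("lambda (", lambda, ") must be smaller than the number of residues")
    }
    f <- tabulate(idx, 20L) / length(idx)
    tau <- tau_fun(idx)
    denom <- sum(f) + weight * sum(tau)
    out[r, ] <- c(f, weight * tau) / denom
  }
  colnames(out) <- c(AA_ALPHABET, tau_names)
  out
}

#' Amphiphilic pseudo-amino-acid composition (APAAC)
#'
#' 20 composition terms plus `2 * lambda` amphiphilic correlation terms built
#' from the normalised hydrophobicity and hydrophilicity scales; `"*"`
#' positions are removed by compressing the window to its residue
#' subsequence before computing correlations.
#'
#' @inheritParams encode_eaac
#' @return Numeric matrix with `20 + 2 * lambda` columns summing to 1 per row.
#' @export
encode_apaac <- function(peptides, config = encoder_config()) {
  lambda <- config$apaac_lambda
  h1 <- normalise_property(AA_HYDROPHOBICITY)
  h2 <- normalise_property(AA_HYDROPHILICITY)
  tau_fun <- function(idx) {
    L <- length(idx)
    unlist(lapply(seq_len(lambda), function(k) {
      i <- seq_len(L - k)
      c(mean(h1[idx[i]] * h1[idx[i + k]]),
        mean(h2[idx[i]] * h2[idx[i + k]]))
    }))
  }
  nm <- as.vector(t(outer(seq_len(lambda), c("H1", "H2"),
                          function(k, p) paste0("tau", k, ".", p))))
  pseaac_core(peptides, lambda, config$apaac_weight, tau_fun, nm)
}

#' Pseudo-amino-acid composition (PAAC)
#'
#' 20 composition terms plus `lambda` sequence-order terms from the
#' squared-difference coupling of normalised hydrophobicity, hydrophilicity
#' and side-chain mass.
#'
#' @inheritParams encode_eaac
#' @return Numeric matrix with `20 + lambda` columns summing to 1 per row.
#' @export
encode_paac <- function(peptides, config = encoder_config()) {
  lambda <- config$paac_lambda
  h1 <- normalise_property(AA_HYDROPHOBICITY)
  h2 <- normalise_property(AA_HYDROPHILICITY)
  m <- normalise_property(AA_SIDECHAIN_MASS)
  tau_fun <- function(idx) {
    L <- length(idx)
    vapply(seq_len(lambda), function(k) {
      i <- seq_len(L - k)
      mean(((h1[idx[i]] - h1[idx[i + k]])^2 +
              (h2[idx[i]] - h2[idx[i + k]])^2 +
              (m[idx[i]] - m[idx[i + k]])^2) / 3)
    }, numeric(1))
  }
  pseaac_core(peptides, lambda, config$paac_weight, tau_fun,
              paste0("theta", seq_len(lambda)))
}

#' Distance-pair composition (DistancePair)
#'
#' Single-letter frequencies (distance 0) plus ordered pair frequencies at
#' distances `1..max_distance`; `"*"`-touching pairs are skipped and each
#' distance block is normalised separately.
#'
#' @inheritParams encode_eaac
#' @return Numeric matrix with `20 + 400 * max_distance` columns.
#' @export
encode_distancepair <- function(peptides, config = encoder_config()) {
  d <- config$distpair_max_distance
  pm <- peptides_to_matrix(peptides)
  if (d >= ncol(pm)) stop("distpair_max_distance too large for the window")
  n_res <- rowSums(pm <= 20L)
  singles <- matrix(0, nrow(pm), 20L)
  for (a in seq_len(20L)) singles[, a] <- rowSums(pm == a) / n_res
  blocks <- if (d >= 1L) {
    lapply(seq_len(d), function(k) pair_block(pm, k - 1L))
  } else {
    list()
  }
  out <- do.call(cbind, c(list(singles), blocks))
  colnames(out) <- c(paste0("d0.", AA_ALPHABET),
                     unlist(lapply(seq_len(d), function(k)
                       aa_pair_names(paste0("d", k, ".")))))
  out
}

#' Group-based peptide similarity score (GPS channel)
#'
#' The score of a query window is the average substitution-matrix similarity
#' to a set of known positive windows:
#' `score = mean_q sum_i S(w_i, q_i)`, where positions at which either symbol
#' is `"*"` contribute 0, and (by default) each per-peptide similarity is
#' floored at 0 before averaging.  When encoding training positives the
#' window's own entry can be excluded (leave-one-out) to avoid leakage.
#'
#' @param peptides Character vector of query windows.
#' @param positive_peptides Character vector of positive windows (all the same
#'   length as the queries).
#' @param config An [encoder_config()] (`gps_floor_at_zero` is honoured).
#' @param sub_matrix 20x20 substitution matrix; defaults to the BLOSUM62 copy
#'   shipped with the package.
#' @param exclude_self Leave-one-out removal of the query itself from the
#'   positive set.
#' @param self_index Optional integer vector (NA-padded) giving, for each
#'   query, its own index in `positive_peptides`; when `exclude_self = TRUE`
#'   and this is `NULL`, queries are matched to positives by string equality.
#' @return One-column numeric matrix of scores.
#' @export
gps_score <- function(peptides, positive_peptides,
                      config = encoder_config(),
                      sub_matrix = NULL,
                      exclude_self = FALSE, self_index = NULL) {
  if (is.null(sub_matrix)) sub_matrix <- default_substitution_matrix()
  if (length(positive_peptides) == 0L) stop("empty positive set")
  if (exclude_self && is.null(self_index)) {
    self_index <- match(peptides, positive_peptides)
  }
  if (exclude_self && length(positive_peptides) == 1L &&
      any(!is.na(self_index))) {
    stop("positive set is empty after self-exclusion")
  }
  # extend to 21x21 with zero row/col for the padding symbol
  M21 <- matrix(0, 21L, 21L)
  M21[1:20, 1:20] <- sub_matrix[AA_ALPHABET, AA_ALPHABET]
  qm <- peptides_to_matrix(positive_peptides)
  pm <- peptides_to_matrix(peptides)
  L <- ncol(pm)
  P <- nrow(qm)
  B <- nrow(pm)
  scores <- numeric(B)
  chunk <- max(1L, floor(2e6 / P))
  for (s in seq(1L, B, by = chunk)) {
    rows <- s:min(B, s + chunk - 1L)
    S <- matrix(0, length(rows), P)
    for (j in seq_len(L)) {
      S <- S + M21[pm[rows, j], , drop = FALSE][, qm[, j], drop = FALSE]
    }
    if (config$gps_floor_at_zero) S[S < 0] <- 0
    tot <- rowSums(S)
    np <- rep(P, length(rows))
    if (!is.null(self_index)) {
      si <- self_index[rows]
      has_self <- !is.na(si)
      if (any(has_self)) {
        tot[has_self] <- tot[has_self] -
          S[cbind(which(has_self), si[has_self])]
        np[has_self] <- P - 1L
      }
    }
    if (any(np == 0L)) stop("positive set is empty after self-exclusion")
    scores[rows] <- tot / np
  }
  matrix(scores, ncol = 1L, dimnames = list(NULL, "GPS"))
}

#' Encode peptide windows on the eight sequence channels
#'
#' Convenience wrapper running APAAC, CKSAAP, CTDC, DDE, DistancePair, EAAC
#' and PAAC, plus the GPS channel when a positive set is supplied.  The two
#' contextual channels (TRANSFORMER, PLM) are produced by
#' [transformer_forward()] and [plm_embed()].
#'
#' @param peptides Character vector of windows.
#' @param config An [encoder_config()].
#' @param gps_positives Optional positive windows for the GPS channel.
#' @param gps_exclude_self,gps_self_index Passed to [gps_score()].
#' @param sub_matrix Optional substitution matrix for GPS.
#' @return Named list of numeric matrices, in registry order.
#' @export
encode_sequence_features <- function(peptides, config = encoder_config(),
                                     gps_positives = NULL,
                                     gps_exclude_self = FALSE,
                                     gps_self_index = NULL,
                                     sub_matrix = NULL) {
  out <- list(
    APAAC = encode_apaac(peptides, config),
    CKSAAP = encode_cksaap(peptides, config),
    CTDC = encode_ctdc(peptides, config),
    DDE = encode_dde(peptides, config),
    DistancePair = encode_distancepair(peptides, config),
    EAAC = encode_eaac(peptides, config),
    PAAC = encode_paac(peptides, config))
  if (!is.null(gps_positives)) {
    out$GPS <- gps_score(peptides, gps_positives, config,
                         sub_matrix = sub_matrix,
                         exclude_self = gps_exclude_self,
                         self_index = gps_self_index)
  }
  out
}
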