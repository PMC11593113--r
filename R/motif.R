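# Motif patterns and enrichment statistics.
#
# Motif grammar: dash-separated tokens, one per consecutive position, with
# "/" alternation and "X" as wildcard.  The phospho-acceptor token is marked
# with a "p" prefix (e.g. "R-X-X-pS/pT-L/I/V"); without any "p" marker the
# first token that is a subset of {S,T,Y}, then {H}, then {R,K} is taken as
# the centre.  Token offsets are read relative to the centre, so
# "R-X-X-pS/pT-L/I/V" places R at -3 and L/I/V at +1.

#' Parse a motif pattern
#'
#' @param text Pattern string, e.g. `"R-X-X-pS/pT-L/I/V"`.
#' @return A `motif_pattern`: list with `offsets` (integer), `tokens` (list of
#'   residue-set character vectors; wildcards are dropped), `center` (residue
#'   set of the acceptor) and `text`.
#' @export
parse_motif <- function(text) {
  raw <- strsplit(trimws(text), "-", fixed = TRUE)[[1]]
  if (!length(raw)) stop("empty motif pattern")
  toks <- lapply(raw, function(t) strsplit(t, "/", fixed = TRUE)[[1]])
  is_marked <- vapply(toks, function(t) any(grepl("^p", t)), logical(1))
  toks <- lapply(toks, function(t) toupper(sub("^p", "", t)))
  ok <- vapply(toks, function(t) all(t %in% c(AA_ALPHABET, "X")), logical(1))
  if (!all(ok)) stop("motif token outside the amino-acid alphabet in: ", text)
  center_i <- if (any(is_marked)) {
    which(is_marked)[1]
  } else {
    cand <- which(vapply(toks, function(t) all(t %in% O_RESIDUES), logical(1)))
    if (!length(cand)) {
      cand <- which(vapply(toks, function(t) identical(t, "H"), logical(1)))
    }
    if (!length(cand)) {
      cand <- which(vapply(toks, function(t) all(t %in% c("R", "K")),
                           logical(1)))
    }
    if (!length(cand)) stop("cannot locate the acceptor token in: ", text)
    cand[1]
  }
  center <- toks[[center_i]]
  if (any(center == "X") || !all(center %in% PHOSPHO_RESIDUES)) {
    stop("acceptor token must be a set of phosphorylatable residues in: ",
         text)
  }
  offsets <- seq_along(toks) - center_i
  keep <- vapply(toks, function(t) !identical(t, "X"), logical(1))
  n_informative <- sum(keep) - 1L  # besides the centre
  structure(list(offsets = offsets[keep], tokens = toks[keep],
                 center = center, n_informative = n_informative,
                 text = text),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern:", x$text, "(centre {",
      paste(x$center, collapse = "/"), "})\n")
  invisible(x)
}

#' Match peptide windows against a motif pattern
#'
#' A window matches iff every non-wildcard token's residue set contains the
#' window symbol at that offset (offsets relative to the centre); the padding
#' symbol `"*"` never matches a residue set.
#'
#' @param peptides Character vector of windows (odd length `2n + 1`).
#' @param pattern A `motif_pattern` (or a string, parsed on the fly).
#' @return Logical vector.
#' @export
motif_match <- function(peptides, pattern) {
  if (is.character(pattern)) pattern <- parse_motif(pattern)
  pm <- peptides_to_matrix(peptides)
  L <- ncol(pm)
  n <- (L - 1L) %/% 2L
  if (any(abs(pattern$offsets) > n)) {
    stop("pattern offsets exceed the window flank (", n, ")")
  }
  hit <- rep(TRUE, nrow(pm))
  for (i in seq_along(pattern$offsets)) {
    col <- n + 1L + pattern$offsets[i]
    allowed <- match(pattern$tokens[[i]], AA_ALPHABET)
    hit <- hit & (pm[, col] %in% allowed)
  }
  hit
}

#' Motif enrichment ratio
#'
#' `E-ratio = (m/M) / (n/N)`: prevalence of the motif among positives
#' relative to its prevalence among all windows.
#'
#' @param N All windows; `n` windows containing the motif; `M` positive
#'   windows; `m` positive windows containing the motif.
#' @param n,M,m See above.
#' @return Numeric ratio (0 when `m = 0`).
#' @export
e_ratio <- function(N, n, M, m) {
  if (N <= 0 || n <= 0 || M <= 0) stop("N, n and M must be positive")
  (m / M) / (n / N)
}

#' Upper-tail hypergeometric p-value
#'
#' Exact tail probability `sum_{m' = m}^{min(n, M)} C(M, m') C(N - M, n - m')
#' / C(N, n)` computed with log-binomial coefficients.  This is the
#' probability of drawing at least `m` motif-containing positives when `n`
#' motif windows are distributed at random among `N` windows of which `M`
#' are positive.
#'
#' @inheritParams e_ratio
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_p <- function(N, n, M, m) {
  if (any(c(N, n, M, m) < 0) || n > N || M > N || m > min(n, M)) {
    stop("invalid hypergeometric counts (need m <= min(n, M), n <= N, M <= N)")
  }
  mprime <- m:min(n, M)
  terms <- lchoose(M, mprime) + lchoose(N - M, n - mprime) - lchoose(N, n)
  p <- sum(exp(terms))
  min(max(p, 0), 1)
}

#' Scan a dataset for enriched motifs
#'
#' For each pattern: `N` = all windows, `n` = windows matching, `M` =
#' positives, `m` = positives matching; reports the E-ratio and the
#' upper-tail hypergeometric p-value, and flags patterns with E-ratio > 1
#' and `p < alpha`.  Patterns absent from every window are reported with
#' `n = 0` and a note.  A Benjamini-Hochberg adjusted column is included for
#' convenience; the `enriched` flag uses the raw p-values.
#'
#' @param dataset A `phospho_dataset`.
#' @param patterns List of `motif_pattern`s or pattern strings.
#' @param alpha Significance level on the raw p-value (default 0.01).
#' @return data.frame, one row per pattern, with counts, `e_ratio`,
#'   `p_value`, `p_adjust`, `enriched`, `note`.
#' @export
enrichment_scan <- function(dataset, patterns, alpha = 0.01) {
  if (is.character(patterns)) patterns <- as.list(patterns)
  patterns <- lapply(patterns, function(p)
    if (is.character(p)) parse_motif(p) else p)
  peptides <- dataset$windows$peptide
  pos <- dataset$windows$label == "positive"
  N <- length(peptides)
  M <- sum(pos)
  rows <- lapply(patterns, function(pat) {
    hit <- motif_match(peptides, pat)
    n <- sum(hit)
    m <- sum(hit & pos)
    if (n == 0L) {
      data.frame(pattern = pat$text, N = N, n = 0L, M = M, m = 0L,
                 e_ratio = NA_real_, p_value = NA_real_,
                 note = "absent from all windows", stringsAsFactors = FALSE)
    } else {
      data.frame(pattern = pat$text, N = N, n = n, M = M, m = m,
                 e_ratio = e_ratio(N, n, M, m),
                 p_value = hypergeom_p(N, n, M, m),
                 note = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- !is.na(out$e_ratio) & out$e_ratio > 1 &
    !is.na(out$p_value) & out$p_value < alpha
  out[order(out$p_value), , drop = FALSE]
}

#' Read a motif catalogue file
#'
#' One pattern per line; `#` comments and blank lines are ignored.
#'
#' @param path Path to a catalogue file; defaults to the catalogue shipped
#'   with the package.
#' @return List of `motif_pattern`s.
#' @export
read_motif_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motif_catalogue.txt",
                        package = "prokphos")
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_motif)
}

#' Attention-derived motif weight matrices
#'
#' Runs the trained encoder over positive windows and derives (a) the mean
#' attention matrix per block/head plus a grand mean, each min-max scaled to
#' `[0, 1]`, and (b) an amino-acid x position matrix: for each offset and
#' residue type, the grand-mean attention from the centre position to
#' positions carrying that residue, summed over the positive windows, then
#' min-max scaled.  High cells mark residue/position combinations the encoder
#' attends to — candidate motif anchors.
#'
#' @param model A trained `phos_transformer`.
#' @param positives Character vector of positive windows (>= 1).
#' @param batch_size Windows per internal batch.
#' @return List with `position_matrices` (list `b<k>.h<j>` + `grand` of
#'   `L x L` matrices), `aa_position_matrix` (`20 x L`, offset column names),
#'   and `diagonal_dominance` (share of rows of the unscaled grand mean whose
#'   maximum is the diagonal — reported, not asserted).
#' @export
attention_motif_weights <- function(model, positives, batch_size = 256L) {
  if (!length(positives)) stop("no positive windows supplied")
  cfg <- model$config
  L <- cfg$L
  ctr <- cfg$flank_n + 1L
  pm <- peptides_to_matrix(positives)
  sum_bh <- lapply(seq_len(cfg$n_blocks * cfg$n_heads),
                   function(i) matrix(0, L, L))
  aa_sum <- matrix(0, 20L, L, dimnames = list(
    AA_ALPHABET, paste0("off", seq_len(L) - ctr)))
  B <- nrow(pm)
  for (s in seq(1L, B, by = batch_size)) {
    bi <- s:min(B, s + batch_size - 1L)
    fwd <- tf_forward(model, pm[bi, , drop = FALSE], attention = TRUE)
    grand_batch <- matrix(0, L, L)
    per_window_center <- matrix(0, length(bi), L)
    for (k in seq_len(cfg$n_blocks)) {
      for (h in seq_len(cfg$n_heads)) {
        idx <- (k - 1L) * cfg$n_heads + h
        slab <- fwd$attn[[k]][, , h, , drop = FALSE]
        sum_bh[[idx]] <- sum_bh[[idx]] + apply(slab, c(1, 2), sum)
        per_window_center <- per_window_center +
          t(slab[ctr, , 1L, ]) / (cfg$n_blocks * cfg$n_heads)
      }
    }
    # accumulate centre-row attention by the residue present at each offset
    for (j in seq_len(L)) {
      sym <- pm[bi, j]
      keep <- sym <= 20L
      if (any(keep)) {
        s <- rowsum(per_window_center[keep, j], group = sym[keep])
        idx <- as.integer(rownames(s))
        aa_sum[idx, j] <- aa_sum[idx, j] + s[, 1L]
      }
    }
  }
  minmax <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(x * 0)
    (x - r[1]) / (r[2] - r[1])
  }
  names(sum_bh) <- paste0("b", rep(seq_len(cfg$n_blocks),
                                   each = cfg$n_heads),
                          ".h", rep(seq_len(cfg$n_heads), cfg$n_blocks))
  grand <- Reduce(`+`, sum_bh) / length(sum_bh) / B
  position_matrices <- c(lapply(sum_bh, function(m) minmax(m / B)),
                         list(grand = minmax(grand)))
  diag_dom <- mean(apply(grand, 1L, which.max) == seq_len(L))
  list(position_matrices = position_matrices,
       aa_position_matrix = minmax(aa_sum),
       diagonal_dominance = diag_dom)
}

#' Read a region interval table
#'
#' BED-like TSV with header `protein_id  start  end  kind`, 1-based inclusive
#' coordinates; intervals are normalised to sorted, non-overlapping half-open
#' `[start, end)` form per protein.
#'
#' @param path Path to the TSV.
#' @return A `region_set`: data.frame `protein_id`, `start`, `end` (half-open),
#'   `kind`.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "start", "end") %in% names(df)))
  if (is.null(df$kind)) df$kind <- "region"
  normalise_regions(df)
}

#' Normalise region intervals
#'
#' Converts 1-based inclusive `[start, end]` intervals to sorted,
#' non-overlapping half-open `[start, end)` intervals per protein (merging
#' overlaps and adjacencies).
#'
#' @param regions data.frame with `protein_id`, `start`, `end`, optional
#'   `kind`.
#' @return Normalised data.frame of class `region_set`.
#' @export
normalise_regions <- function(regions) {
  if (is.null(regions$kind)) regions$kind <- "region"
  regions$end <- regions$end + 1L  # to half-open
  out <- do.call(rbind, lapply(split(regions, regions$protein_id),
                               function(g) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    merged <- g[1, , drop = FALSE]
    if (nrow(g) > 1L) {
      for (i in 2:nrow(g)) {
        last <- nrow(merged)
        if (g$start[i] <= merged$end[last]) {
          merged$end[last] <- max(merged$end[last], g$end[i])
        } else {
          merged <- rbind(merged, g[i, , drop = FALSE])
        }
      }
    }
    merged
  }))
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}

in_regions <- function(protein_id, position, regions) {
  hit <- logical(length(protein_id))
  for (i in seq_along(protein_id)) {
    g <- regions[regions$protein_id == protein_id[i], , drop = FALSE]
    hit[i] <- any(g$start <= position[i] & position[i] < g$end)
  }
  hit
}

#' Site-in-region enrichment test
#'
#' Hypergeometric test of whether predicted sites fall inside the supplied
#' regions more often than expected: `N` = candidate universe size, `n` =
#' universe residues inside regions, `M` = predicted sites, `m` = predicted
#' sites inside regions.
#'
#' @param predicted_sites data.frame (`protein_id`, `position`) of predicted
#'   sites.
#' @param regions A `region_set` (see [read_regions()]).
#' @param universe data.frame (`protein_id`, `position`) of all candidate
#'   residues considered (must contain the predicted sites).
#' @return List with the four counts, `e_ratio` and `p_value`.
#' @export
region_enrichment <- function(predicted_sites, regions, universe) {
  if (nrow(universe) == 0L) stop("empty candidate universe")
  N <- nrow(universe)
  in_u <- in_regions(universe$protein_id, universe$position, regions)
  n <- sum(in_u)
  M <- nrow(predicted_sites)
  in_p <- in_regions(predicted_sites$protein_id, predicted_sites$position,
                     regions)
  m <- sum(in_p)
  list(N = N, n = n, M = M, m = m,
       e_ratio = if (n > 0 && M > 0) e_ratio(N, n, M, m) else NA_real_,
       p_value = hypergeom_p(N, n, M, m))
}
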