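#' Extract a residue-centred peptide window
#'
#' Returns the `PSP(n, n)` peptide around `position`: the central residue with
#' `n` residues on each side, padded with `"*"` where the window runs past the
#' protein termini.
#'
#' @param sequence Protein sequence (already sanitized).
#' @param position 1-based residue position.
#' @param n Number of flanking residues per side (default 10).
#' @return Character scalar of length `2n + 1`.
#' @export
extract_window <- function(sequence, position, n = 10L) {
  L <- nchar(sequence)
  if (position < 1L || position > L) {
    stop("position ", position, " out of range 1..", L)
  }
  left <- max(1L, position - n)
  right <- min(L, position + n)
  core <- substr(sequence, left, right)
  pad_l <- strrep(PAD_SYMBOL, n - (position - left))
  pad_r <- strrep(PAD_SYMBOL, n - (right - position))
  paste0(pad_l, core, pad_r)
}

#' Build a labelled peptide-window dataset
#'
#' Positives are windows centred on the listed phosphosites whose residue is
#' in `residue_set`; negatives are windows at every other occurrence of those
#' residues within the same proteins.  Every site must match its protein's
#' sequence.
#'
#' @param proteins data.frame with `id`, `sequence`, `species` and optionally
#'   `timestamp` columns (see [read_fasta()]).
#' @param sites data.frame of phosphosites (see [read_sites()]).
#' @param n Flank size per side (default 10).
#' @param residue_set Subset of `c("S","T","Y","H","R","K")`.
#' @param provenance Free-text provenance note.
#' @return A `phospho_dataset`: list with `windows` (data.frame of
#'   `protein_id`, `position`, `residue`, `peptide`, `label`, `species`,
#'   `timestamp`), `flank_n`, `residue_set`, `provenance`.
#' @export
build_dataset <- function(proteins, sites, n = 10L,
                          residue_set = O_RESIDUES,
                          provenance = "") {
  stopifnot(all(residue_set %in% PHOSPHO_RESIDUES))
  unknown <- setdiff(sites$protein_id, proteins$id)
  if (length(unknown)) {
    stop("site(s) reference unknown protein(s): ",
         paste(utils::head(unique(unknown), 5), collapse = ", "))
  }
  prot_idx <- match(sites$protein_id, proteins$id)
  actual <- substr(proteins$sequence[prot_idx], sites$position, sites$position)
  bad <- actual != sites$residue
  if (any(bad)) {
    i <- which(bad)[1]
    stop("site record ", sites$protein_id[i], ":", sites$position[i],
         " claims residue ", sites$residue[i], " but sequence has ", actual[i])
  }

  sites <- sites[sites$residue %in% residue_set, , drop = FALSE]
  pos_key <- paste(sites$protein_id, sites$position)

  prot_ts <- if (!is.null(proteins$timestamp)) {
    as.Date(proteins$timestamp)
  } else {
    as.Date(rep(NA, nrow(proteins)))
  }

  out <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    seq_i <- proteins$sequence[i]
    chars <- strsplit(seq_i, "", fixed = TRUE)[[1]]
    cand <- which(chars %in% residue_set)
    if (!length(cand)) next
    peptides <- vapply(cand, function(p) extract_window(seq_i, p, n),
                       character(1))
    key <- paste(proteins$id[i], cand)
    is_pos <- key %in% pos_key
    ts <- prot_ts[i]
    if (is.na(ts) && any(is_pos)) {
      site_ts <- sites$timestamp[match(key[is_pos], pos_key)]
      if (!all(is.na(site_ts))) ts <- min(site_ts, na.rm = TRUE)
    }
    out[[i]] <- data.frame(
      protein_id = proteins$id[i],
      position = cand,
      residue = chars[cand],
      peptide = peptides,
      label = ifelse(is_pos, "positive", "negative"),
      species = proteins$species[i],
      timestamp = ts,
      stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(windows)) {
    windows <- data.frame(protein_id = character(), position = integer(),
                          residue = character(), peptide = character(),
                          label = character(), species = character(),
                          timestamp = as.Date(character()),
                          stringsAsFactors = FALSE)
  }
  new_dataset(windows, flank_n = as.integer(n), residue_set = residue_set,
              provenance = provenance)
}

new_dataset <- function(windows, flank_n, residue_set, provenance = "") {
  rownames(windows) <- NULL
  structure(list(windows = windows, flank_n = as.integer(flank_n),
                 residue_set = residue_set, provenance = provenance),
            class = "phospho_dataset")
}

#' @export
print.phospho_dataset <- function(x, ...) {
  tab <- table(factor(x$windows$label,
                      levels = c("positive", "negative", "unlabeled")))
  cat("phospho_dataset: ", nrow(x$windows), " windows (",
      tab[["positive"]], " positive / ", tab[["negative"]], " negative), ",
      "PSP(", x$flank_n, ",", x$flank_n, "), residues {",
      paste(x$residue_set, collapse = ","), "}\n", sep = "")
  invisible(x)
}

# Fractional identity between two aligned peptides: matches at positions where
# both symbols are residues, divided by the number of such compared positions.
# Windows with no comparable positions have identity 0.
peptide_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  comp <- ca != PAD_SYMBOL & cb != PAD_SYMBOL
  if (!any(comp)) return(0)
  sum(ca[comp] == cb[comp]) / sum(comp)
}

#' Reduce peptide redundancy by greedy identity filtering
#'
#' Windows are scanned in a deterministic order (earliest timestamp, then
#' `protein_id`, then `position`); a window is kept iff its fractional peptide
#' identity to every already-kept window of the same label does not exceed
#' `identity_threshold`.  Exact duplicate peptides of the same label always
#' collapse to the earliest-scanned copy, so at `identity_threshold = 1` the
#' filter only removes exact duplicates.  Alternatively a precomputed cluster
#' table (see [read_cluster_file()]) restricts the dataset to cluster
#' representatives, reproducing an external clustering run.
#'
#' @param dataset A `phospho_dataset`.
#' @param identity_threshold Fraction in (0, 1]; published protocols use 0.4
#'   (routine) or 0.25 (stringent).
#' @param clusters Optional data.frame from [read_cluster_file()]; when given,
#'   the greedy reducer is skipped and only windows on representative proteins
#'   are kept.
#' @return A reduced `phospho_dataset`.
#' @export
reduce_redundancy <- function(dataset, identity_threshold = 0.4,
                              clusters = NULL) {
  w <- dataset$windows
  if (!is.null(clusters)) {
    keep <- w$protein_id %in% clusters$representative_id
    return(new_dataset(w[keep, , drop = FALSE], dataset$flank_n,
                       dataset$residue_set,
                       paste0(dataset$provenance, " | external clusters")))
  }
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(w) == 0L) return(dataset)
  ts <- w$timestamp
  ts_key <- ifelse(is.na(ts), Inf, as.numeric(ts))
  ord <- order(ts_key, w$protein_id, w$position)
  w <- w[ord, , drop = FALSE]

  pm <- peptides_to_matrix(w$peptide)
  pad_idx <- length(AA_PAD_ALPHABET)
  keep <- logical(nrow(w))
  kept_by_label <- list()
  for (i in seq_len(nrow(w))) {
    lab <- w$label[i]
    kept <- kept_by_label[[lab]]
    ok <- TRUE
    if (length(kept)) {
      vi <- pm[i, ]
      sub <- pm[kept, , drop = FALSE]
      comp <- sweep(sub != pad_idx, 2, vi != pad_idx, `&`)
      eqs <- sweep(sub, 2, vi, `==`) & comp
      n_comp <- rowSums(comp)
      ident <- ifelse(n_comp == 0, 0, rowSums(eqs) / n_comp)
      exact_dup <- w$peptide[kept] == w$peptide[i]
      ok <- all(ident <= identity_threshold) && !any(exact_dup)
    }
    if (ok) {
      keep[i] <- TRUE
      kept_by_label[[lab]] <- c(kept, i)
    }
  }
  new_dataset(w[keep, , drop = FALSE], dataset$flank_n, dataset$residue_set,
              paste0(dataset$provenance, " | reduced@", identity_threshold))
}

#' Split a dataset into train/test by timestamp
#'
#' Train = windows dated strictly before `cutoff_date`; test = the rest.
#' Every window must carry a timestamp.
#'
#' @param dataset A `phospho_dataset`.
#' @param cutoff_date A `Date` (or string coercible to one).
#' @return Named list `train`, `test` of `phospho_dataset`s.
#' @export
split_by_timestamp <- function(dataset, cutoff_date) {
  cutoff_date <- as.Date(cutoff_date)
  ts <- dataset$windows$timestamp
  if (anyNA(ts)) stop("all windows must carry a timestamp for a time split")
  pre <- ts < cutoff_date
  list(
    train = new_dataset(dataset$windows[pre, , drop = FALSE],
                        dataset$flank_n, dataset$residue_set,
                        paste0(dataset$provenance, " | train<", cutoff_date)),
    test = new_dataset(dataset$windows[!pre, , drop = FALSE],
                       dataset$flank_n, dataset$residue_set,
                       paste0(dataset$provenance, " | test>=", cutoff_date)))
}
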