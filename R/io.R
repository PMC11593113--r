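#' Read protein records from a FASTA file
#'
#' Sequences are uppercased and validated against the 20 standard amino-acid
#' letters.  Nonstandard letters (B, J, O, U, X, Z or anything else) are
#' rejected by default; with `nonstandard = "pad"` they are mapped to the
#' terminal-padding symbol `"*"`, which the downstream encoders treat as
#' "no residue".
#'
#' @param path Path to a FASTA file (wrapped or single-line).
#' @param species Species label attached to every record (FASTA carries none).
#' @param nonstandard Either `"reject"` (default) or `"pad"`.
#' @return A data.frame with columns `id`, `sequence`, `species`
#'   (one row per entry).
#' @export
read_fasta <- function(path, species = NA_character_,
                       nonstandard = c("reject", "pad")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- vapply(as.character(set), sanitize_sequence, character(1),
                 nonstandard = nonstandard, USE.NAMES = FALSE)
  data.frame(id = ids, sequence = seqs, species = species,
             stringsAsFactors = FALSE)
}

#' Sanitize a protein sequence
#'
#' @param sequence Character scalar.
#' @param nonstandard `"reject"` to error on non-standard letters, `"pad"` to
#'   replace them with `"*"`.
#' @return Uppercased sequence over the 20 amino-acid letters (plus `"*"` when
#'   `nonstandard = "pad"`).
#' @export
sanitize_sequence <- function(sequence, nonstandard = c("reject", "pad")) {
  nonstandard <- match.arg(nonstandard)
  s <- toupper(gsub("[\\s]", "", sequence, perl = TRUE))
  if (nchar(s) == 0L) stop("empty protein sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    if (nonstandard == "reject") {
      stop("sequence contains non-standard residue(s): ",
           paste(unique(chars[bad]), collapse = ", "))
    }
    chars[bad] <- PAD_SYMBOL
    s <- paste(chars, collapse = "")
  }
  s
}

#' Write protein records to FASTA
#'
#' @param proteins data.frame with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a phosphosite table
#'
#' Expected TSV columns (header required): `protein_id`, `position`,
#' `residue`, `species`, `timestamp`, `source`; `timestamp` and `source` may
#' be absent.  Positions are 1-based.
#'
#' @param path Path to a TSV file.
#' @return data.frame of sites with `position` integer and `timestamp`
#'   parsed to `Date` (NA when absent).
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_id", "position", "residue")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("site table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  if (is.null(df$species)) df$species <- NA_character_
  if (is.null(df$source)) df$source <- "experimental"
  df$timestamp <- if (is.null(df$timestamp)) {
    as.Date(rep(NA, nrow(df)))
  } else {
    as.Date(df$timestamp)
  }
  bad <- !(df$residue %in% PHOSPHO_RESIDUES)
  if (any(bad)) {
    stop("non-phosphorylatable residue code(s) in site table: ",
         paste(unique(df$residue[bad]), collapse = ", "))
  }
  df
}

#' Write a phosphosite table
#'
#' @param sites data.frame as returned by [read_sites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-separated layout with a header row of
#' residue letters and one labelled row per residue (comment lines start
#' with `#`).  Only the 20 standard amino-acid rows/columns are retained.
#'
#' @param path Path to a matrix file, e.g. the BLOSUM62 copy shipped under
#'   `system.file("extdata", "BLOSUM62.txt", package = "prokphos")`.
#' @return A 20x20 numeric matrix with amino-acid dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  keep_r <- intersect(AA_ALPHABET, rownames(vals))
  keep_c <- intersect(AA_ALPHABET, colnames(vals))
  if (length(keep_r) < 20L || length(keep_c) < 20L) {
    stop("substitution matrix does not cover the 20 standard amino acids")
  }
  vals[AA_ALPHABET, AA_ALPHABET]
}

# Default matrix used by the GPS similarity channel.
default_substitution_matrix <- function() {
  read_substitution_matrix(
    system.file("extdata", "BLOSUM62.txt", package = "prokphos"))
}

#' Read a precomputed cluster file
#'
#' Two-column TSV `representative_id<TAB>member_id` (no header), e.g. exported
#' from an external homology-clustering run.  Used to reproduce an external
#' redundancy reduction instead of the built-in greedy reducer.
#'
#' @param path Path to the cluster TSV.
#' @return data.frame with columns `representative_id`, `member_id`.
#' @export
read_cluster_file <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("representative_id", "member_id"))
  if (nrow(df) == 0L) stop("empty cluster file: ", path)
  df
}
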