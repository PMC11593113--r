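# Protein-language-model embedding providers.
#
# The PLM channel is pluggable: a provider maps a peptide window to a
# fixed-width numeric vector.  The shipped "stub" provider is a seeded random
# projection of the one-hot window — deterministic and dependency-free — so
# the pipeline is exercisable without an external model.  An ESM-2-style
# checkpoint can be wired in by registering a provider whose `embed_fun`
# calls the external model.

#' Create a PLM provider
#'
#' @param name Provider name.
#' @param embed_dim Embedding width.
#' @param embed_fun Function `(peptides) -> B x embed_dim matrix`, or `NULL`
#'   for an unavailable external provider.
#' @return A `plm_provider` object.
#' @export
plm_provider <- function(name, embed_dim, embed_fun = NULL) {
  structure(list(name = name, embed_dim = as.integer(embed_dim),
                 embed_fun = embed_fun),
            class = "plm_provider")
}

#' Deterministic stub PLM provider
#'
#' Projects the flattened one-hot window (length `(2n+1) * 21`) through a
#' fixed Gaussian matrix drawn from `seed`.  Identical windows map to
#' identical vectors; windows differing at any residue differ.
#'
#' @param flank_n Window flank size.
#' @param embed_dim Embedding width.
#' @param seed Seed of the projection matrix.
#' @return A `plm_provider`.
#' @export
plm_provider_stub <- function(flank_n = 10L, embed_dim = 128L, seed = 1L) {
  L <- 2L * flank_n + 1L
  set.seed(seed)
  proj <- matrix(stats::rnorm(L * 21L * embed_dim, sd = 1 / sqrt(L)),
                 L * 21L, embed_dim)
  plm_provider(
    name = sprintf("stub-onehot-%d-seed%d", embed_dim, seed),
    embed_dim = embed_dim,
    embed_fun = function(peptides) {
      pm <- peptides_to_matrix(peptides)
      oh <- matrix(0, nrow(pm), L * 21L)
      for (j in seq_len(L)) {
        oh[cbind(seq_len(nrow(pm)), (j - 1L) * 21L + pm[, j])] <- 1
      }
      out <- oh %*% proj
      colnames(out) <- paste0("plm", seq_len(embed_dim))
      out
    })
}

#' External ESM-2 provider placeholder
#'
#' The package does not bundle protein-language-model weights; calling this
#' provider raises an explicit error directing users to the stub (or to
#' register their own provider around a local checkpoint).
#'
#' @param embed_dim Declared embedding width of the checkpoint.
#' @return A `plm_provider` whose `embed_fun` errors when called.
#' @export
plm_provider_esm2 <- function(embed_dim = 1280L) {
  plm_provider(
    name = "esm2_t33_650M_UR50D",
    embed_dim = embed_dim,
    embed_fun = function(peptides) {
      stop("the ESM-2 provider requires an external checkpoint; ",
           "use plm_provider_stub() or register a provider wrapping ",
           "your local model")
    })
}

#' Embed windows with a PLM provider
#'
#' @param peptides Character vector of windows.
#' @param provider A `plm_provider`.
#' @return `B x embed_dim` numeric matrix.
#' @export
plm_embed <- function(peptides, provider) {
  stopifnot(inherits(provider, "plm_provider"))
  if (is.null(provider$embed_fun)) {
    stop("provider '", provider$name, "' has no embedding function; ",
         "use plm_provider_stub()")
  }
  out <- provider$embed_fun(peptides)
  if (ncol(out) != provider$embed_dim) {
    stop("provider returned ", ncol(out), " dims, declared ",
         provider$embed_dim)
  }
  out
}
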