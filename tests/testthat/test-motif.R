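test_that("motif grammar parses offsets relative to the acceptor", {
  pat <- parse_motif("R-X-X-pS/pT-L/I/V")
  expect_equal(pat$center, c("S", "T"))
  expect_equal(pat$offsets, c(-3L, 0L, 1L))
  expect_equal(pat$tokens[[3]], c("L", "I", "V"))
  expect_equal(pat$n_informative, 2L)

  # unmarked acceptor located by convention; H before R/K
  expect_equal(parse_motif("G-H-A")$offsets, c(-1L, 0L, 1L))
  expect_equal(parse_motif("R-R-X-S/T")$center, c("S", "T"))
  expect_error(parse_motif("A-X-G"), "acceptor")
})

test_that("window matching honours residue sets, wildcards and padding", {
  w_hit <- paste0(strrep("A", 7), "RAA", "S", "L", strrep("A", 9))
  w_miss <- paste0(strrep("A", 7), "AAA", "S", "L", strrep("A", 9))
  pat <- parse_motif("R-X-X-pS/pT-L/I/V")
  expect_true(motif_match(w_hit, pat))
  expect_false(motif_match(w_miss, pat))
  # all-wildcard except the centre matches every S/T-centred window
  expect_true(all(motif_match(random_peptides(20, seed = 3),
                              "X-pS/pT/pY-X")))
  # "*" never matches a residue set
  star <- paste0(strrep("*", 10), "S", strrep("A", 10))
  expect_false(motif_match(star, parse_motif("R-X-X-pS/pT")))

  # regex oracle recount over 500 random windows
  peps <- random_peptides(500, seed = 4, pad_prob = 0.3)
  got <- motif_match(peps, pat)
  oracle <- grepl("R..[ST][LIV]", substr(peps, 8, 12))
  expect_equal(got, oracle)
})

test_that("E-ratio follows its closed form", {
  expect_equal(e_ratio(100, 10, 20, 5), 2.5)
  expect_equal(e_ratio(100, 10, 20, 2), 1.0)   # m/M = n/N
  expect_equal(e_ratio(100, 10, 20, 0), 0.0)
  expect_error(e_ratio(0, 1, 1, 0), "positive")
})

test_that("hypergeometric tail matches enumeration and phyper", {
  expect_equal(hypergeom_p(10, 4, 5, 0), 1)
  # full enumeration for N=10, n=4, M=5
  pmf <- vapply(0:4, function(k)
    choose(5, k) * choose(5, 4 - k) / choose(10, 4), numeric(1))
  expect_equal(hypergeom_p(10, 4, 5, 4), pmf[5])
  expect_equal(hypergeom_p(10, 4, 5, 2), sum(pmf[3:5]))
  expect_equal(sum(pmf), 1)
  # nested tails are monotone
  ps <- vapply(0:4, function(m) hypergeom_p(10, 4, 5, m), numeric(1))
  expect_true(all(diff(ps) <= 0))
  # independent distribution-function oracle
  expect_equal(hypergeom_p(50, 12, 20, 7),
               phyper(6, 20, 30, 12, lower.tail = FALSE))
  expect_error(hypergeom_p(10, 11, 5, 0), "invalid")
})

test_that("enrichment scan counts agree with independent recounts", {
  ds <- small_sim()$dataset
  pats <- list("R/K-X-X-pS/pT/pY", "pS/pT-P", "W-W-pS/pT-W-W")
  scan <- enrichment_scan(ds, pats, alpha = 0.01)
  expect_equal(nrow(scan), 3L)
  for (i in seq_len(nrow(scan))) {
    row <- scan[i, ]
    hit <- motif_match(ds$windows$peptide, parse_motif(row$pattern))
    pos <- ds$windows$label == "positive"
    expect_equal(row$N, nrow(ds$windows))
    expect_equal(row$n, sum(hit))
    expect_equal(row$M, sum(pos))
    expect_equal(row$m, sum(hit & pos))
  }
  rare <- scan[scan$pattern == "W-W-pS/pT-W-W", ]
  expect_equal(rare$n, 0L)
  expect_match(rare$note, "absent")

  # invariant to window order
  w2 <- ds$windows[rev(seq_len(nrow(ds$windows))), ]
  ds2 <- prokphos:::new_dataset(w2, ds$flank_n, ds$residue_set)
  scan2 <- enrichment_scan(ds2, pats, alpha = 0.01)
  expect_equal(scan[order(scan$pattern), -1],
               scan2[order(scan2$pattern), -1], ignore_attr = TRUE)
  expect_equal(scan$pattern[order(scan$pattern)],
               scan2$pattern[order(scan2$pattern)])
})

test_that("attention motif matrices are min-max scaled per matrix", {
  model <- prokphos:::transformer_init(transformer_config(), seed = 21)
  peps <- random_peptides(15, seed = 22, pad_prob = 0.3)
  aw <- attention_motif_weights(model, peps)
  expect_equal(length(aw$position_matrices), 13L)  # 12 block/head + grand
  for (m in aw$position_matrices) {
    expect_equal(min(m), 0)
    expect_equal(max(m), 1)
  }
  expect_equal(dim(aw$aa_position_matrix), c(20L, 21L))
  expect_equal(min(aw$aa_position_matrix), 0)
  expect_equal(max(aw$aa_position_matrix), 1)
  expect_true(aw$diagonal_dominance >= 0 && aw$diagonal_dominance <= 1)
  expect_error(attention_motif_weights(model, character(0)), "no positive")

  # single-window degenerate mean: scaled version of that window's attention
  aw1 <- attention_motif_weights(model, peps[1])
  fw <- transformer_forward(model, peps[1], return_attention = TRUE)
  a11 <- fw$attention[[1]][, , 1, 1]
  expect_equal(aw1$position_matrices[["b1.h1"]],
               (a11 - min(a11)) / (max(a11) - min(a11)))
})

test_that("region enrichment counts sites inside normalised intervals", {
  regions <- normalise_regions(data.frame(
    protein_id = c("p1", "p1", "p2"),
    start = c(1L, 5L, 10L), end = c(6L, 9L, 20L),
    kind = "hypervariable"))
  expect_equal(nrow(regions), 2L)  # p1 intervals merge
  expect_equal(regions$end[regions$protein_id == "p1"], 10L)

  universe <- data.frame(protein_id = rep(c("p1", "p2"), each = 10),
                         position = rep(1:10, 2))
  sites <- data.frame(protein_id = c("p1", "p1", "p2"),
                      position = c(2L, 9L, 10L))
  res <- region_enrichment(sites, regions, universe)
  # membership recount oracle
  inside <- function(pid, pos) {
    (pid == "p1" & pos >= 1 & pos <= 9) | (pid == "p2" & pos >= 10 & pos <= 20)
  }
  expect_equal(res$N, 20L)
  expect_equal(res$n, sum(inside(universe$protein_id, universe$position)))
  expect_equal(res$m, sum(inside(sites$protein_id, sites$position)))
  expect_equal(res$M, 3L)

  # regions covering the whole universe: m = M and p = 1
  all_reg <- normalise_regions(data.frame(protein_id = c("p1", "p2"),
                                          start = 1L, end = 50L))
  full <- region_enrichment(sites, all_reg, universe)
  expect_equal(full$m, full$M)
  expect_equal(full$p_value, 1)

  # no predicted site inside any region
  far <- normalise_regions(data.frame(protein_id = "p9", start = 1L,
                                      end = 5L))
  none <- region_enrichment(sites, far, universe)
  expect_equal(none$m, 0L)
  expect_error(region_enrichment(sites, regions,
                                 universe[0, , drop = FALSE]), "empty")
})
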