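test_that("FASTA reading uppercases, validates and enforces unique IDs", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "mkst"), fa)
  rec <- read_fasta(fa)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$sequence, "MKST")

  writeLines(c(">p1", "MKST", ">p1", "ARND"), fa)
  expect_error(read_fasta(fa), "duplicate")

  writeLines(c(">p1", "MKUST"), fa)
  expect_error(read_fasta(fa), "non-standard")
  expect_equal(read_fasta(fa, nonstandard = "pad")$sequence, "MK*ST")
})

test_that("sanitizer accepts exactly the 20 standard amino-acid letters", {
  ok <- vapply(LETTERS, function(l) {
    !inherits(tryCatch(sanitize_sequence(strrep(l, 3)),
                       error = function(e) e), "error")
  }, logical(1))
  expect_equal(sum(ok), 20L)
  expect_equal(sort(LETTERS[!ok]), c("B", "J", "O", "U", "X", "Z"))
})

test_that("window extraction pads termini with '*' to fixed length", {
  expect_equal(extract_window("MKSTAR", 3, 2), "MKSTA")
  expect_equal(extract_window("MKSTAR", 1, 3), "***MKST")
  expect_error(extract_window("MKSTAR", 7, 2), "out of range")

  # brute-force padding count across all positions of a length-25 protein
  set.seed(1)
  prot <- paste(sample(c("A", "S", "G", "L"), 25, replace = TRUE),
                collapse = "")
  for (pos in 1:25) {
    w <- extract_window(prot, pos, 10)
    expect_equal(nchar(w), 21L)
    lead <- attr(regexpr("^\\*+", w), "match.length")
    expect_equal(max(lead, 0), max(0, 10 - (pos - 1)))
    trail <- attr(regexpr("\\*+$", w), "match.length")
    expect_equal(max(trail, 0), max(0, 10 - (25 - pos)))
    expect_false(substr(w, 11, 11) == "*")
  }
})

test_that("dataset construction labels sites positive and the rest negative", {
  prot <- data.frame(id = "p1", sequence = "ASASA", species = "x")
  sites <- data.frame(protein_id = "p1", position = 2L, residue = "S",
                      species = "x", timestamp = as.Date("2020-01-01"),
                      source = "experimental")
  ds <- build_dataset(prot, sites, n = 2L, residue_set = "S")
  expect_equal(nrow(ds$windows), 2L)
  expect_equal(ds$windows$label[ds$windows$position == 2], "positive")
  expect_equal(ds$windows$label[ds$windows$position == 4], "negative")

  # residue mismatch names the record
  bad <- data.frame(protein_id = "p1", position = 1L, residue = "S")
  expect_error(build_dataset(prot, bad, 2L, "S"), "p1:1")

  # window count equals the residue-set letter count (O-class candidates)
  sim <- small_sim()
  n_letters <- sum(vapply(strsplit(sim$sim$proteins$sequence, ""),
                          function(ch) sum(ch %in% c("S", "T", "Y")),
                          integer(1)))
  expect_equal(nrow(sim$dataset$windows), n_letters)
  expect_true(all(nchar(sim$dataset$windows$peptide) == 21L))
})

# independent quadratic greedy oracle for the redundancy reducer
greedy_oracle <- function(peps, labels, thr) {
  ident <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    comp <- ca != "*" & cb != "*"
    if (!any(comp)) return(0)
    sum(ca[comp] == cb[comp]) / sum(comp)
  }
  kept <- integer(0)
  for (i in seq_along(peps)) {
    same <- kept[labels[kept] == labels[i]]
    ok <- TRUE
    for (j in same) {
      if (peps[j] == peps[i] || ident(peps[i], peps[j]) > thr) ok <- FALSE
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

test_that("redundancy reduction matches a brute-force greedy oracle", {
  set.seed(7)
  peps <- random_peptides(10, seed = 11)
  peps <- c(peps, peps[1])  # one exact duplicate
  w <- data.frame(protein_id = sprintf("p%02d", seq_along(peps)),
                  position = 11L, residue = substr(peps, 11, 11),
                  peptide = peps,
                  label = rep(c("positive", "negative"), length.out = 11),
                  species = "x",
                  timestamp = as.Date("2020-01-01") + seq_along(peps))
  ds <- prokphos:::new_dataset(w, 10L, c("S", "T", "Y"))
  red <- reduce_redundancy(ds, 0.4)
  oracle <- greedy_oracle(w$peptide, w$label, 0.4)  # input already ordered
  expect_equal(red$windows$peptide, w$peptide[oracle])

  # duplicate collapses even at threshold 1; otherwise threshold 1 is vacuous
  red1 <- reduce_redundancy(ds, 1.0)
  expect_equal(nrow(red1$windows), 10L)

  # idempotence
  red2 <- reduce_redundancy(red, 0.4)
  expect_equal(red2$windows$peptide, red$windows$peptide)
})

test_that("timestamp split partitions the dataset exhaustively", {
  ds <- small_sim()$dataset
  cut <- as.Date("2022-10-01")
  parts <- split_by_timestamp(ds, cut)
  expect_equal(nrow(parts$train$windows) + nrow(parts$test$windows),
               nrow(ds$windows))
  expect_true(all(parts$train$windows$timestamp < cut))
  expect_true(all(parts$test$windows$timestamp >= cut))

  expect_equal(nrow(split_by_timestamp(ds, as.Date("2010-01-01"))$train$windows),
               0L)
  expect_equal(nrow(split_by_timestamp(ds, as.Date("2030-01-01"))$test$windows),
               0L)

  w <- ds$windows
  w$timestamp[1] <- NA
  ds_na <- prokphos:::new_dataset(w, ds$flank_n, ds$residue_set)
  expect_error(split_by_timestamp(ds_na, cut), "timestamp")
})

test_that("external cluster files restrict windows to representatives", {
  ds <- small_sim()$dataset
  reps <- unique(ds$windows$protein_id)[1:5]
  cl <- data.frame(representative_id = reps, member_id = reps)
  red <- reduce_redundancy(ds, clusters = cl)
  expect_setequal(unique(red$windows$protein_id), reps)
})
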