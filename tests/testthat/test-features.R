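cfgdef <- encoder_config()

test_that("EAAC counts sliding sub-window composition and ignores padding", {
  allA <- paste(rep("A", 21), collapse = "")
  e <- encode_eaac(allA, cfgdef)
  expect_equal(ncol(e), 340L)  # 17 sub-windows x 20
  a_cols <- grepl("\\.A$", colnames(e))
  expect_true(all(e[1, a_cols] == 1))
  expect_true(all(e[1, !a_cols] == 0))

  padded <- paste0(strrep("*", 10), "S", strrep("A", 10))
  ep <- encode_eaac(padded, cfgdef)
  expect_true(all(ep[1, grepl("^w01\\.", colnames(ep))] == 0))  # all-pad window
  # unpadded sub-windows sum to 1
  full <- random_peptides(3, seed = 2)
  ef <- encode_eaac(full, cfgdef)
  for (s in 1:17) {
    expect_equal(unname(rowSums(ef[, grepl(sprintf("^w%02d\\.", s),
                                           colnames(ef))])),
                 rep(1, 3))
  }
})

test_that("CKSAAP matches hand enumeration and normalises per k-block", {
  allA <- paste(rep("A", 21), collapse = "")
  ck <- encode_cksaap(allA, cfgdef)
  expect_equal(ncol(ck), 1600L)
  expect_equal(unname(ck[1, "k0.AA"]), 1)

  # hand enumeration on ARNDA, k = 1: pairs A.N, R.D, N.A
  ck1 <- encode_cksaap("ARNDA", encoder_config(cksaap_kmax = 1))
  expect_equal(unname(ck1[1, c("k1.AN", "k1.RD", "k1.NA")]), rep(1 / 3, 3))
  expect_equal(sum(ck1[1, grepl("^k1\\.", colnames(ck1))]), 1)

  peps <- random_peptides(5, seed = 3, pad_prob = 1)
  ckp <- encode_cksaap(peps, cfgdef)
  for (k in 0:3) {
    expect_equal(unname(rowSums(ckp[, grepl(sprintf("^k%d\\.", k),
                                            colnames(ckp))])),
                 rep(1, 5))
  }
})

test_that("CTDC class fractions follow the grouping tables and sum to 1", {
  allR <- paste(rep("R", 21), collapse = "")
  ct <- encode_ctdc(allR)
  expect_equal(ncol(ct), 39L)
  expect_equal(unname(ct[1, "charge.g1"]), 1)  # KR group

  # manual tally on a 6-residue toy (centre padded window not required here)
  toy <- "LKKDDA"
  ct2 <- encode_ctdc(toy)
  # polarity groups: LIFWCMVY / PATGS / HQRKNED -> L | A | KKDD
  expect_equal(unname(ct2[1, c("polarity.g1", "polarity.g2", "polarity.g3")]),
               c(1, 1, 4) / 6)
  attr_sums <- vapply(names(prokphos:::CTDC_GROUPS), function(a)
    sum(ct2[1, paste0(a, ".g", 1:3)]), numeric(1))
  expect_equal(unname(attr_sums), rep(1, 13))
})

test_that("DDE equals an independently coded formula evaluation", {
  d <- encode_dde("MKST")
  # oracle: direct evaluation over the 3 adjacent pairs
  codon <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3, K = 2,
             L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6, T = 4, V = 4,
             W = 1, Y = 2)
  pairs <- c("MK", "KS", "ST")
  for (nm in colnames(d)) {
    a <- substr(nm, 1, 1); b <- substr(nm, 2, 2)
    dc <- mean(pairs == nm)
    tm <- (codon[[a]] / 61) * (codon[[b]] / 61)
    tv <- tm * (1 - tm) / 3
    expect_equal(unname(d[1, nm]), (dc - tm) / sqrt(tv))
  }
  expect_true(all(d[1, !colnames(d) %in% pairs] < 0))  # absent pairs negative
})

test_that("APAAC/PAAC components sum to 1 and match a direct oracle", {
  peps <- random_peptides(4, seed = 5, pad_prob = 0.5)
  ap <- encode_apaac(peps, cfgdef)
  pa <- encode_paac(peps, cfgdef)
  expect_equal(ncol(ap), 28L)
  expect_equal(ncol(pa), 24L)
  expect_equal(unname(rowSums(ap)), rep(1, 4))
  expect_equal(unname(rowSums(pa)), rep(1, 4))

  # independent formula evaluation on one fixed 21-mer
  pep <- peps[1]
  chars <- strsplit(gsub("\\*", "", pep), "")[[1]]
  norm <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  h1 <- norm(prokphos:::AA_HYDROPHOBICITY)
  h2 <- norm(prokphos:::AA_HYDROPHILICITY)
  ms <- norm(prokphos:::AA_SIDECHAIN_MASS)
  L <- length(chars)
  f <- table(factor(chars, levels = names(h1))) / L
  tau <- unlist(lapply(1:4, function(k) {
    i <- 1:(L - k)
    c(mean(h1[chars[i]] * h1[chars[i + k]]),
      mean(h2[chars[i]] * h2[chars[i + k]]))
  }))
  expect_equal(unname(ap[1, ]),
               unname(c(f, 0.05 * tau) / (sum(f) + 0.05 * sum(tau))),
               tolerance = 1e-12)
  theta <- vapply(1:4, function(k) {
    i <- 1:(L - k)
    mean(((h1[chars[i]] - h1[chars[i + k]])^2 +
            (h2[chars[i]] - h2[chars[i + k]])^2 +
            (ms[chars[i]] - ms[chars[i + k]])^2) / 3)
  }, numeric(1))
  expect_equal(unname(pa[1, ]),
               unname(c(f, 0.05 * theta) / (sum(f) + 0.05 * sum(theta))),
               tolerance = 1e-12)
})

test_that("DistancePair reduces to composition at d=0 and matches counting", {
  dp0 <- encode_distancepair("ARND",
                             encoder_config(distpair_max_distance = 0))
  expect_equal(ncol(dp0), 20L)
  expect_equal(unname(dp0[1, c("d0.A", "d0.R", "d0.N", "d0.D")]), rep(0.25, 4))

  dp <- encode_distancepair("ARND", cfgdef)
  expect_equal(ncol(dp), 820L)
  expect_equal(unname(dp[1, c("d1.AR", "d1.RN", "d1.ND")]), rep(1 / 3, 3))
  expect_equal(unname(dp[1, c("d2.AN", "d2.RD")]), rep(1 / 2, 2))
  expect_equal(sum(dp[1, grepl("^d2\\.", colnames(dp))]), 1)
})

test_that("GPS similarity equals a brute-force double loop", {
  B62 <- read_substitution_matrix(
    system.file("extdata", "BLOSUM62.txt", package = "prokphos"))
  # self-similarity = diagonal sum
  pep <- random_peptides(1, seed = 8)
  self <- gps_score(pep, pep)
  chars <- strsplit(pep, "")[[1]]
  expect_equal(unname(self[1, 1]), sum(B62[cbind(chars, chars)]))

  # padded flanks: only the centre contributes
  star <- paste0(strrep("*", 10), "S", strrep("*", 10))
  expect_equal(unname(gps_score(star, pep)[1, 1]),
               max(0, B62["S", substr(pep, 11, 11)]))

  # brute-force double loop over a 5-peptide positive set
  qs <- random_peptides(5, seed = 9, pad_prob = 0.5)
  ws <- random_peptides(3, seed = 10, pad_prob = 0.5)
  got <- gps_score(ws, qs)
  for (i in 1:3) {
    sims <- vapply(qs, function(q) {
      ca <- strsplit(ws[i], "")[[1]]; cb <- strsplit(q, "")[[1]]
      s <- 0
      for (j in 1:21) if (ca[j] != "*" && cb[j] != "*")
        s <- s + B62[ca[j], cb[j]]
      max(s, 0)
    }, numeric(1))
    expect_equal(unname(got[i, 1]), mean(sims))
  }

  # permutation invariance and linearity in set concatenation
  expect_equal(gps_score(ws, rev(qs)), got)
  g1 <- gps_score(ws, qs[1:2]); g2 <- gps_score(ws, qs[3:5])
  expect_equal((2 * g1 + 3 * g2) / 5, got)

  # leave-one-out
  loo <- gps_score(qs, qs, exclude_self = TRUE)
  for (i in 1:5) {
    expect_equal(unname(loo[i, 1]),
                 unname(gps_score(qs[i], qs[-i])[1, 1]))
  }
  expect_error(gps_score(qs[1], qs[1], exclude_self = TRUE), "empty")
})

test_that("encoders are pure functions with config-fixed dimensions", {
  peps <- random_peptides(3, seed = 12, pad_prob = 0.5)
  f1 <- encode_sequence_features(peps, cfgdef, gps_positives = peps)
  f2 <- encode_sequence_features(peps, cfgdef, gps_positives = peps)
  expect_identical(f1, f2)
  dims <- feature_dims(cfgdef)
  for (ch in names(f1)) expect_equal(ncol(f1[[ch]]), unname(dims[ch]))
  expect_true(all(vapply(f1, function(m) all(is.finite(m)), logical(1))))
})
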