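# Shared fixtures.  The heavy end-to-end fixtures (planted-motif benchmark,
# transfer benchmark, small trained model) are built lazily once per test run
# and cached, so several test files can interrogate the same trained models.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small simulated dataset (fast; used across unit tests).
small_sim <- function() fixture("small_sim", function() {
  cfg <- sim_config(n_proteins = 80L, seed = 42L)
  sim <- simulate_phosphoproteome(cfg)
  ds <- build_dataset(sim$proteins, sim$sites, n = 10L,
                      residue_set = O_RESIDUES)
  list(cfg = cfg, sim = sim, dataset = ds)
})

# Small trained integrated model (minutes-free; architecture/contract tests).
mini_model <- function() fixture("mini_model", function() {
  ds <- small_sim()$dataset
  parts <- split_by_timestamp(ds, as.Date("2022-10-01"))
  model <- suppressWarnings(
    pretrain_general(parts$train, class = "O", seed = 7L,
                     tf_epochs = 2L, epochs = 3L, tf_max_windows = 400L))
  list(model = model, train = parts$train, test = parts$test)
})

# Full planted-motif recovery benchmark (the study-scale conditions:
# 2,000 proteins, motif rate 0.8, background rate 0.05).
benchmark_fixture <- function() fixture("benchmark", function() {
  run_recovery_benchmark(101L)
})

# Transfer-learning benchmark on the two-species fixture.
transfer_fixture <- function() fixture("transfer", function() {
  run_transfer_benchmark(202L)
})

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptides <- function(n, len = 21L, seed = 1L, pad_prob = 0) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    chars <- sample(AA20, len, replace = TRUE)
    npad <- if (pad_prob > 0 && stats::runif(1) < pad_prob)
      sample.int(5L, 1L) else 0L
    if (npad > 0) chars[seq_len(npad)] <- "*"
    chars[(len + 1L) %/% 2L] <- sample(c("S", "T", "Y"), 1L)
    paste(chars, collapse = "")
  }, character(1))
}
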