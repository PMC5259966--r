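# Standard chain specifications used across tests.

# Memory-1 chain over the 4-letter test alphabet with a strong diagonal:
# each residue tends to repeat. Matched by a 2-gram model.
chain_a <- function() {
  tm <- matrix(0.1, 4, 4, dimnames = list(test_alphabet, test_alphabet))
  diag(tm) <- 0.7
  chain_spec(tm, order = 1)
}

# Memory-1 chain favoring the cyclic successor instead: well separated
# from chain_a but with identical stationary residue frequencies.
chain_b <- function() {
  tm <- matrix(0.1, 4, 4, dimnames = list(test_alphabet, test_alphabet))
  for (i in 1:4) tm[i, (i %% 4) + 1] <- 0.7
  chain_spec(tm, order = 1)
}

# An asymmetric memory-1 chain used for parameter-recovery experiments.
chain_recovery <- function() {
  tm <- matrix(c(0.50, 0.30, 0.15, 0.05,
                 0.10, 0.40, 0.30, 0.20,
                 0.25, 0.25, 0.25, 0.25,
                 0.05, 0.15, 0.30, 0.50),
               4, 4, byrow = TRUE,
               dimnames = list(test_alphabet, test_alphabet))
  chain_spec(tm, order = 1)
}

gen_corpus <- function(spec, n, len, seed, label = "sim") {
  seqs <- vapply(seq_len(n), function(i) {
    sample_sequence(spec, len, seed = seed + i)$seq
  }, character(1))
  protein_corpus(sprintf("%s_%04d", label, seq_len(n)), seqs, label = label)
}

# Two families of near-duplicate sequences over the 20-letter alphabet:
# each family derives from one seed sequence by at most `max_mut` point
# substitutions per member (<= 5% of the length).
family_corpus <- function(seed = 404, n_per_family = 5L, len = 120L,
                          max_mut = 6L) {
  set.seed(seed)
  aa <- aa_alphabet()
  founders <- replicate(2, paste(sample(aa, len, replace = TRUE),
                                 collapse = ""))
  seqs <- character(0)
  ids <- character(0)
  for (f in 1:2) {
    for (j in seq_len(n_per_family)) {
      chars <- strsplit(founders[f], "")[[1]]
      n_mut <- sample(0:max_mut, 1)
      if (n_mut > 0) {
        pos <- sample(len, n_mut)
        for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1)
      }
      seqs <- c(seqs, paste(chars, collapse = ""))
      ids <- c(ids, sprintf("fam%d_%d", f, j))
    }
  }
  protein_corpus(ids, seqs, label = "families")
}
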