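two_letter_models <- function(p_a_human = 0.9, p_a_nonhuman = 0.1) {
  # order-1 MLE models over {A, C} with the requested P(A) per class,
  # built from training corpora with the matching residue composition
  stopifnot(p_a_human * 10 == round(p_a_human * 10))
  mk <- function(p_a, label) {
    s <- paste(c(rep("A", p_a * 10), rep("C", 10 - p_a * 10)), collapse = "")
    train_ngram_model(protein_corpus("t", s, label = label), 1,
                      smoothing_config("none"), alphabet = c("A", "C"))
  }
  list(h = mk(p_a_human, "human"), nh = mk(p_a_nonhuman, "non-human"))
}

test_that("priors are maximum-likelihood corpus-size ratios", {
  expect_equal(estimate_priors(1, 1)$p_human, 0.5)
  expect_equal(estimate_priors(3, 1)$p_human, 0.75)
  expect_equal(estimate_priors(3, 1)$p_nonhuman, 0.25)
  # ratio of the reference training corpus sizes after redundancy filtering
  pr <- estimate_priors(14189, 59060)
  expect_identical(pr$p_human, 14189 / (14189 + 59060))
  expect_equal(pr$p_human, 0.19371, tolerance = 1e-5)
  expect_equal(pr$p_human + pr$p_nonhuman, 1, tolerance = 1e-12)
  expect_error(estimate_priors(0, 5), "positive integers")
  expect_error(class_priors(1), "between 0 and 1")
})

test_that("identical models give exact symmetry; priors alone can decide", {
  set.seed(51)
  co <- random_corpus(3, c(10, 25), test_alphabet)
  m <- train_ngram_model(co, 2, alphabet = test_alphabet)
  queries <- random_corpus(10, c(5, 15), test_alphabet, label = "q")

  even <- classify_corpus(queries, m, m, estimate_priors(1, 1))
  expect_true(all(even$decisions$log_odds == 0))
  expect_true(all(even$decisions$label == "tie"))

  skewed <- classify_corpus(queries, m, m, estimate_priors(3, 1))
  expect_equal(skewed$decisions$log_odds, rep(log(3), 10),
               tolerance = 1e-12)
  expect_true(all(skewed$decisions$label == "human"))
})

test_that("log-odds match the hand computation on the two-letter toy", {
  ms <- two_letter_models(0.9, 0.1)
  d <- score_sequence("AAAA", ms$h, ms$nh, estimate_priors(1, 1))
  expect_equal(d$log_odds, 4 * log(9), tolerance = 1e-12)
  expect_equal(d$label, "human")
  expect_equal(d$log_odds_per_pos, log(9), tolerance = 1e-12)

  # posterior odds by explicit enumeration of the Bayes formula
  for (seq in c("AAAA", "ACCA", "CCCC", "ACACACAC")) {
    want <- oracle_posterior_odds_direct(
      "AAAAAAAAAC", "ACCCCCCCCC", 1, seq, 0.3, "none", 0, c("A", "C"))
    got <- score_sequence(seq, ms$h, ms$nh, class_priors(0.3))$log_odds
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("infinite likelihoods force labels and flag unscoreable queries", {
  # human model has never seen C, non-human model has never seen A
  mh <- train_ngram_model(protein_corpus("h", "AAAA"), 1,
                          smoothing_config("none"), alphabet = c("A", "C"))
  mnh <- train_ngram_model(protein_corpus("n", "CCCC"), 1,
                           smoothing_config("none"), alphabet = c("A", "C"))
  pr <- estimate_priors(1, 1)
  expect_equal(score_sequence("AA", mh, mnh, pr)$label, "human")
  expect_equal(score_sequence("CC", mh, mnh, pr)$label, "non-human")
  d <- score_sequence("AC", mh, mnh, pr)
  expect_true(d$unscoreable)
  expect_equal(d$label, "tie")
})

test_that("model-pair mismatches are configuration errors", {
  co <- random_corpus(2, c(10, 20), test_alphabet)
  m2 <- train_ngram_model(co, 2, alphabet = test_alphabet)
  m3 <- train_ngram_model(co, 3, alphabet = test_alphabet)
  mk <- train_ngram_model(co, 2, smoothing_config("add_k", k = 1),
                          alphabet = test_alphabet)
  pr <- estimate_priors(1, 1)
  expect_error(score_sequence("ACDE", m2, m3, pr), "order mismatch")
  expect_error(score_sequence("ACDE", m2, mk, pr), "smoothing")
})

test_that("swapping models and inverting priors negates every log-odds", {
  set.seed(61)
  a <- random_corpus(3, c(15, 30), test_alphabet, label = "a")
  b <- random_corpus(3, c(15, 30), test_alphabet, label = "b")
  ma <- train_ngram_model(a, 2, alphabet = test_alphabet)
  mb <- train_ngram_model(b, 2, alphabet = test_alphabet)
  q <- random_corpus(12, c(6, 20), test_alphabet, label = "q")
  fwd <- classify_corpus(q, ma, mb, estimate_priors(3, 7))
  rev <- classify_corpus(q, mb, ma, estimate_priors(7, 3))
  expect_identical(fwd$decisions$log_odds, -rev$decisions$log_odds)
})

test_that("scaling the prior odds shifts every log-odds by the same constant", {
  set.seed(71)
  a <- random_corpus(3, c(15, 30), test_alphabet, label = "a")
  b <- random_corpus(3, c(15, 30), test_alphabet, label = "b")
  ma <- train_ngram_model(a, 2, alphabet = test_alphabet)
  mb <- train_ngram_model(b, 2, alphabet = test_alphabet)
  q <- random_corpus(12, c(6, 20), test_alphabet, label = "q")
  p1 <- class_priors(0.5)
  p2 <- class_priors(0.8)
  c_shift <- (log(p2$p_human) - log(p2$p_nonhuman)) -
    (log(p1$p_human) - log(p1$p_nonhuman))
  d1 <- classify_corpus(q, ma, mb, p1)$decisions$log_odds
  d2 <- classify_corpus(q, ma, mb, p2)$decisions$log_odds
  expect_equal(d2 - d1, rep(c_shift, 12), tolerance = 1e-12)
})

test_that("the human call count is non-increasing in the margin", {
  set.seed(81)
  a <- gen_corpus(chain_a(), 20, 60, seed = 500, label = "a")
  b <- gen_corpus(chain_b(), 20, 60, seed = 600, label = "b")
  ma <- train_ngram_model(a, 2, alphabet = test_alphabet)
  mb <- train_ngram_model(b, 2, alphabet = test_alphabet)
  q <- gen_corpus(chain_a(), 30, 60, seed = 700, label = "q")
  pr <- estimate_priors(1, 1)
  margins <- c(0, 1, 5, 20, 100, Inf)
  n_human <- vapply(margins, function(m) {
    classify_corpus(q, ma, mb, pr, margin = m)$summary[["n_human"]]
  }, numeric(1))
  expect_true(all(diff(n_human) <= 0))
  expect_equal(n_human[length(margins)], 0)
  expect_error(classify_corpus(q, ma, mb, pr, margin = -1), "non-negative")
})
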