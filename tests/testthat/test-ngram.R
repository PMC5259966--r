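test_that("count_ngrams enumerates within-sequence windows", {
  ct <- count_ngrams(protein_corpus("s", "AAA"), 2)
  expect_equal(ct$counts, c(AA = 2L))
  expect_equal(ct$context_counts, c(A = 3L))
  expect_equal(ct$total_tokens, 2L)

  ct1 <- count_ngrams(protein_corpus("s", "ACDA"), 1)
  expect_equal(ct1$counts, c(A = 2L, C = 1L, D = 1L))

  # no windows cross the boundary between the two sequences
  ct2 <- count_ngrams(protein_corpus(c("a", "b"), c("ACAC", "CA")), 2)
  expect_equal(ct2$counts, c(AC = 2L, CA = 2L))

  expect_error(count_ngrams(protein_corpus("s", "ACDA"), 0), "integer >= 1")
  expect_warning(count_ngrams(protein_corpus("s", "AC"), 5), "shorter than")
})

test_that("n-gram counts match the brute-force window oracle", {
  set.seed(101)
  for (rep in 1:25) {
    co <- random_corpus(sample(1:5, 1), c(3, 12), test_alphabet)
    n <- sample(1:3, 1)
    got <- count_ngrams(co, n)$counts
    want <- oracle_count_windows(co$seq, n)
    expect_identical(as.integer(got), as.integer(want))
    expect_identical(names(got), names(want))
    # count conservation: total windows = sum over sequences of max(L-n+1,0)
    expect_equal(sum(got), sum(pmax(nchar(co$seq) - n + 1, 0)))
  }
})

test_that("conditional probabilities follow MLE and add-k formulas", {
  # corpus "AAAC": 2-gram counts AA=2, AC=1; prefix marginal of context A = 3
  co <- protein_corpus("s", "AAAC")
  mle <- train_ngram_model(co, 2, smoothing_config("none"))
  expect_equal(conditional_prob(mle, "A", "A"), 2 / 3)
  expect_equal(conditional_prob(mle, "A", "C"), 1 / 3)
  expect_error(conditional_prob(mle, "W", "A"), "undefined context")

  addk <- train_ngram_model(co, 2, smoothing_config("add_k", k = 1))
  expect_equal(conditional_prob(addk, "A", "A"), (2 + 1) / (3 + 20))
  # an entirely unseen context is uniform under pure pseudocounts
  expect_equal(conditional_prob(addk, "W", aa_alphabet()),
               rep(1 / 20, 20))

  expect_error(conditional_prob(mle, "AA", "A"), "length order - 1")
  expect_error(conditional_prob(mle, "A", "B"), "canonical residue")
})

test_that("every context's conditional distribution sums to one", {
  set.seed(202)
  co <- random_corpus(5, c(20, 60), test_alphabet)
  for (method in c("none", "add_k")) {
    for (n in 1:3) {
      m <- train_ngram_model(co, n, smoothing_config(method, k = 0.01),
                             alphabet = test_alphabet)
      contexts <- if (n == 1) "" else {
        apply(expand.grid(rep(list(test_alphabet), n - 1)), 1,
              paste, collapse = "")
      }
      for (ctx in contexts) {
        p <- tryCatch(conditional_prob(m, ctx, test_alphabet),
                      error = function(e) NULL)  # unseen context under MLE
        if (!is.null(p)) expect_lt(abs(sum(p) - 1), 1e-9)
        if (method == "add_k") expect_false(is.null(p))
      }
    }
  }
})

test_that("log-likelihood is the log product of conditional probabilities", {
  # trained and scored on "AAA": the only observed context extends only to
  # A, so P(A|A) = 1 and the log-likelihood is exactly 0
  m <- train_ngram_model(protein_corpus("s", "AAA"), 2,
                         smoothing_config("none"))
  expect_identical(as.numeric(log_likelihood(m, "AAA")), 0)

  # i.i.d. case: order 1 with P(A) = 1/4
  m1 <- train_ngram_model(protein_corpus("s", "ACDE"), 1,
                          smoothing_config("none"),
                          alphabet = test_alphabet)
  expect_equal(as.numeric(log_likelihood(m1, "AA")), 2 * log(0.25))

  # a zero-probability factor is the -Inf sentinel, never an exception
  expect_identical(as.numeric(log_likelihood(m1, "AW")), -Inf)
  m2 <- train_ngram_model(protein_corpus("s", "ACACAC"), 2,
                          smoothing_config("none"),
                          alphabet = test_alphabet)
  expect_identical(as.numeric(log_likelihood(m2, "ACDE")), -Inf)

  # sequences shorter than the order: error unless chain-rule scoring
  expect_error(log_likelihood(m2, "A"), "shorter than model order")
  ll <- log_likelihood(m2, "A", prefix = "chain")
  expect_equal(as.numeric(ll), log(1 / 2))  # unigram P(A) = 3/6
  expect_equal(attr(ll, "positions"), 1L)
})

test_that("log-likelihoods match the brute-force oracle", {
  set.seed(303)
  for (rep in 1:25) {
    co <- random_corpus(sample(1:5, 1), c(4, 12), test_alphabet)
    n <- sample(1:3, 1)
    method <- sample(c("none", "add_k"), 1)
    k <- runif(1, 0.001, 2)
    m <- train_ngram_model(co, n, smoothing_config(method, k = k),
                           alphabet = test_alphabet)
    query <- paste(sample(test_alphabet, 8, replace = TRUE), collapse = "")
    got <- as.numeric(log_likelihood(m, query))
    want <- oracle_loglik(co$seq, n, query, method, k, test_alphabet)
    if (is.infinite(want)) {
      expect_identical(got, -Inf)
    } else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("appending a residue never increases the log-likelihood", {
  set.seed(404)
  co <- random_corpus(4, c(10, 30), test_alphabet)
  m <- train_ngram_model(co, 2, smoothing_config("add_k", k = 0.5),
                         alphabet = test_alphabet)
  for (rep in 1:20) {
    s <- paste(sample(test_alphabet, sample(3:10, 1), replace = TRUE),
               collapse = "")
    extended <- paste0(s, sample(test_alphabet, 1))
    expect_lte(as.numeric(log_likelihood(m, extended)),
               as.numeric(log_likelihood(m, s)))
  }
})

test_that("perplexity has the uniform closed form and the MLE bound", {
  uni <- train_ngram_model(
    protein_corpus("u", paste(rep(paste(aa_alphabet(), collapse = ""), 2),
                              collapse = "")),
    1, smoothing_config("none"))
  q <- random_corpus(3, c(10, 20), aa_alphabet())
  expect_equal(perplexity(uni, q), 20)

  # MLE fits its own training corpus at least as well as uniform
  set.seed(7)
  train <- random_corpus(1, c(200, 200), aa_alphabet())
  m <- train_ngram_model(train, 1, smoothing_config("none"))
  expect_lte(perplexity(m, train), 20)

  # any -Inf sequence log-likelihood gives +Inf perplexity
  m4 <- train_ngram_model(protein_corpus("s", "ACAC"), 1,
                          smoothing_config("none"), alphabet = test_alphabet)
  expect_identical(perplexity(m4, protein_corpus("q", "ADE")), Inf)
})
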