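# Independent brute-force oracle: explicit window sliding and explicit
# Bayes-formula enumeration, deliberately sharing no code with the package.

oracle_count_windows <- function(seqs, n) {
  env <- new.env(parent = emptyenv())
  for (s in seqs) {
    L <- nchar(s)
    if (L < n) next
    for (i in seq_len(L - n + 1)) {
      g <- substr(s, i, i + n - 1)
      env[[g]] <- (if (is.null(env[[g]])) 0L else env[[g]]) + 1L
    }
  }
  out <- unlist(as.list(env))
  if (is.null(out)) integer(0) else out[order(names(out))]
}

oracle_cond_prob <- function(counts_n, n, context, residue,
                             method, k, alphabet) {
  get0c <- function(key) {
    v <- counts_n[key]
    if (is.na(v)) 0 else as.numeric(v)
  }
  num <- get0c(paste0(context, residue))
  den <- 0
  for (r in alphabet) den <- den + get0c(paste0(context, r))
  if (method == "add_k") {
    (num + k) / (den + k * length(alphabet))
  } else {
    if (den == 0) 0 else num / den  # 0 signals the -Inf sentinel downstream
  }
}

oracle_loglik <- function(train_seqs, n, seq, method, k, alphabet) {
  counts_n <- oracle_count_windows(train_seqs, n)
  L <- nchar(seq)
  if (L < n) stop("oracle: sequence shorter than order")
  ll <- 0
  for (i in n:L) {
    ctx <- if (n == 1) "" else substr(seq, i - n + 1, i - 1)
    p <- oracle_cond_prob(counts_n, n, ctx, substr(seq, i, i),
                          method, k, alphabet)
    ll <- ll + log(p)
  }
  ll
}

# Posterior log-odds by explicit enumeration of the Bayes formula:
# P(H | seq) = p_h * P(seq | H) / [p_h * P(seq | H) + p_nh * P(seq | NH)]
oracle_log_odds <- function(train_h, train_nh, n, seq, p_h,
                            method, k, alphabet) {
  ll_h <- oracle_loglik(train_h, n, seq, method, k, alphabet)
  ll_nh <- oracle_loglik(train_nh, n, seq, method, k, alphabet)
  (log(p_h) + ll_h) - (log(1 - p_h) + ll_nh)
}

# Full-probability variant (only safe for short sequences): exponentiates
# the likelihoods and forms the posterior ratio directly.
oracle_posterior_odds_direct <- function(train_h, train_nh, n, seq, p_h,
                                         method, k, alphabet) {
  lik_h <- exp(oracle_loglik(train_h, n, seq, method, k, alphabet))
  lik_nh <- exp(oracle_loglik(train_nh, n, seq, method, k, alphabet))
  post_h <- p_h * lik_h
  post_nh <- (1 - p_h) * lik_nh
  log(post_h / post_nh)
}

random_corpus <- function(n_seqs, len_range, alphabet, label = "rand") {
  seqs <- vapply(seq_len(n_seqs), function(i) {
    L <- len_range[1] + sample.int(len_range[2] - len_range[1] + 1L, 1) - 1L
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
  protein_corpus(sprintf("%s_%03d", label, seq_len(n_seqs)), seqs,
                 label = label)
}

test_alphabet <- c("A", "C", "D", "E")  # reduced alphabet for tractability
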