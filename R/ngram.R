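#' Smoothing configuration for n-gram models
#'
#' `method = "none"` is pure maximum-likelihood estimation: an unseen n-gram
#' has probability 0 and any sequence containing one scores `-Inf`.
#' `method = "add_k"` adds a pseudocount `k` to every n-gram count so that
#' every conditional distribution stays strictly positive and normalized
#' over the alphabet.
#'
#' @param method `"add_k"` (default) or `"none"`.
#' @param k Positive pseudocount, used when `method = "add_k"`
#'   (default 0.01).
#' @param alphabet_size Number of residues the conditional distributions
#'   normalize over (default 20; reduced alphabets override this through
#'   [train_ngram_model()]).
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(method = c("add_k", "none"), k = 0.01,
                             alphabet_size = 20L) {
  method <- match.arg(method)
  if (method == "add_k" && (!is.numeric(k) || length(k) != 1L || k <= 0)) {
    stop("`k` must be a single positive number under add_k smoothing",
         call. = FALSE)
  }
  structure(
    list(method = method,
         k = if (method == "add_k") as.numeric(k) else 0,
         alphabet_size = as.integer(alphabet_size)),
    class = "smoothing_config"
  )
}

sliding_windows <- function(s, n) {
  L <- nchar(s)
  if (L < n) return(character(0))
  substring(s, 1:(L - n + 1), n:L)
}

count_map <- function(grams) {
  if (length(grams) == 0L) {
    return(integer(0))
  }
  tab <- table(grams)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(names(counts))]
}

#' Count amino-acid n-grams in a corpus
#'
#' Windows are taken strictly within each sequence (never across sequence
#' boundaries), so a sequence of length L contributes `max(L - n + 1, 0)`
#' n-gram windows. Context counts are the raw (n-1)-window counts, kept for
#' diagnostics; note that the trailing context of every sequence never
#' extends to an n-gram, so the conditional-probability denominator used by
#' the models is the left-prefix marginal of the n-gram counts (see
#' [conditional_prob()]), which guarantees per-context normalization.
#'
#' @param corpus A `protein_corpus`.
#' @param order Window length n (integer >= 1).
#' @return An object of class `ngram_counts`: list with `order`, `counts`
#'   (named integer vector of n-gram counts, keys sorted), `context_counts`
#'   (raw (n-1)-window counts; for `order = 1` the single empty-string
#'   context carries the total residue count), and `total_tokens`.
#' @export
#' @examples
#' co <- protein_corpus("s1", "AAA")
#' count_ngrams(co, 2)  # counts AA = 2, context A = 3
count_ngrams <- function(corpus, order) {
  if (!inherits(corpus, "protein_corpus")) {
    stop("`corpus` must be a protein_corpus", call. = FALSE)
  }
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    stop("`order` must be a single integer >= 1", call. = FALSE)
  }
  order <- as.integer(order)
  grams <- unlist(lapply(corpus$seq, sliding_windows, n = order),
                  use.names = FALSE)
  if (length(grams) == 0L) {
    warning("all sequences shorter than order ", order,
            "; count table is empty", call. = FALSE)
  }
  counts <- count_map(grams)
  if (order == 1L) {
    context_counts <- c(sum(nchar(corpus$seq)))
    names(context_counts) <- ""
  } else {
    ctx <- unlist(lapply(corpus$seq, sliding_windows, n = order - 1L),
                  use.names = FALSE)
    context_counts <- count_map(ctx)
  }
  structure(
    list(order = order, counts = counts, context_counts = context_counts,
         total_tokens = sum(counts)),
    class = "ngram_counts"
  )
}

# Left-prefix marginal of the n-gram counts: for each (n-1)-context c,
# sum over residues r of counts[c + r]. This is the normalizing denominator.
prefix_marginals <- function(counts_obj) {
  n <- counts_obj$order
  cnt <- counts_obj$counts
  if (length(cnt) == 0L) return(numeric(0))
  ctx <- if (n == 1L) rep("", length(cnt)) else substr(names(cnt), 1L, n - 1L)
  m <- vapply(split(as.numeric(cnt), ctx), sum, numeric(1))
  m[order(names(m))]
}

#' Train an n-gram model on a corpus
#'
#' Estimates the conditional probabilities
#' `P(a_i | a_{i-n+1} ... a_{i-1})` by maximum likelihood — the ratio of the
#' n-gram count to its left-prefix context marginal — with optional additive
#' smoothing. Count tables for all orders `1..order` are stored so that a
#' sequence can optionally be scored with the full chain-rule factorization
#' (lower-order terms for the first n-1 positions; see [log_likelihood()]).
#'
#' @param corpus A `protein_corpus` of training sequences.
#' @param order Model order n (the Markov memory is n-1 residues).
#' @param smoothing A [smoothing_config()]; its `alphabet_size` is set from
#'   `alphabet`.
#' @param alphabet Residue alphabet the model normalizes over (default the
#'   canonical 20). Training sequences must not contain residues outside it.
#' @return An object of class `ngram_model`.
#' @export
train_ngram_model <- function(corpus, order,
                              smoothing = smoothing_config(),
                              alphabet = aa_alphabet()) {
  if (!inherits(smoothing, "smoothing_config")) {
    stop("`smoothing` must be a smoothing_config", call. = FALSE)
  }
  smoothing$alphabet_size <- length(alphabet)
  seen <- unique(strsplit(paste(corpus$seq, collapse = ""), "")[[1]])
  extra <- setdiff(seen, alphabet)
  if (length(extra) > 0L) {
    stop("training sequences contain residues outside the alphabet: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  order <- as.integer(order)
  tables <- lapply(seq_len(order), function(j) count_ngrams(corpus, j))
  marginals <- lapply(tables, prefix_marginals)
  structure(
    list(order = order,
         smoothing = smoothing,
         alphabet = alphabet,
         class_label = corpus$label,
         n_sequences = length(corpus),
         n_residues = sum(nchar(corpus$seq)),
         tables = tables,
         marginals = marginals),
    class = "ngram_model"
  )
}

#' @export
print.ngram_model <- function(x, ...) {
  cat(sprintf(
    "ngram_model (order %d, %s%s) for class '%s': %d sequences, %d residues, %d distinct %d-grams\n",
    x$order, x$smoothing$method,
    if (x$smoothing$method == "add_k") sprintf(" k=%g", x$smoothing$k) else "",
    x$class_label, x$n_sequences, x$n_residues,
    length(x$tables[[x$order]]$counts), x$order))
  invisible(x)
}

# Vectorized conditional probability lookup at a given order j.
# Unseen-context handling: "error" raises the undefined-context error
# required of conditional_prob(); "zero" returns 0 so that log_likelihood()
# can convert it into the -Inf sentinel rather than an exception.
cond_prob_lookup <- function(model, contexts, residues, j,
                             unseen_context = c("error", "zero")) {
  unseen_context <- match.arg(unseen_context)
  cnt <- model$tables[[j]]$counts
  marg <- model$marginals[[j]]
  key <- paste0(contexts, residues)
  num <- as.numeric(cnt[key])
  num[is.na(num)] <- 0
  ctx_key <- if (j == 1L) rep("", length(contexts)) else contexts
  if (j == 1L) {
    # the single empty-string context: R cannot index a vector by the empty
    # name, so take the marginal directly
    den <- rep(if (length(marg) > 0L) as.numeric(marg[[1]]) else 0,
               length(contexts))
  } else {
    den <- as.numeric(marg[ctx_key])
    den[is.na(den)] <- 0
  }
  sm <- model$smoothing
  if (sm$method == "add_k") {
    (num + sm$k) / (den + sm$k * sm$alphabet_size)
  } else {
    if (any(den == 0)) {
      if (unseen_context == "error") {
        bad <- unique(ctx_key[den == 0])
        stop("undefined context under MLE (never observed in training): ",
             paste(sprintf("'%s'", bad), collapse = ", "), call. = FALSE)
      }
      out <- numeric(length(num))
      ok <- den > 0
      out[ok] <- num[ok] / den[ok]
      return(out)
    }
    num / den
  }
}

#' Conditional probability of a residue given its context
#'
#' Under pure MLE (`method = "none"`) this is the n-gram count divided by
#' the left-prefix context marginal; a context never observed in training is
#' an explicit error. Under add-k smoothing it is
#' `(count + k) / (context + k * alphabet_size)`, defined for every context
#' (an entirely unseen context gives the uniform `1/alphabet_size`).
#'
#' @param model An `ngram_model`.
#' @param context Residue string of length `order - 1` (empty string for a
#'   unigram model). Vectorized.
#' @param residue Single residue character (vectorized, recycled against
#'   `context`).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
conditional_prob <- function(model, context, residue) {
  if (!inherits(model, "ngram_model")) {
    stop("`model` must be an ngram_model", call. = FALSE)
  }
  if (any(nchar(context) != model$order - 1L)) {
    stop("`context` must have length order - 1 = ", model$order - 1L,
         call. = FALSE)
  }
  if (any(nchar(residue) != 1L) || any(!(residue %in% model$alphabet))) {
    stop("`residue` must be a single canonical residue", call. = FALSE)
  }
  n <- max(length(context), length(residue))
  context <- rep_len(context, n)
  residue <- rep_len(residue, n)
  cond_prob_lookup(model, context, residue, model$order,
                   unseen_context = "error")
}

#' Log-likelihood of a sequence under an n-gram model
#'
#' Computes the Markov-approximated sequence likelihood as a sum of log
#' conditional probabilities (the log of the product form of the chain
#' rule). With `prefix = "eq"` (default) scoring starts at position n and
#' the first n-1 positions are discarded; with `prefix = "chain"` positions
#' `1..n-1` are additionally scored with the stored lower-order models so
#' the full chain-rule factorization telescopes (and sequences shorter than
#' the order remain scoreable).
#'
#' Any zero-probability factor — including an unseen context under pure
#' MLE — yields the `-Inf` sentinel, never an exception.
#'
#' @param model An `ngram_model`.
#' @param seq A residue string, or a single-sequence `protein_corpus` (its
#'   first sequence is scored).
#' @param prefix `"truncate"` (score positions n..L only) or `"chain"` (full
#'   factorization).
#' @return Log-likelihood in natural-log units, with attribute `"positions"`
#'   giving the number of scored positions.
#' @export
log_likelihood <- function(model, seq, prefix = c("truncate", "chain")) {
  prefix <- match.arg(prefix)
  if (inherits(seq, "protein_corpus")) seq <- seq$seq[1]
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("`seq` must be a single non-empty residue string", call. = FALSE)
  }
  n <- model$order
  L <- nchar(seq)
  if (prefix == "truncate" && L < n) {
    stop(sprintf(
      "sequence of length %d is shorter than model order %d; use prefix = \"chain\" to score it with lower-order terms",
      L, n), call. = FALSE)
  }
  ll <- 0
  pos <- 0L
  if (L >= n) {
    grams <- sliding_windows(seq, n)
    ctx <- if (n == 1L) rep("", length(grams)) else substr(grams, 1L, n - 1L)
    res <- substr(grams, n, n)
    p <- cond_prob_lookup(model, ctx, res, n, unseen_context = "zero")
    ll <- ll + sum(log(p))
    pos <- pos + length(grams)
  }
  if (prefix == "chain") {
    for (i in seq_len(min(n - 1L, L))) {
      ctx_i <- if (i == 1L) "" else substr(seq, 1L, i - 1L)
      res_i <- substr(seq, i, i)
      p <- cond_prob_lookup(model, ctx_i, res_i, i, unseen_context = "zero")
      ll <- ll + log(p)
      pos <- pos + 1L
    }
  }
  structure(ll, positions = pos)
}

#' Perplexity of a model on a corpus
#'
#' The exponential of the average negative log-likelihood per scored
#' position: the model's effective branching factor on the corpus. A uniform
#' model over k residues has perplexity exactly k; any `-Inf` sequence
#' log-likelihood gives `+Inf` perplexity.
#'
#' @param model An `ngram_model`.
#' @param corpus A `protein_corpus`.
#' @param prefix Scoring mode passed to [log_likelihood()].
#' @return A single positive number (possibly `Inf`).
#' @export
perplexity <- function(model, corpus, prefix = c("truncate", "chain")) {
  prefix <- match.arg(prefix)
  lls <- lapply(corpus$seq, function(s) log_likelihood(model, s, prefix))
  total_ll <- sum(vapply(lls, as.numeric, numeric(1)))
  total_pos <- sum(vapply(lls, function(x) attr(x, "positions"), integer(1)))
  if (total_pos == 0L) {
    stop("no scoreable positions in corpus", call. = FALSE)
  }
  if (is.infinite(total_ll)) return(Inf)
  exp(-total_ll / total_pos)
}
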