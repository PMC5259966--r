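all_contexts <- function(alphabet, m) {
  if (m == 0L) return("")
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), m),
                    list(stringsAsFactors = FALSE)))
  # vary the last position fastest so contexts come out in lexicographic order
  sort(apply(grid, 1, paste, collapse = ""))
}

#' Specify a Markov chain over a residue alphabet
#'
#' Fully determines a sequence-generating process: an alphabet, a Markov
#' memory `order` m (0 = i.i.d.), a transition matrix giving
#' `P(next residue | previous m residues)`, and an initial distribution over
#' m-residue contexts. Used to simulate protein-like corpora with known
#' statistics for parameter-recovery, perplexity and classification-power
#' experiments.
#'
#' @param transition For `order >= 1`: a numeric matrix with one row per
#'   m-length context (rownames) and one column per residue (colnames);
#'   each row sums to 1. If rownames are missing, all `length(alphabet)^m`
#'   contexts in lexicographic order are assumed. For `order = 0`: a
#'   probability vector over the alphabet (names optional).
#' @param alphabet Residue alphabet (default taken from the transition
#'   matrix colnames, falling back to [aa_alphabet()]).
#' @param order Markov memory m >= 0. Note an order-m chain is matched by an
#'   (m+1)-gram model.
#' @param initial Probability vector over contexts for the first m residues.
#'   Default: the stationary distribution of the context chain.
#' @return An object of class `chain_spec`.
#' @export
#' @examples
#' # symmetric 2-state chain with flip probability 0.1
#' tm <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE,
#'              dimnames = list(c("A", "C"), c("A", "C")))
#' chain_spec(tm, order = 1)
chain_spec <- function(transition, alphabet = NULL, order = 1L,
                       initial = NULL) {
  order <- as.integer(order)
  if (order < 0L) stop("`order` must be >= 0", call. = FALSE)
  if (order == 0L) {
    p <- as.numeric(transition)
    if (is.null(alphabet)) {
      alphabet <- names(transition) %||% aa_alphabet()[seq_along(p)]
    }
    if (length(p) != length(alphabet)) {
      stop("probability vector length must match the alphabet", call. = FALSE)
    }
    transition <- matrix(p, nrow = 1,
                         dimnames = list("", alphabet))
  } else {
    transition <- as.matrix(transition)
    if (is.null(alphabet)) alphabet <- colnames(transition)
    if (is.null(alphabet)) {
      stop("`alphabet` required when the transition matrix has no colnames",
           call. = FALSE)
    }
    colnames(transition) <- alphabet
    if (is.null(rownames(transition))) {
      ctx <- all_contexts(alphabet, order)
      if (nrow(transition) != length(ctx)) {
        stop("transition matrix must have one row per context (",
             length(ctx), " expected)", call. = FALSE)
      }
      rownames(transition) <- ctx
    }
    if (any(nchar(rownames(transition)) != order)) {
      stop("context rownames must have length `order`", call. = FALSE)
    }
  }
  if (any(transition < 0)) {
    stop("transition probabilities must be non-negative", call. = FALSE)
  }
  rs <- rowSums(transition)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("every transition row must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  spec <- structure(
    list(alphabet = alphabet, order = order, transition = transition,
         initial = NULL),
    class = "chain_spec"
  )
  if (order == 0L) {
    spec$initial <- stats::setNames(as.numeric(transition[1, ]), alphabet)
  } else if (is.null(initial)) {
    spec$initial <- stationary_context_dist(spec)
  } else {
    initial <- as.numeric(initial)
    if (length(initial) != nrow(transition) ||
        any(initial < 0) || abs(sum(initial) - 1) > 1e-12) {
      stop("`initial` must be a probability vector over the ",
           nrow(transition), " contexts", call. = FALSE)
    }
    spec$initial <- stats::setNames(initial, rownames(transition))
  }
  spec
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("chain_spec: order %d over %d-letter alphabet {%s}\n",
              x$order, length(x$alphabet),
              paste(x$alphabet, collapse = "")))
  invisible(x)
}

# Context-level transition matrix Q[c, c'] for the context process of an
# order-m chain (m >= 1): emitting residue r from context c moves to the
# context formed by dropping the oldest residue and appending r.
context_transition_matrix <- function(spec) {
  tm <- spec$transition
  ctx <- rownames(tm)
  m <- spec$order
  Q <- matrix(0, nrow = length(ctx), ncol = length(ctx),
              dimnames = list(ctx, ctx))
  for (c_i in ctx) {
    for (r in spec$alphabet) {
      p <- tm[c_i, r]
      if (p > 0) {
        nxt <- paste0(substr(c_i, 2L, m), r)
        if (!nxt %in% ctx) {
          stop("transition undefined for reachable context '", nxt, "'",
               call. = FALSE)
        }
        Q[c_i, nxt] <- Q[c_i, nxt] + p
      }
    }
  }
  Q
}

reachable_from <- function(adj, start) {
  seen <- stats::setNames(rep(FALSE, nrow(adj)), rownames(adj))
  queue <- start
  seen[queue] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1]
    queue <- queue[-1]
    nxt <- rownames(adj)[adj[v, ] & !seen]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  names(seen)[seen]
}

stationary_context_dist <- function(spec, start = NULL) {
  Q <- context_transition_matrix(spec)
  ctx <- rownames(Q)
  adj <- Q > 0
  if (is.null(start)) start <- ctx[1]
  fwd <- reachable_from(adj, start)
  # every context reachable from the start set must be able to return to
  # it, otherwise the chain is reducible and has no unique stationary
  # distribution over the reachable contexts
  bwd <- reachable_from(t(adj), start)
  stray <- setdiff(fwd, bwd)
  if (length(stray) > 0L) {
    stop("chain is reducible; contexts outside the recurrent class: ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  Qr <- Q[fwd, fwd, drop = FALSE]
  n <- nrow(Qr)
  # solve pi Q = pi with sum(pi) = 1 as an overdetermined linear system
  A <- rbind(t(Qr) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_r <- qr.solve(A, b)
  pi_full <- stats::setNames(rep(0, length(ctx)), ctx)
  pi_full[fwd] <- pi_r
  pi_full
}

#' Entropy rate of a chain specification
#'
#' The asymptotic per-residue entropy (nats): for an i.i.d. spec it is the
#' entropy of the residue distribution; for an order-m chain it is the
#' stationary-weighted average of the per-context transition entropies.
#' `exp(entropy rate)` is the perplexity floor any model can achieve on
#' long samples from the chain.
#'
#' @param spec A `chain_spec`. The context chain must be irreducible over
#'   the contexts reachable from its initial support.
#' @return Entropy rate in nats (non-negative).
#' @export
chain_entropy_rate <- function(spec) {
  if (!inherits(spec, "chain_spec")) {
    stop("`spec` must be a chain_spec", call. = FALSE)
  }
  tm <- spec$transition
  plogp <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  if (spec$order == 0L) {
    return(plogp(tm[1, ]))
  }
  pi_ctx <- stationary_context_dist(
    spec, start = names(spec$initial)[spec$initial > 0])
  h_ctx <- apply(tm, 1, plogp)
  sum(pi_ctx[rownames(tm)] * h_ctx)
}

sample_from <- function(cum, values) {
  values[findInterval(stats::runif(1), cum) + 1L]
}

#' Sample one sequence from a chain specification
#'
#' The first m residues are drawn from the initial context distribution and
#' every subsequent residue from the transition row of the current context.
#' With `seed` set, the draw is fully reproducible; with `seed = NULL` the
#' current RNG stream is used (this is how [generate_labeled_corpora()]
#' derives per-sequence substreams).
#'
#' @param spec A `chain_spec`.
#' @param length Sequence length (>= max(order, 1)).
#' @param seed Optional integer seed.
#' @param id Sequence identifier (default `"sim"`).
#' @return A single-sequence `protein_corpus`.
#' @export
sample_sequence <- function(spec, length, seed = NULL, id = "sim") {
  if (!inherits(spec, "chain_spec")) {
    stop("`spec` must be a chain_spec", call. = FALSE)
  }
  length <- as.integer(length)
  if (length < max(spec$order, 1L)) {
    stop("`length` must be at least max(order, 1) = ",
         max(spec$order, 1L), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- spec$order
  if (m == 0L) {
    s <- paste(sample(spec$alphabet, length, replace = TRUE,
                      prob = spec$initial),
               collapse = "")
    return(protein_corpus(id, s, label = "simulated"))
  }
  ctx_names <- rownames(spec$transition)
  cum_init <- cumsum(spec$initial)
  cum_trans <- t(apply(spec$transition, 1, cumsum))
  ctx <- sample_from(cum_init, ctx_names)
  res <- character(length)
  res[seq_len(m)] <- strsplit(ctx, "")[[1]]
  if (length > m) {
    for (i in (m + 1L):length) {
      r <- sample_from(cum_trans[ctx, ], spec$alphabet)
      res[i] <- r
      ctx <- paste0(substr(ctx, 2L, m), r)
    }
  }
  protein_corpus(id, paste(res, collapse = ""), label = "simulated")
}

# Deterministic substream seed: one root seed, per-(stream, index) offsets,
# kept below 2^31 so set.seed() accepts it on every platform.
substream_seed <- function(seed, stream, index) {
  as.integer((as.numeric(seed) * 48271 + stream * 7919009 +
                index * 104729) %% 2147483647)
}

#' Generate two labeled corpora from two chain specifications
#'
#' Draws `n_per_class` sequences per class with systematic ids
#' (`classA_0001`, ...). Each sequence uses its own substream derived from
#' the root seed, so generation is reproducible and independent of order of
#' evaluation; the two classes use disjoint substreams.
#'
#' @param spec_a,spec_b `chain_spec` objects for the two classes.
#' @param n_per_class Number of sequences per class (>= 1).
#' @param length Either a single fixed length or a length-2 vector
#'   `c(min, max)` for uniform integer lengths.
#' @param seed Root integer seed.
#' @param labels Corpus labels, default `c("classA", "classB")`.
#' @return A list of two `protein_corpus` objects named by `labels`.
#' @export
generate_labeled_corpora <- function(spec_a, spec_b, n_per_class,
                                     length = 300L, seed = 1L,
                                     labels = c("classA", "classB")) {
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop("`n_per_class` must be >= 1", call. = FALSE)
  }
  n_per_class <- as.integer(n_per_class)
  length <- as.integer(length)
  if (!(base::length(length) %in% c(1L, 2L)) || any(is.na(length))) {
    stop("`length` must be a fixed value or c(min, max)", call. = FALSE)
  }
  min_len <- max(spec_a$order, spec_b$order, 1L)
  if (base::length(length) == 2L && length[1] > length[2]) {
    stop("`length` bounds must satisfy min <= max", call. = FALSE)
  }
  if (any(length < min_len)) {
    stop("`length` must be at least the larger chain order (", min_len, ")",
         call. = FALSE)
  }
  one_class <- function(spec, stream, label) {
    ids <- sprintf("%s_%04d", label, seq_len(n_per_class))
    seqs <- vapply(seq_len(n_per_class), function(i) {
      set.seed(substream_seed(seed, stream, i))
      L <- if (base::length(length) == 2L) {
        # sample.int avoids the base-R scalar expansion of sample()
        length[1] + sample.int(length[2] - length[1] + 1L, 1L) - 1L
      } else {
        length
      }
      sample_sequence(spec, L)$seq
    }, character(1))
    protein_corpus(ids, seqs, label = label)
  }
  out <- list(one_class(spec_a, 1L, labels[1]),
              one_class(spec_b, 2L, labels[2]))
  names(out) <- labels
  out
}
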