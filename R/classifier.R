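#' Estimate class priors from corpus sizes
#'
#' Maximum-likelihood priors: the probability of the human class is the
#' fraction of training sequences that are human. With the post-filtering
#' Swiss-Prot corpus sizes (14189 human, 59060 non-human) this gives
#' `P(H) ~ 0.194`.
#'
#' @param n_human,n_nonhuman Positive integer corpus sizes.
#' @return An object of class `class_priors`: list with `p_human`,
#'   `p_nonhuman`, `n_human`, `n_nonhuman`.
#' @export
#' @examples
#' estimate_priors(14189, 59060)
estimate_priors <- function(n_human, n_nonhuman) {
  for (v in list(n_human, n_nonhuman)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop("corpus sizes must be positive integers", call. = FALSE)
    }
  }
  total <- n_human + n_nonhuman
  structure(
    list(p_human = n_human / total,
         p_nonhuman = n_nonhuman / total,
         n_human = as.integer(n_human),
         n_nonhuman = as.integer(n_nonhuman)),
    class = "class_priors"
  )
}

#' Build priors from explicit probabilities
#'
#' @param p_human Probability of the human class, strictly between 0 and 1.
#' @return A `class_priors` object with `p_nonhuman = 1 - p_human`.
#' @export
class_priors <- function(p_human) {
  if (!is.numeric(p_human) || length(p_human) != 1L ||
      p_human <= 0 || p_human >= 1) {
    stop("`p_human` must be strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(p_human = p_human, p_nonhuman = 1 - p_human,
         n_human = NA_integer_, n_nonhuman = NA_integer_),
    class = "class_priors"
  )
}

#' @export
print.class_priors <- function(x, ...) {
  cat(sprintf("class_priors: P(H) = %.6g, P(NH) = %.6g\n",
              x$p_human, x$p_nonhuman))
  invisible(x)
}

check_model_pair <- function(model_h, model_nh) {
  if (model_h$order != model_nh$order) {
    stop("model order mismatch: ", model_h$order, " vs ", model_nh$order,
         call. = FALSE)
  }
  sh <- model_h$smoothing
  sn <- model_nh$smoothing
  if (!identical(sh$method, sn$method) || !identical(sh$k, sn$k) ||
      !identical(sh$alphabet_size, sn$alphabet_size)) {
    stop("smoothing configuration mismatch between the two models",
         call. = FALSE)
  }
  if (!identical(model_h$alphabet, model_nh$alphabet)) {
    stop("alphabet mismatch between the two models", call. = FALSE)
  }
  invisible(TRUE)
}

decision_row <- function(id, seq, model_h, model_nh, priors, prefix) {
  lh <- log_likelihood(model_h, seq, prefix = prefix)
  lnh <- log_likelihood(model_nh, seq, prefix = prefix)
  pos <- attr(lh, "positions")
  log_odds <- (log(priors$p_human) + as.numeric(lh)) -
    (log(priors$p_nonhuman) + as.numeric(lnh))
  unscoreable <- is.nan(log_odds)  # -Inf under both models
  label <- if (unscoreable || log_odds == 0) "tie"
           else if (log_odds > 0) "human" else "non-human"
  data.frame(
    id = id,
    length = nchar(seq),
    loglik_human = as.numeric(lh),
    loglik_nonhuman = as.numeric(lnh),
    log_odds = log_odds,
    log_odds_per_pos = if (pos > 0) log_odds / pos else NaN,
    label = label,
    unscoreable = unscoreable,
    stringsAsFactors = FALSE
  )
}

#' Score one sequence under the two-class Bayesian decision rule
#'
#' Computes the posterior log-odds
#' `[log P(H) + log P(seq | H)] - [log P(NH) + log P(seq | NH)]` (the shared
#' evidence term cancels) and labels the sequence `human` when the log-odds
#' is positive, `non-human` when negative, and `tie` at exactly zero.
#' A `-Inf` likelihood on one side forces the opposite label; `-Inf` on both
#' sides gives `tie` with `unscoreable = TRUE`.
#'
#' @param seq Residue string (or single-sequence `protein_corpus`).
#' @param model_h,model_nh Trained [train_ngram_model()] objects for the
#'   human and non-human class; they must share order, smoothing and
#'   alphabet.
#' @param priors A `class_priors` object.
#' @param id Identifier recorded in the decision (default `"query"`).
#' @param prefix Scoring mode passed to [log_likelihood()].
#' @return A one-row decision data frame with columns `id`, `length`,
#'   `loglik_human`, `loglik_nonhuman`, `log_odds`, `log_odds_per_pos`
#'   (log-odds divided by the number of scored positions), `label`,
#'   `unscoreable`.
#' @export
score_sequence <- function(seq, model_h, model_nh, priors, id = "query",
                           prefix = c("truncate", "chain")) {
  prefix <- match.arg(prefix)
  check_model_pair(model_h, model_nh)
  if (inherits(seq, "protein_corpus")) {
    id <- seq$id[1]
    seq <- seq$seq[1]
  }
  decision_row(id, seq, model_h, model_nh, priors, prefix)
}

#' Classify every sequence in a corpus
#'
#' Applies [score_sequence()] to each sequence (input order preserved) and
#' labels a sequence `human` only when its log-odds exceeds `margin`;
#' `margin = 0` reproduces the bare posterior comparison. Exact zero
#' log-odds is always a `tie`.
#'
#' @param corpus A `protein_corpus` of query sequences.
#' @param model_h,model_nh Trained models for the two classes.
#' @param priors A `class_priors` object.
#' @param margin Non-negative log-odds threshold for the `human` call
#'   (default 0).
#' @param prefix Scoring mode passed to [log_likelihood()].
#' @return An object of class `classification`: list with `decisions` (data
#'   frame, one row per query in input order), `summary` (named counts
#'   `n_human`, `n_nonhuman`, `n_tie`, `n_unscoreable`), and `margin`.
#' @export
classify_corpus <- function(corpus, model_h, model_nh, priors, margin = 0,
                            prefix = c("truncate", "chain")) {
  prefix <- match.arg(prefix)
  if (!inherits(corpus, "protein_corpus") || length(corpus) == 0L) {
    stop("`corpus` must be a non-empty protein_corpus", call. = FALSE)
  }
  if (!is.numeric(margin) || length(margin) != 1L || is.na(margin) ||
      margin < 0) {
    stop("`margin` must be a single non-negative number", call. = FALSE)
  }
  check_model_pair(model_h, model_nh)
  rows <- lapply(seq_along(corpus$id), function(i) {
    decision_row(corpus$id[i], corpus$seq[i], model_h, model_nh, priors,
                 prefix)
  })
  d <- do.call(rbind, rows)
  relabel <- !d$unscoreable & d$log_odds != 0
  d$label[relabel] <- ifelse(d$log_odds[relabel] > margin,
                             "human", "non-human")
  structure(
    list(
      decisions = d,
      summary = c(n_human = sum(d$label == "human"),
                  n_nonhuman = sum(d$label == "non-human"),
                  n_tie = sum(d$label == "tie"),
                  n_unscoreable = sum(d$unscoreable)),
      margin = margin
    ),
    class = "classification"
  )
}

#' @export
print.classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "classification of %d sequences (margin %g): %d human, %d non-human, %d tie (%d unscoreable)\n",
    nrow(x$decisions), x$margin, s[["n_human"]], s[["n_nonhuman"]],
    s[["n_tie"]], s[["n_unscoreable"]]))
  invisible(x)
}
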