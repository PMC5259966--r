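write_json_file <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con = con, sep = "\n")
  invisible(path)
}

log_stage <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...)))
}

#' Train the two-class models from FASTA files
#'
#' The full training pipeline: read and sanitize both corpora, optionally
#' de-duplicate each independently with [greedy_cluster()], train one n-gram
#' model per class, and estimate class priors from the post-deduplication
#' corpus sizes (redundancy filtering happens before counting, matching the
#' order of operations of the reference screening pipeline). Writes
#' `H.json`, `NH.json`, `priors.json` and an effective-configuration dump
#' `run_config.json` to `out_dir`; reruns with identical inputs and
#' configuration produce byte-identical files.
#'
#' @param human_fasta,nonhuman_fasta Paths to the two training FASTA files.
#' @param out_dir Output directory (created if missing).
#' @param order Model order n (default 3).
#' @param smoothing A [smoothing_config()] (default add-k with k = 0.01).
#' @param dedup_threshold Optional identity threshold in (0, 1]; when set,
#'   each corpus is reduced to cluster representatives before training
#'   (0.9 reproduces the standard redundancy stage).
#' @param policy Residue sanitization policy (see [sanitize_residues()]).
#' @param alphabet Model alphabet (default the canonical 20).
#' @param prior_counts `"post_dedup"` (default) or `"pre_dedup"`, selecting
#'   which corpus sizes feed [estimate_priors()] (the latter is available
#'   for sensitivity analysis).
#' @return Invisibly, a list with `model_h`, `model_nh`, `priors` and the
#'   output `paths`.
#' @export
train_models <- function(human_fasta, nonhuman_fasta, out_dir,
                         order = 3L,
                         smoothing = smoothing_config(),
                         dedup_threshold = NULL,
                         policy = "drop",
                         alphabet = aa_alphabet(),
                         prior_counts = c("post_dedup", "pre_dedup")) {
  prior_counts <- match.arg(prior_counts)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  human <- read_fasta(human_fasta, label = "human", policy = policy,
                      alphabet = alphabet)
  nonhuman <- read_fasta(nonhuman_fasta, label = "non-human", policy = policy,
                         alphabet = alphabet)
  n_pre <- c(human = length(human), nonhuman = length(nonhuman))
  log_stage("read %d human and %d non-human sequences",
            n_pre[["human"]], n_pre[["nonhuman"]])
  if (!is.null(dedup_threshold)) {
    human <- greedy_cluster(human, dedup_threshold)$representatives
    nonhuman <- greedy_cluster(nonhuman, dedup_threshold)$representatives
    log_stage("redundancy filtering at %g%% identity: %d -> %d human, %d -> %d non-human",
              100 * dedup_threshold,
              n_pre[["human"]], length(human),
              n_pre[["nonhuman"]], length(nonhuman))
  }
  model_h <- train_ngram_model(human, order, smoothing, alphabet)
  model_nh <- train_ngram_model(nonhuman, order, smoothing, alphabet)
  priors <- if (prior_counts == "post_dedup") {
    estimate_priors(length(human), length(nonhuman))
  } else {
    estimate_priors(n_pre[["human"]], n_pre[["nonhuman"]])
  }
  paths <- list(
    model_h = file.path(out_dir, "H.json"),
    model_nh = file.path(out_dir, "NH.json"),
    priors = file.path(out_dir, "priors.json"),
    config = file.path(out_dir, "run_config.json")
  )
  save_ngram_model(model_h, paths$model_h)
  save_ngram_model(model_nh, paths$model_nh)
  write_json_file(
    list(n_human = priors$n_human, n_nonhuman = priors$n_nonhuman,
         p_human = priors$p_human, p_nonhuman = priors$p_nonhuman),
    paths$priors
  )
  write_json_file(
    list(command = "train",
         human_fasta = human_fasta, nonhuman_fasta = nonhuman_fasta,
         order = order,
         smoothing = list(method = smoothing$method, k = smoothing$k),
         dedup_threshold = dedup_threshold,
         policy = policy,
         alphabet = paste(alphabet, collapse = ""),
         prior_counts = prior_counts,
         n_pre_dedup = as.list(n_pre),
         n_trained = list(human = model_h$n_sequences,
                          nonhuman = model_nh$n_sequences)),
    paths$config
  )
  log_stage("trained order-%d models; priors P(H) = %.5f", order,
            priors$p_human)
  invisible(list(model_h = model_h, model_nh = model_nh, priors = priors,
                 paths = paths))
}

#' Classify a query FASTA against saved models
#'
#' Loads the two model files and the priors, reads and sanitizes the query
#' corpus, scores every sequence with [classify_corpus()], and writes the
#' ranked TSV report plus a machine-readable run summary. A per-label count
#' summary goes to the message stream.
#'
#' @param human_model,nonhuman_model Paths to model files written by
#'   [save_ngram_model()].
#' @param priors_file Path to the priors JSON written by [train_models()]
#'   (fields `n_human`, `n_nonhuman` or `p_human`).
#' @param query_fasta Path to the query FASTA.
#' @param out_tsv Output TSV report path.
#' @param margin Non-negative log-odds margin for the `human` call.
#' @param policy Sanitization policy for the query sequences.
#' @param prefix Scoring mode passed to [log_likelihood()].
#' @return Invisibly, the `classification` object.
#' @export
classify_files <- function(human_model, nonhuman_model, priors_file,
                           query_fasta, out_tsv, margin = 0,
                           policy = "drop",
                           prefix = c("truncate", "chain")) {
  prefix <- match.arg(prefix)
  model_h <- load_ngram_model(human_model)
  model_nh <- load_ngram_model(nonhuman_model)
  pj <- jsonlite::fromJSON(readLines(priors_file, warn = FALSE))
  priors <- if (!is.null(pj$n_human) && !is.null(pj$n_nonhuman)) {
    estimate_priors(pj$n_human, pj$n_nonhuman)
  } else if (!is.null(pj$p_human)) {
    class_priors(pj$p_human)
  } else {
    stop("priors file must contain n_human/n_nonhuman or p_human",
         call. = FALSE)
  }
  query <- read_fasta(query_fasta, label = "query", policy = policy,
                      alphabet = model_h$alphabet)
  cl <- classify_corpus(query, model_h, model_nh, priors, margin = margin,
                        prefix = prefix)
  write_tsv_report(cl$decisions, out_tsv)
  s <- cl$summary
  log_stage("classified %d queries: %d human, %d non-human, %d tie (%d unscoreable)",
            nrow(cl$decisions), s[["n_human"]], s[["n_nonhuman"]],
            s[["n_tie"]], s[["n_unscoreable"]])
  write_json_file(
    list(command = "classify", query_fasta = query_fasta,
         margin = margin, prefix = prefix,
         summary = as.list(s)),
    paste0(out_tsv, ".summary.json")
  )
  invisible(cl)
}

#' Select the model order by held-out perplexity
#'
#' Splits the corpus into training and held-out subsets (deterministic for
#' a given seed), trains one model per candidate order on the training
#' part, and evaluates held-out perplexity. The recommended order is the
#' perplexity minimizer; orders exceeding the longest training sequence are
#' flagged rather than fatal.
#'
#' @param corpus A `protein_corpus` with at least 2 sequences.
#' @param orders Integer vector of candidate orders (default 1:4).
#' @param holdout_fraction Fraction of sequences held out, in (0, 1)
#'   (default 0.2; at least one sequence is always held out).
#' @param seed Integer seed for the split.
#' @param smoothing A [smoothing_config()]; smoothing keeps high-order
#'   models finite on held-out n-grams never seen in training.
#' @param alphabet Model alphabet.
#' @return A data frame with columns `order`, `perplexity`, `flagged`, with
#'   attribute `"recommended_order"`.
#' @export
select_order <- function(corpus, orders = 1:4, holdout_fraction = 0.2,
                         seed = 1L, smoothing = smoothing_config(),
                         alphabet = aa_alphabet()) {
  if (!inherits(corpus, "protein_corpus") || length(corpus) < 2L) {
    stop("`corpus` must contain at least 2 sequences", call. = FALSE)
  }
  if (!is.numeric(holdout_fraction) || length(holdout_fraction) != 1L ||
      holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("`holdout_fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- length(corpus)
  n_hold <- max(1L, round(n * holdout_fraction))
  hold <- sort(sample(n, n_hold))
  train <- corpus[setdiff(seq_len(n), hold)]
  heldout <- corpus[hold]
  max_len <- max(nchar(train$seq))
  rows <- lapply(orders, function(o) {
    if (o > max_len) {
      return(data.frame(order = o, perplexity = NA_real_, flagged = TRUE))
    }
    model <- train_ngram_model(train, o, smoothing, alphabet)
    # held-out sequences shorter than the order are scored with the full
    # chain-rule factorization so every order sees the same sequences
    pp <- perplexity(model, heldout, prefix = "chain")
    data.frame(order = o, perplexity = pp, flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- which(!out$flagged & is.finite(out$perplexity))
  attr(out, "recommended_order") <-
    if (length(ok) > 0) out$order[ok[which.min(out$perplexity[ok])]] else NA
  out
}
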