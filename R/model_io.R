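MODEL_SCHEMA_VERSION <- "1"

counts_to_list <- function(x) {
  # named integer vector -> named list with deterministic (sorted) key order
  x <- x[order(names(x))]
  out <- as.list(unname(as.integer(x)))
  names(out) <- names(x)
  out
}

list_to_counts <- function(x, what) {
  if (is.null(x)) {
    stop("model file schema error: missing '", what, "'", call. = FALSE)
  }
  v <- vapply(x, function(e) as.numeric(e)[1], numeric(1))
  if (any(is.na(v)) || any(v != round(v))) {
    stop("model file validation error: non-integer count in '", what, "'",
         call. = FALSE)
  }
  if (any(v < 0)) {
    stop("model file validation error: negative count in '", what, "'",
         call. = FALSE)
  }
  out <- as.integer(v)
  names(out) <- names(x) %||% rep("", length(out))
  out[order(names(out))]
}

#' Save an n-gram model to a versioned JSON file
#'
#' The document records the schema version, order, smoothing configuration,
#' alphabet, class label and all count tables with keys in sorted order, so
#' the file is diffable and byte-identical across reruns on the same input.
#'
#' @param model An `ngram_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_ngram_model()]
#' @export
save_ngram_model <- function(model, path) {
  if (!inherits(model, "ngram_model")) {
    stop("`model` must be an ngram_model", call. = FALSE)
  }
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    order = model$order,
    class_label = model$class_label,
    alphabet = paste(model$alphabet, collapse = ""),
    smoothing = list(method = model$smoothing$method,
                     k = model$smoothing$k,
                     alphabet_size = model$smoothing$alphabet_size),
    n_sequences = model$n_sequences,
    n_residues = model$n_residues,
    tables = lapply(model$tables, function(tb) {
      list(order = tb$order,
           total_tokens = tb$total_tokens,
           counts = counts_to_list(tb$counts),
           context_counts = counts_to_list(tb$context_counts))
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con = con, sep = "\n")
  invisible(path)
}

#' Load an n-gram model from a JSON file
#'
#' Validates the schema version, the presence of every count table and the
#' non-negativity of every count; the reloaded model reproduces every
#' conditional probability of the saved one exactly.
#'
#' @param path Path to a file written by [save_ngram_model()].
#' @return An `ngram_model`.
#' @export
load_ngram_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = FALSE)
  if (is.null(doc$schema_version) ||
      !identical(as.character(doc$schema_version), MODEL_SCHEMA_VERSION)) {
    stop("incompatible model file: schema_version '",
         doc$schema_version %||% "<missing>", "' (expected '",
         MODEL_SCHEMA_VERSION, "')", call. = FALSE)
  }
  for (f in c("order", "alphabet", "smoothing", "tables")) {
    if (is.null(doc[[f]])) {
      stop("model file schema error: missing '", f, "'", call. = FALSE)
    }
  }
  order <- as.integer(doc$order)
  if (length(doc$tables) != order) {
    stop("model file schema error: expected ", order, " count tables, found ",
         length(doc$tables), call. = FALSE)
  }
  alphabet <- strsplit(doc$alphabet, "")[[1]]
  sm <- smoothing_config(
    method = if (identical(doc$smoothing$method, "none")) "none" else "add_k",
    k = if (identical(doc$smoothing$method, "none")) 0.01
        else as.numeric(doc$smoothing$k),
    alphabet_size = as.integer(doc$smoothing$alphabet_size)
  )
  tables <- lapply(doc$tables, function(tb) {
    ctx_counts <- list_to_counts(tb$context_counts, "context_counts")
    if (identical(as.integer(tb$order), 1L)) {
      # the unigram table has the single empty-string context; JSON cannot
      # carry an empty object key, so restore it here
      names(ctx_counts) <- ""
    }
    structure(
      list(order = as.integer(tb$order),
           counts = list_to_counts(tb$counts, "counts"),
           context_counts = ctx_counts,
           total_tokens = as.integer(tb$total_tokens)),
      class = "ngram_counts"
    )
  })
  structure(
    list(order = order,
         smoothing = sm,
         alphabet = alphabet,
         class_label = as.character(doc$class_label %||% "unknown"),
         n_sequences = as.integer(doc$n_sequences %||% NA),
         n_residues = as.integer(doc$n_residues %||% NA),
         tables = tables,
         marginals = lapply(tables, prefix_marginals)),
    class = "ngram_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
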