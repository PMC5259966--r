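#' Sanitize a raw residue string
#'
#' Folds to uppercase, removes whitespace, and resolves characters outside
#' the model alphabet according to `policy`:
#' \describe{
#'   \item{`drop`}{(default) non-canonical characters (B, Z, X, U, O, J,
#'     `*`, gaps, ...) are removed; the rest of the sequence is kept. This
#'     preserves maximal training data while keeping the 20-letter event
#'     space of the model closed.}
#'   \item{`reject`}{any non-canonical character is an error naming the
#'     offending residue and its position.}
#'   \item{`map_x`}{non-canonical characters are first mapped to the
#'     ambiguity code `X`, and all `X` are then removed before modeling
#'     (same retained residues as `drop`, but substitutions and removals
#'     are reported separately by [read_fasta()]).}
#' }
#'
#' @param raw Single non-empty string of residue characters.
#' @param policy One of `"drop"`, `"reject"`, `"map_x"`.
#' @param alphabet Character vector of allowed residues
#'   (default [aa_alphabet()]).
#' @return Sanitized string containing only alphabet residues. Errors if the
#'   result would be empty.
#' @export
#' @examples
#' sanitize_residues("acde")            # "ACDE"
#' sanitize_residues("AC*DE")           # "ACDE"
#' try(sanitize_residues("ACBDE", policy = "reject"))
sanitize_residues <- function(raw, policy = c("drop", "reject", "map_x"),
                              alphabet = aa_alphabet()) {
  policy <- match.arg(policy)
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("`raw` must be a single non-empty string", call. = FALSE)
  }
  s <- toupper(gsub("[[:space:]]+", "", raw))
  chars <- strsplit(s, "")[[1]]
  bad <- !(chars %in% alphabet)
  if (any(bad)) {
    if (policy == "reject") {
      pos <- which(bad)[1]
      stop(sprintf("non-canonical residue '%s' at position %d",
                   chars[pos], pos), call. = FALSE)
    }
    chars <- chars[!bad]
  }
  out <- paste(chars, collapse = "")
  if (!nzchar(out)) stop("empty after sanitization", call. = FALSE)
  out
}

first_header_token <- function(x) sub("[[:space:]].*$", "", x)

#' Read a protein FASTA file into a corpus
#'
#' Parses a (multi-record, wrapped or unwrapped) FASTA file, takes the first
#' whitespace-delimited token of each header as the sequence id, and
#' sanitizes every record with [sanitize_residues()]. Records left empty by
#' sanitization are omitted; the omission is counted in the attached
#' sanitization report.
#'
#' @param path Path to a FASTA file (gzip-compressed files are accepted).
#' @param label Corpus label (e.g. `"human"`).
#' @param policy Sanitization policy passed to [sanitize_residues()].
#' @param alphabet Allowed residues (default the canonical 20).
#' @return A `protein_corpus` with attribute `"sanitization_report"`, a list
#'   with `n_records`, `n_kept`, `n_dropped_empty` (records removed because
#'   nothing survived sanitization), and `n_residues_removed`.
#' @export
read_fasta <- function(path, label = "corpus",
                       policy = c("drop", "reject", "map_x"),
                       alphabet = aa_alphabet()) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop(sprintf("malformed FASTA file '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop("no FASTA records in file: ", path, call. = FALSE)
  }
  ids <- first_header_token(names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA ids in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  raw <- unname(as.character(set))
  kept_id <- character(0)
  kept_seq <- character(0)
  n_dropped <- 0L
  n_removed <- 0L
  for (i in seq_along(raw)) {
    res <- tryCatch(
      sanitize_residues(raw[i], policy = policy, alphabet = alphabet),
      error = function(e) {
        msg <- conditionMessage(e)
        if (grepl("empty after sanitization", msg, fixed = TRUE)) {
          return(NA_character_)
        }
        stop(sprintf("record '%s': %s", ids[i], msg), call. = FALSE)
      }
    )
    if (is.na(res)) {
      n_dropped <- n_dropped + 1L
      n_removed <- n_removed + nchar(gsub("[[:space:]]+", "", raw[i]))
    } else {
      n_removed <- n_removed +
        (nchar(gsub("[[:space:]]+", "", raw[i])) - nchar(res))
      kept_id <- c(kept_id, ids[i])
      kept_seq <- c(kept_seq, res)
    }
  }
  if (length(kept_id) == 0L) {
    stop("corpus empty after sanitization: ", path, call. = FALSE)
  }
  corpus <- protein_corpus(kept_id, kept_seq, label = label)
  attr(corpus, "sanitization_report") <- list(
    n_records = length(raw),
    n_kept = length(kept_id),
    n_dropped_empty = n_dropped,
    n_residues_removed = n_removed
  )
  corpus
}

#' Write a corpus to FASTA
#'
#' @param corpus A `protein_corpus`.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(corpus, path, width = 60L) {
  set <- Biostrings::AAStringSet(corpus$seq)
  names(set) <- corpus$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

format_score <- function(x) {
  ifelse(is.nan(x), "NaN", sprintf("%.6g", x))
}

#' Write a classification report as TSV
#'
#' Writes one row per decision with columns `id`, `length`, `loglik_human`,
#' `loglik_nonhuman`, `log_odds`, `log_odds_per_pos`, `label`, sorted by
#' descending log-odds with ties broken by id. Scores are printed with 6
#' significant digits; unscoreable sequences print `NaN` and sort last.
#'
#' @param decisions A decision data frame as returned by [classify_corpus()]
#'   (the `decisions` element) or by [score_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(decisions, path) {
  if (inherits(decisions, "classification")) decisions <- decisions$decisions
  if (!is.data.frame(decisions) || nrow(decisions) == 0L) {
    stop("`decisions` must be a non-empty decision data frame", call. = FALSE)
  }
  need <- c("id", "length", "loglik_human", "loglik_nonhuman",
            "log_odds", "log_odds_per_pos", "label")
  missing_cols <- setdiff(need, names(decisions))
  if (length(missing_cols) > 0L) {
    stop("decision table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  o <- order(-decisions$log_odds, decisions$id, na.last = TRUE)
  d <- decisions[o, , drop = FALSE]
  lines <- c(
    paste(need, collapse = "\t"),
    paste(d$id, d$length,
          format_score(d$loglik_human), format_score(d$loglik_nonhuman),
          format_score(d$log_odds), format_score(d$log_odds_per_pos),
          d$label, sep = "\t")
  )
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write report to '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}
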