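#' Construct a protein corpus
#'
#' A corpus is an ordered, labeled collection of protein sequences: a vector
#' of unique identifiers and a parallel vector of residue strings. It is the
#' unit consumed by every model-building and classification function.
#'
#' @param ids Character vector of sequence identifiers (unique, non-empty).
#' @param seqs Character vector of residue strings, same length as `ids`.
#'   Each must be non-empty; residues are not re-sanitized here (see
#'   [sanitize_residues()]).
#' @param label Single string naming the corpus (e.g. `"human"`,
#'   `"non-human"`, `"query"`).
#' @return An object of class `protein_corpus`: a list with elements `label`,
#'   `id`, `seq`.
#' @export
#' @examples
#' protein_corpus(c("s1", "s2"), c("ACDE", "WYV"), label = "demo")
protein_corpus <- function(ids, seqs, label = "corpus") {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs)) {
    stop("`ids` and `seqs` must have the same length", call. = FALSE)
  }
  if (length(ids) == 0L) {
    stop("a corpus must contain at least one sequence", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequences in corpus: ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  structure(
    list(label = as.character(label)[1], id = ids, seq = seqs),
    class = "protein_corpus"
  )
}

#' @export
length.protein_corpus <- function(x) length(x$id)

#' @export
print.protein_corpus <- function(x, ...) {
  cat(sprintf("protein_corpus '%s': %d sequences, lengths %d-%d\n",
              x$label, length(x$id),
              min(nchar(x$seq)), max(nchar(x$seq))))
  invisible(x)
}

#' @export
as.data.frame.protein_corpus <- function(x, ...) {
  data.frame(id = x$id, seq = x$seq, length = nchar(x$seq),
             stringsAsFactors = FALSE)
}

#' Subset a corpus by position or id
#'
#' @param x A `protein_corpus`.
#' @param i Integer or logical index, or character vector of ids.
#' @param ... Unused.
#' @return A `protein_corpus` with the selected sequences, order preserved.
#' @export
`[.protein_corpus` <- function(x, i, ...) {
  if (is.character(i)) {
    i <- match(i, x$id)
    if (anyNA(i)) stop("unknown sequence ids in subset", call. = FALSE)
  }
  protein_corpus(x$id[i], x$seq[i], label = x$label)
}

sequence_lengths <- function(corpus) nchar(corpus$seq)
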