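identity_submatrix <- function(letters) {
  m <- diag(1, length(letters))
  dimnames(m) <- list(letters, letters)
  m
}

#' Pairwise sequence identity
#'
#' Fraction of identical aligned positions in the optimal global alignment
#' under match = 1, mismatch = 0, gap = 0 scoring (so the aligner maximizes
#' the number of identities), normalized by the length of the shorter
#' sequence — the convention used by CD-HIT-style redundancy filters. The
#' measure is symmetric and equals 1 for identical sequences.
#'
#' @param a,b Non-empty residue strings (or single-sequence
#'   `protein_corpus` objects).
#' @return Identity fraction in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("ACDEFG", "ACDEFH")  # 5/6
pairwise_identity <- function(a, b) {
  if (inherits(a, "protein_corpus")) a <- a$seq[1]
  if (inherits(b, "protein_corpus")) b <- b$seq[1]
  if (!nzchar(a) || !nzchar(b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  letters <- sort(unique(strsplit(paste0(a, b), "")[[1]]))
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b,
    substitutionMatrix = identity_submatrix(letters),
    gapOpening = 0, gapExtension = 0, type = "global"
  )
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

kmer_set <- function(s, k) unique(sliding_windows(s, k))

kmer_containment <- function(ka, kb) {
  if (length(ka) == 0L || length(kb) == 0L) return(1)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Greedy identity-threshold clustering of a corpus
#'
#' De-duplicates a corpus CD-HIT style: sequences are visited in order of
#' decreasing length (ties by id); each sequence joins the first existing
#' representative with [pairwise_identity()] at or above `threshold`, and
#' otherwise founds a new cluster. Representatives are therefore mutually
#' below the identity threshold, and the procedure is deterministic.
#'
#' For corpora larger than `prefilter_size`, a k-mer containment prefilter
#' skips the alignment for candidate pairs sharing fewer than
#' `prefilter_min_share` of their k-mers. The prefilter can only skip a
#' merge, never force one, so representatives always satisfy the identity
#' contract.
#'
#' @param corpus A non-empty `protein_corpus`.
#' @param threshold Identity threshold in (0, 1]; the redundancy stage of
#'   the training pipeline uses 0.9.
#' @param prefilter_size Corpus size above which the k-mer prefilter is
#'   enabled (default 5000).
#' @param prefilter_k k-mer length for the prefilter (default 5).
#' @param prefilter_min_share Minimum shared k-mer fraction below which the
#'   alignment is skipped (default 0.1).
#' @return An object of class `cluster_result`: list with `representatives`
#'   (a `protein_corpus`), `assignments` (data frame `id`,
#'   `representative`, one row per input sequence), and `threshold`.
#' @export
greedy_cluster <- function(corpus, threshold,
                           prefilter_size = 5000L,
                           prefilter_k = 5L,
                           prefilter_min_share = 0.1) {
  if (!inherits(corpus, "protein_corpus") || length(corpus) == 0L) {
    stop("`corpus` must be a non-empty protein_corpus", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  use_prefilter <- length(corpus) > prefilter_size
  o <- order(-nchar(corpus$seq), corpus$id)
  ids <- corpus$id[o]
  seqs <- corpus$seq[o]
  rep_idx <- integer(0)          # indices (into ids/seqs) of representatives
  rep_kmers <- list()
  assigned <- character(length(ids))
  for (i in seq_along(ids)) {
    km <- if (use_prefilter) kmer_set(seqs[i], prefilter_k) else NULL
    hit <- NA_integer_
    for (j in seq_along(rep_idx)) {
      if (use_prefilter &&
          kmer_containment(km, rep_kmers[[j]]) < prefilter_min_share) {
        next
      }
      if (pairwise_identity(seqs[i], seqs[rep_idx[j]]) >= threshold) {
        hit <- j
        break
      }
    }
    if (is.na(hit)) {
      rep_idx <- c(rep_idx, i)
      if (use_prefilter) rep_kmers[[length(rep_idx)]] <- km
      assigned[i] <- ids[i]
    } else {
      assigned[i] <- ids[rep_idx[hit]]
    }
  }
  reps <- protein_corpus(ids[rep_idx], seqs[rep_idx], label = corpus$label)
  # report assignments in the original corpus order
  m <- match(corpus$id, ids)
  structure(
    list(representatives = reps,
         assignments = data.frame(id = corpus$id,
                                  representative = assigned[m],
                                  stringsAsFactors = FALSE),
         threshold = threshold),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "cluster_result: %d sequences -> %d representatives at identity >= %g\n",
    nrow(x$assignments), length(x$representatives), x$threshold))
  invisible(x)
}
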