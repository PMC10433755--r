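as_dna <- function(sequences) {
  if (is(sequences, "DNAStringSet")) return(sequences)
  Biostrings::DNAStringSet(toupper(as.character(sequences)))
}

all_kmer_names <- function(k_min, k_max) {
  unlist(lapply(k_min:k_max, function(k) {
    # lexicographic enumeration of all 4^k ACGT words
    names(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString("ACGT"), width = k))
  }), use.names = FALSE)
}

#' Overlapping k-mer count matrix
#'
#' Counts every occurrence (overlapping, forward strand only; reverse
#' complements are not collapsed) of all 4^k DNA words for each k in
#' `k_min:k_max`. Windows containing a non-ACGT character are skipped.
#' Counting runs in compiled code straight into sparse triplets.
#'
#' @param sequences character vector or `DNAStringSet`.
#' @param k_min,k_max word-length range (defaults 6 and 8).
#' @return sparse `dgCMatrix`, rows = sequences, columns = k-mers ordered
#'   by k then lexicographically; column names are the words.
#' @export
kmer_count_matrix <- function(sequences, k_min = 6, k_max = 8) {
  if (k_min > k_max) stop("k_min must be <= k_max")
  if (k_min < 1) stop("k_min must be >= 1")
  if (k_max > 15) stop("k_max above 15 is not supported")
  x <- if (is(sequences, "DNAStringSet")) as.character(sequences) else
    as.character(sequences)
  if (length(x) == 0) stop("no sequences")
  tr <- kmer_count_triplets(x, as.integer(k_min), as.integer(k_max))
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(length(x), tr$ncol),
                       dimnames = list(names(sequences),
                                       all_kmer_names(k_min, k_max)))
}

#' Build a k-mer vocabulary from training sequences
#'
#' The vocabulary contains exactly the k-mers (k in `k_min:k_max`, ACGT
#' alphabet) observed at least once in the training sequences, in
#' deterministic lexicographic order. Words seen only at prediction time
#' are thereby ignored, mirroring a fit-then-transform text vectorizer.
#'
#' @param sequences training sequences (character or `DNAStringSet`).
#' @param k_min,k_max word-length range.
#' @return object of class `kmer_vocabulary` with fields `kmers`, `k_min`,
#'   `k_max`.
#' @export
build_vocabulary <- function(sequences, k_min = 6, k_max = 8) {
  counts <- kmer_count_matrix(sequences, k_min, k_max)
  seen <- colnames(counts)[Matrix::colSums(counts) > 0]
  structure(list(kmers = sort(seen, method = "radix"),
                 k_min = as.integer(k_min), k_max = as.integer(k_max)),
            class = "kmer_vocabulary")
}

#' @export
print.kmer_vocabulary <- function(x, ...) {
  cat("k-mer vocabulary:", length(x$kmers), "words, k =",
      x$k_min, "to", x$k_max, "\n")
  invisible(x)
}

#' Featurize sequences against a fixed vocabulary
#'
#' @param sequences character or `DNAStringSet`.
#' @param vocab a [build_vocabulary()] result.
#' @return sparse count matrix with one column per vocabulary word;
#'   out-of-vocabulary words contribute nothing.
#' @export
count_features <- function(sequences, vocab) {
  stopifnot(inherits(vocab, "kmer_vocabulary"))
  full <- kmer_count_matrix(sequences, vocab$k_min, vocab$k_max)
  full[, match(vocab$kmers, colnames(full)), drop = FALSE]
}
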