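# Independent brute-force oracles the fast implementations are checked
# against. All deliberately naive: per-base bitmaps, sliding windows,
# exhaustive enumeration.

# Per-base boolean bitmap of a GRanges over a genome table (list of
# logical vectors, one per chromosome).
oracle_bitmap <- function(gr, genome) {
  maps <- lapply(genome, function(L) logical(L))
  ch <- as.character(GenomicRanges::seqnames(gr))
  for (i in seq_along(gr)) {
    s <- GenomicRanges::start(gr)[i]
    e <- GenomicRanges::end(gr)[i]
    maps[[ch[i]]][s:e] <- TRUE
  }
  maps
}

bitmap_total <- function(maps) sum(vapply(maps, sum, numeric(1)))

bitmap_op <- function(a, b, op) mapply(op, a, b, SIMPLIFY = FALSE)

# Random interval set on a genome table.
random_granges <- function(n, genome, max_width = 500) {
  ch <- sample(names(genome), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i) {
    sample.int(genome[[ch[i]]] - w[i] + 1, 1)
  }, integer(1))
  GenomicRanges::GRanges(ch, IRanges::IRanges(s, width = w))
}

# Sliding-window k-mer census of one sequence: named counts of every
# ACGT-only window of each length in k_min:k_max.
oracle_kmer_counts <- function(seq, k_min, k_max) {
  seq <- toupper(seq)
  out <- new.env(parent = emptyenv())
  n <- nchar(seq)
  for (k in k_min:k_max) {
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (grepl("^[ACGT]+$", w)) {
        out[[w]] <- (if (is.null(out[[w]])) 0 else out[[w]]) + 1
      }
    }
  }
  as.list(out)
}

# Pairwise-comparison ROC AUC.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Exact two-sided binomial p-value by full outcome enumeration
# (minimum-likelihood method).
oracle_binomial <- function(k, n, p0) {
  probs <- stats::dbinom(0:n, n, p0)
  min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
}

# Exact two-sided Mann-Whitney p-value by enumerating all assignments of
# ranks to the x-sample (no ties assumed).
oracle_mann_whitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  r_all <- seq_len(nx + ny)
  u_null <- apply(combs, 2, function(idx) sum(r_all[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(u_null - mu) >= abs(u_obs - mu) - 1e-9)
}
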