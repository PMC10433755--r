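#' Apply an enhancer model to another assay's peaks
#'
#' Extracts summit-centered windows at the model's training width from the
#' target assay's peaks, scores them with the ensemble, and flags peaks
#' with probability above 0.5 as predicted enhancers. Windows falling off a
#' chromosome end are dropped and excluded from the denominator.
#'
#' @param model a [fit_kmer_ensemble()] model.
#' @param peaks `GRanges` of target-assay peaks (with `summit`).
#' @param sequences `DNAStringSet` genome.
#' @param width window width; must equal the model's training width
#'   (default: the model's width).
#' @param threshold probability cutoff for the binary call (default 0.5).
#' @return tibble, one row per retained peak: `id`, `chrom`, `peak_start0`,
#'   `peak_end0`, `window_start0`, `window_end0`, `probability`,
#'   `predicted`.
#' @export
apply_model <- function(model, peaks, sequences, width = NULL,
                        threshold = 0.5) {
  stopifnot(inherits(model, "kmer_ensemble"))
  width <- as.integer(width %||% model$width)
  if (width != model$width) {
    stop("window width ", width, " does not match the model's training width ",
         model$width)
  }
  win <- extract_windows(peaks, sequences, width = width)
  dropped <- attr(win, "dropped")
  keep <- setdiff(seq_along(peaks), dropped)
  prob <- predict_probability(model, win$sequence)
  tibble::tibble(
    id = win$id, chrom = win$chrom,
    peak_start0 = GenomicRanges::start(peaks)[keep] - 1L,
    peak_end0 = GenomicRanges::end(peaks)[keep],
    window_start0 = win$start0, window_end0 = win$end0,
    probability = prob, predicted = prob > threshold)
}

#' Prediction-by-overlap breakdown against a reference peak set
#'
#' Cross-tabulates the model's enhancer calls with whether each peak is
#' overlapped (>= 1 bp of its full called interval) by a reference peak
#' set, yielding the predicted-enhancer fraction and the four quadrant
#' percentages. The quadrants sum to 100% and the two positive quadrants
#' sum to the predicted fraction before rounding.
#'
#' @param predictions tibble from [apply_model()].
#' @param reference `GRanges` reference peak set.
#' @param on_window cross-tabulate on the extraction window instead of the
#'   full peak interval (default `FALSE`).
#' @return object of class `cross_assay_report`: list with `n_peaks`,
#'   `predicted_fraction` (percent), `quadrants` (named percents),
#'   `counts`, and `per_peak` (the input tibble plus `overlap`).
#' @export
overlap_breakdown <- function(predictions, reference, on_window = FALSE) {
  iv <- if (on_window) {
    GenomicRanges::GRanges(predictions$chrom,
                           IRanges::IRanges(predictions$window_start0 + 1,
                                            predictions$window_end0))
  } else {
    GenomicRanges::GRanges(predictions$chrom,
                           IRanges::IRanges(predictions$peak_start0 + 1,
                                            predictions$peak_end0))
  }
  ovl <- if (length(reference)) overlaps_any(iv, reference) else
    rep(FALSE, nrow(predictions))
  per_peak <- predictions
  per_peak$overlap <- ovl
  n <- nrow(per_peak)
  counts <- c(pos_ovl = sum(per_peak$predicted & ovl),
              pos_noovl = sum(per_peak$predicted & !ovl),
              neg_ovl = sum(!per_peak$predicted & ovl),
              neg_noovl = sum(!per_peak$predicted & !ovl))
  structure(list(n_peaks = n,
                 predicted_fraction = 100 * sum(per_peak$predicted) / n,
                 quadrants = 100 * counts / n,
                 counts = counts,
                 per_peak = per_peak),
            class = "cross_assay_report")
}

#' @export
print.cross_assay_report <- function(x, ...) {
  cat("cross-assay report:", x$n_peaks, "peaks, ",
      sprintf("%.1f%%", x$predicted_fraction), "predicted enhancers\n")
  print(round(x$quadrants, 1))
  invisible(x)
}

#' Compare luciferase-active counts with model predictions
#'
#' Exact two-sided binomial test of `k_active` active fragments out of
#' `n_tested` against the model's predicted-enhancer fraction as the null
#' probability: are reporter-assay hit rates consistent with what the
#' sequence model predicts for that assay's peaks?
#'
#' @param k_active fragments called active by [luciferase_analysis()].
#' @param n_tested fragments tested.
#' @param predicted_fraction model predicted-enhancer fraction as a ratio
#'   in (0, 1).
#' @return two-sided binomial p-value.
#' @export
#' @examples
#' compare_to_luciferase(5, 18, 0.354)
compare_to_luciferase <- function(k_active, n_tested, predicted_fraction) {
  if (predicted_fraction <= 0 || predicted_fraction >= 1) {
    stop("predicted_fraction must be strictly between 0 and 1")
  }
  binomial_test(k_active, n_tested, predicted_fraction)
}

#' Published peak-set characteristics for eight fly assay datasets
#'
#' Peak counts, width mean +/- sd, genome coverage and model ROC AUC for
#' eight published *D. melanogaster* functional-genomics peak sets
#' (ATAC-seq, DNase-seq, FAIRE-seq, H3K27ac/H3K4me1/H3K4me3 ChIP-seq,
#' STARR-seq, UMI-STARR-seq). Used as printed inputs to the correlation
#' analyses relating model accuracy to peak-set geometry.
#'
#' @return tibble: `dataset`, `peak_count`, `width_mean`, `width_sd`,
#'   `genome_coverage_pct`, `roc_auc_pct`.
#' @export
published_peak_stats <- function() {
  tibble::tibble(
    dataset = c("ATAC-seq", "DNase-seq", "FAIRE-seq", "H3K27ac",
                "H3K4me1", "H3K4me3", "STARR-seq", "UMI-STARR-seq"),
    peak_count = c(30956, 8314, 16387, 11272, 14922, 16098, 2926, 13548),
    width_mean = c(199, 343, 185, 722, 1044, 968, 988, 325),
    width_sd = c(156, 305, 127, 519, 717, 609, 490, 157),
    genome_coverage_pct = c(4.3, 2.0, 2.2, 7.5, 11.7, 7.6, 2.0, 3.1),
    roc_auc_pct = c(83.2, 90.4, 86.2, 80.5, 77.8, 82.2, 90.4, 88.3)
  )
}

#' Published cross-assay prediction/overlap table
#'
#' Predicted-enhancer fractions and prediction-by-overlap quadrant
#' percentages for a published STARR-seq enhancer model applied to six
#' other fly assay peak sets (overlap taken against UMI-STARR-seq peaks).
#' Useful for checking the structural identities every such report obeys.
#'
#' @return tibble with `dataset`, `predicted_pct` and the four quadrant
#'   percentage columns.
#' @export
published_crossassay_table <- function() {
  tibble::tibble(
    dataset = c("ATAC-seq", "DNase-seq", "FAIRE-seq", "H3K27ac",
                "H3K4me1", "H3K4me3"),
    predicted_pct = c(39.3, 60.1, 40.6, 26.9, 35.4, 26.5),
    pos_ovl = c(15.3, 42.6, 18.9, 10.8, 12.2, 9.8),
    pos_noovl = c(24.0, 17.5, 21.7, 16.2, 23.3, 17.0),
    neg_ovl = c(12.7, 19.0, 16.3, 12.9, 5.9, 10.8),
    neg_noovl = c(47.9, 20.8, 43.0, 60.1, 58.6, 62.4)
  )
}
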