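#' Summarize a peak set
#'
#' Peak count, width mean and sample standard deviation, and merged genome
#' coverage fraction -- the descriptive statistics usually tabulated when
#' comparing peak sets across assays.
#'
#' @param peaks `GRanges` of peaks.
#' @param genome [genome_table()].
#' @param name dataset label.
#' @return one-row tibble: `dataset`, `peak_count`, `width_mean`,
#'   `width_sd`, `genome_coverage`.
#' @export
summarize_peaks <- function(peaks, genome, name = "peaks") {
  if (length(peaks) == 0) stop("empty peak set")
  genome <- genome_table(genome)
  w <- GenomicRanges::width(peaks)
  tibble::tibble(
    dataset = name,
    peak_count = length(peaks),
    width_mean = mean(w),
    width_sd = if (length(w) > 1) stats::sd(w) else 0,
    genome_coverage = total_length(peaks) / sum(as.numeric(genome))
  )
}

#' Normalized peak coverage of annotated element classes
#'
#' For each genomic element class (exon, intron, TSS, intergenic, whole
#' genome) computes the summed intersection length with the peaks divided
#' by the summed element length. Intergenic space is derived by subtracting
#' exon, intron and TSS regions from the chromosomes. Element classes may
#' overlap each other; each fraction is computed independently.
#'
#' @param peaks `GRanges` of peaks (may be empty: all fractions are 0).
#' @param annotation list with `exon`, `intron`, `tss` `GRanges` (e.g. from
#'   [simulate_annotation()]).
#' @param genome [genome_table()].
#' @return tibble with columns `element` and `fraction`.
#' @export
element_coverage <- function(peaks, annotation, genome) {
  genome <- genome_table(genome)
  need <- c("exon", "intron", "tss")
  if (!all(need %in% names(annotation))) {
    stop("annotation must provide exon, intron and tss sets")
  }
  whole <- genome_granges(genome)
  annotated <- c(GenomicRanges::granges(annotation$exon),
                 GenomicRanges::granges(annotation$intron),
                 GenomicRanges::granges(annotation$tss))
  classes <- list(
    genome = whole,
    exon = annotation$exon,
    intron = annotation$intron,
    tss = annotation$tss,
    intergenic = subtract_intervals(whole, annotated)
  )
  frac <- vapply(names(classes), function(cl) {
    el <- classes[[cl]]
    if (total_length(el) == 0) {
      stop("element class '", cl, "' has zero total length")
    }
    if (length(peaks) == 0) return(0)
    coverage_fraction(peaks, el)
  }, numeric(1))
  tibble::tibble(element = names(classes), fraction = unname(frac))
}
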