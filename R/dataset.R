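#' Extract summit-centered sequence windows
#'
#' For each peak, extracts the fixed-width window
#' `[summit - floor(width/2), summit - floor(width/2) + width)` from the
#' genome (0-based half-open coordinates; the default 501 bp window spans
#' summit +/- 250). Windows extending past a chromosome end are dropped,
#' not clipped, so every retained sequence has identical length. Sequences
#' are uppercased; soft-masked bases therefore count like any other.
#'
#' @param peaks `GRanges` with a `summit` metadata column (absolute,
#'   1-based; [read_narrowpeak()] provides it).
#' @param sequences `DNAStringSet` genome named by chromosome.
#' @param width window width in bp (default 501, summit-centered).
#' @return tibble: `id`, `chrom`, `start0`, `end0`, `summit`, `sequence`,
#'   plus attribute `dropped` holding the indices of off-edge peaks.
#' @export
extract_windows <- function(peaks, sequences, width = 501) {
  if (length(peaks) == 0) stop("empty peak set")
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  missing_chr <- setdiff(unique(chrom), names(sequences))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from FASTA: ", paste(missing_chr, collapse = ", "))
  }
  mc <- S4Vectors::mcols(peaks)
  summit <- if ("summit" %in% names(mc)) mc$summit else
    as.integer(GenomicRanges::start(peaks) + GenomicRanges::width(peaks) %/% 2)
  half <- width %/% 2
  start1 <- summit - half
  end1 <- start1 + width - 1
  seqlen <- Biostrings::width(sequences)[match(chrom, names(sequences))]
  keep <- start1 >= 1 & end1 <= seqlen
  dropped <- which(!keep)
  if (length(dropped)) {
    message(length(dropped), " window(s) dropped at chromosome edges")
  }
  ids <- if (!is.null(mc$name)) as.character(mc$name) else
    sprintf("peak_%d", seq_along(peaks))
  out <- tibble::tibble(id = ids[keep], chrom = chrom[keep],
                        start0 = start1[keep] - 1L, end0 = end1[keep],
                        summit = summit[keep],
                        sequence = character(sum(keep)))
  for (ch in unique(out$chrom)) {
    sel <- out$chrom == ch
    at <- IRanges::IRanges(out$start0[sel] + 1, out$end0[sel])
    out$sequence[sel] <- toupper(as.character(
      Biostrings::extractAt(sequences[[ch]], at)))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Build the labeled peak-versus-control sequence dataset
#'
#' The core training-set construction: summit-centered windows for all
#' peaks on the five chromosome arms (label 1), plus one width-matched
#' control window per retained peak (label 0) sampled by
#' [shuffle_with_exclusions()] with exclusions = coding sequence plus the
#' assay's own peaks. Controls inherit their source peak's chromosome so
#' chromosome folds stay balanced, and never overlap each other. Class
#' balance is exact by construction.
#'
#' @param peaks `GRanges` of assay peaks with `summit`.
#' @param sequences `DNAStringSet` genome.
#' @param genome [genome_table()].
#' @param cds `GRanges` of coding sequence to exclude (may be empty).
#' @param width window width (default 501).
#' @param seed integer seed for control sampling.
#' @param arms chromosomes retained (default 2L, 2R, 3L, 3R, X).
#' @return tibble: `id`, `chrom`, `start0`, `end0`, `label` (1 peak /
#'   0 control), `fold` (= chromosome), `sequence`.
#' @export
build_dataset <- function(peaks, sequences, genome, cds = NULL,
                          width = 501, seed = 1L, arms = FLY_ARMS) {
  genome <- genome_table(genome)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  off_arm <- !(chrom %in% arms)
  if (all(off_arm)) stop("no peaks on the retained chromosome arms")
  if (any(off_arm)) {
    message(sum(off_arm), " peak(s) outside arms ",
            paste(arms, collapse = "/"), " discarded")
    peaks <- peaks[!off_arm]
  }
  pos <- extract_windows(peaks, sequences, width = width)
  # Controls are sampled at the window width so that the negative class is
  # width-matched to what the model actually sees.
  src <- GenomicRanges::GRanges(pos$chrom, IRanges::IRanges(1, width = width))
  exclusions <- GenomicRanges::granges(peaks)
  if (!is.null(cds) && length(cds)) {
    exclusions <- c(exclusions, GenomicRanges::granges(cds))
  }
  ctrl <- shuffle_with_exclusions(src, genome[arms[arms %in% names(genome)]],
                                  exclusions = exclusions,
                                  same_chrom = TRUE,
                                  forbid_mutual_overlap = TRUE,
                                  seed = seed)
  S4Vectors::mcols(ctrl)$summit <- as.integer(GenomicRanges::start(ctrl) +
                                                width %/% 2)
  S4Vectors::mcols(ctrl)$name <- sprintf("control_%d", seq_along(ctrl))
  neg <- extract_windows(ctrl, sequences, width = width)
  if (nrow(neg) != nrow(pos)) {
    stop("control extraction lost windows; dataset would be unbalanced")
  }
  out <- rbind(
    tibble::tibble(id = pos$id, chrom = pos$chrom, start0 = pos$start0,
                   end0 = pos$end0, label = 1L, sequence = pos$sequence),
    tibble::tibble(id = neg$id, chrom = neg$chrom, start0 = neg$start0,
                   end0 = neg$end0, label = 0L, sequence = neg$sequence)
  )
  out$fold <- out$chrom
  attr(out, "width") <- as.integer(width)
  out[, c("id", "chrom", "start0", "end0", "label", "fold", "sequence")]
}

#' Chromosome-arm fold partition
#'
#' Assigns every sequence to the fold named after its chromosome arm. The
#' training set for a fold is everything *not* on that arm, so no training
#' sequence ever shares a chromosome with a test sequence.
#'
#' @param dataset tibble from [build_dataset()] (needs `chrom`).
#' @param arms fold names (default the five large arms).
#' @return factor of fold labels, one per row of `dataset`.
#' @export
partition_folds <- function(dataset, arms = FLY_ARMS) {
  unknown <- setdiff(unique(dataset$chrom), arms)
  if (length(unknown)) {
    stop("unknown chromosome(s) for fold assignment: ",
         paste(unknown, collapse = ", "))
  }
  factor(dataset$chrom, levels = arms)
}

#' Serialize a dataset as FASTA plus manifest
#'
#' @param dataset tibble from [build_dataset()].
#' @param prefix output path prefix; writes `<prefix>.fa` and
#'   `<prefix>.tsv`.
#' @return named character vector of the two paths, invisibly.
#' @export
write_dataset <- function(dataset, prefix) {
  fold <- partition_folds(dataset)
  ids <- sprintf("%s:%s:%d-%d:%d", dataset$id, dataset$chrom,
                 dataset$start0, dataset$end0, dataset$label)
  seqs <- Biostrings::DNAStringSet(dataset$sequence)
  names(seqs) <- ids
  fa <- paste0(prefix, ".fa"); tsv <- paste0(prefix, ".tsv")
  Biostrings::writeXStringSet(seqs, fa, width = 60)
  utils::write.table(
    data.frame(id = dataset$id, chrom = dataset$chrom,
               start = dataset$start0, end = dataset$end0,
               label = dataset$label, fold = as.character(fold)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, manifest = tsv))
}
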