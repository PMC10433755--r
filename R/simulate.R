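#' Position weight matrix motif model
#'
#' @param name motif name.
#' @param pwm numeric matrix, rows = positions, columns = A, C, G, T; each
#'   row must sum to 1.
#' @return a `motif_model` object.
#' @export
motif_model <- function(name, pwm) {
  pwm <- as.matrix(pwm)
  colnames(pwm) <- c("A", "C", "G", "T")
  if (nrow(pwm) < 4) stop("motif width must be >= 4")
  if (any(abs(rowSums(pwm) - 1) > 1e-9) || any(pwm < 0)) {
    stop("each PWM row must be a probability distribution")
  }
  structure(list(name = name, pwm = pwm), class = "motif_model")
}

# Build a mostly-deterministic PWM from a consensus string.
consensus_pwm <- function(name, consensus, strength = 0.94) {
  bases <- c("A", "C", "G", "T")
  letters <- strsplit(consensus, "")[[1]]
  pwm <- t(vapply(letters, function(b) {
    p <- rep((1 - strength) / 3, 4)
    p[match(b, bases)] <- strength
    p
  }, numeric(4)))
  motif_model(name, pwm)
}

#' Default planted-motif set
#'
#' Three transcription-factor-like motifs (GATA-, AP-1- and GAGA-like
#' consensus) used by the simulator to endow peaks with learnable sequence
#' signal. They stand in for the binding-site content that makes real
#' regulatory peaks predictable from sequence alone.
#'
#' @param strength per-position probability of the consensus base.
#' @return list of [motif_model()] objects.
#' @export
default_motifs <- function(strength = 0.94) {
  list(
    consensus_pwm("gata_like", "TTATCTTATC", strength),
    consensus_pwm("ap1_like", "TTGACTCAT", strength),
    consensus_pwm("gaga_like", "GAGAGAGAGA", strength)
  )
}

sample_motif_instance <- function(motif) {
  bases <- c("A", "C", "G", "T")
  paste(apply(motif$pwm, 1, function(p) sample(bases, 1, prob = p)),
        collapse = "")
}

#' Simulate a five-arm genome
#'
#' Generates i.i.d. bases at the requested GC content for the chromosome
#' arms used by the fold scheme (2L, 2R, 3L, 3R, X by default).
#'
#' @param arm_lengths named vector of arm lengths in bp (default five arms
#'   of 200 kb).
#' @param gc_content genome GC fraction in (0, 1). Default 0.42, close to
#'   the *D. melanogaster* euchromatin.
#' @param seed integer seed; the genome is deterministic given the seed.
#' @return list with `sequences` (`DNAStringSet`) and `genome`
#'   ([genome_table()]).
#' @export
simulate_genome <- function(arm_lengths = stats::setNames(rep(2e5, 5), FLY_ARMS),
                            gc_content = 0.42, seed = 1L) {
  genome <- genome_table(arm_lengths)
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  if (any(genome < 10000)) stop("arm lengths must be >= 10 kb")
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  seqs <- with_seed(seed, {
    lapply(seq_along(genome), function(i) {
      paste(sample(c("A", "C", "G", "T"), genome[[i]], replace = TRUE,
                   prob = p), collapse = "")
    })
  })
  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  names(sequences) <- names(genome)
  list(sequences = sequences, genome = genome)
}

#' Write genome sequences as FASTA
#'
#' @param sequences `DNAStringSet`.
#' @param path output path (uncompressed, 60-column lines).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, path, width = 60)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA path.
#' @return `DNAStringSet` named by chromosome.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

# Place `widths` non-overlapping intervals on `chroms` (or anywhere),
# avoiding `exclusions`, by rejection sampling. Shared engine behind
# annotation, peak planting and control shuffling. Returns GRanges.
place_intervals <- function(widths, genome, chroms = NULL,
                            exclusions = NULL, margin = 0,
                            max_tries = 10000L, seed = 1L) {
  src <- if (is.null(chroms)) {
    GenomicRanges::GRanges(
      sample_chroms_by_room(widths, genome, seed = derive_seed(seed, 7L)),
      IRanges::IRanges(1, width = widths))
  } else {
    GenomicRanges::GRanges(chroms, IRanges::IRanges(1, width = widths))
  }
  ex <- if (is.null(exclusions)) NULL else GenomicRanges::granges(exclusions)
  if (margin > 0) {
    edges <- GenomicRanges::GRanges(
      rep(names(genome), each = 2),
      IRanges::IRanges(start = as.vector(rbind(1, unname(genome) - margin + 1)),
                       end = as.vector(rbind(margin, unname(genome)))))
    ex <- if (is.null(ex)) edges else
      suppressWarnings(c(ex, edges))
  }
  shuffle_with_exclusions(src, genome, exclusions = ex,
                          same_chrom = TRUE, forbid_mutual_overlap = TRUE,
                          max_tries = max_tries, seed = seed)
}

sample_chroms_by_room <- function(widths, genome, seed) {
  with_seed(seed, {
    vapply(widths, function(w) {
      room <- pmax(genome - w + 1, 0)
      sample(names(genome), 1, prob = room / sum(room))
    }, "")
  })
}

#' Simulate a gene annotation
#'
#' Places non-overlapping gene bodies, splits each into exons and introns,
#' and derives strand-aware transcription start site (TSS) regions as the
#' 500 bp immediately upstream of the coding start, clipped at the arm
#' boundary. Coding sequence (CDS) is the exon set of each gene.
#'
#' @param genome [genome_table()].
#' @param gene_count number of genes.
#' @param seed integer seed.
#' @param gene_length_range min/max gene body length (bp).
#' @param max_exons maximum exons per gene (>= 1 each).
#' @param tss_width upstream extent defining the TSS region (default 500).
#' @return list of `GRanges`: `genes`, `cds`, `exon`, `intron`, `tss`.
#' @export
simulate_annotation <- function(genome, gene_count = 50, seed = 1L,
                                gene_length_range = c(2000, 6000),
                                max_exons = 4, tss_width = 500) {
  genome <- genome_table(genome)
  widths <- with_seed(derive_seed(seed, 1L), {
    round(stats::runif(gene_count, gene_length_range[1], gene_length_range[2]))
  })
  bodies <- place_intervals(widths, genome,
                            margin = tss_width + 10,
                            seed = derive_seed(seed, 2L))
  strand <- with_seed(derive_seed(seed, 3L), {
    sample(c("+", "-"), gene_count, replace = TRUE)
  })
  GenomicRanges::strand(bodies) <- strand
  exon_list <- list(); intron_list <- list()
  with_seed(derive_seed(seed, 4L), {
    for (g in seq_along(bodies)) {
      gs <- GenomicRanges::start(bodies)[g]
      ge <- GenomicRanges::end(bodies)[g]
      w <- ge - gs + 1
      k <- sample(seq_len(max_exons), 1)
      nseg <- 2 * k - 1
      if (w < nseg * 120) k <- 1
      if (k == 1) {
        exon_list[[g]] <- GenomicRanges::GRanges(
          GenomicRanges::seqnames(bodies)[g], IRanges::IRanges(gs, ge),
          strand = strand[g])
        next
      }
      nseg <- 2 * k - 1
      prop <- stats::rexp(nseg) + 0.2
      seg <- floor(w * prop / sum(prop))
      seg[nseg] <- w - sum(seg[-nseg])
      bounds <- gs + cumsum(c(0, seg))
      iv <- IRanges::IRanges(bounds[-length(bounds)], bounds[-1] - 1)
      ch <- GenomicRanges::seqnames(bodies)[g]
      exon_list[[g]] <- GenomicRanges::GRanges(ch, iv[seq(1, nseg, 2)],
                                               strand = strand[g])
      intron_list[[g]] <- GenomicRanges::GRanges(ch, iv[seq(2, nseg, 2)],
                                                 strand = strand[g])
    }
  })
  exons <- do.call(c, exon_list)
  introns <- if (length(intron_list)) {
    do.call(c, intron_list[!vapply(intron_list, is.null, TRUE)])
  } else GenomicRanges::GRanges()
  # TSS: 500 bp upstream of CDS start, strand-aware, clipped at arm bounds.
  tss_start <- ifelse(strand == "+",
                      pmax(GenomicRanges::start(bodies) - tss_width, 1),
                      GenomicRanges::end(bodies) + 1)
  tss_end <- ifelse(strand == "+",
                    GenomicRanges::start(bodies) - 1,
                    pmin(GenomicRanges::end(bodies) + tss_width,
                         genome[as.character(GenomicRanges::seqnames(bodies))]))
  keep <- tss_end >= tss_start
  tss <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(bodies))[keep],
    IRanges::IRanges(tss_start[keep], tss_end[keep]),
    strand = strand[keep])
  si <- genome_seqinfo(genome)
  for (nm in c("bodies", "exons", "introns", "tss")) {
    x <- get(nm)
    GenomeInfoDb::seqlevels(x) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(x) <- si
    assign(nm, x)
  }
  list(genes = bodies, cds = exons, exon = exons, intron = introns, tss = tss)
}

#' Assay simulation settings
#'
#' Bundles the knobs controlling one synthetic assay-like peak set:
#' how many peaks, their width distribution, what fraction carry planted
#' motif signal, how many motif instances a signal peak receives, and where
#' those instances sit relative to the recorded summit. A positive
#' `summit_offset_bp` displaces the planted signal downstream of the summit,
#' emulating assays (e.g. histone ChIP) whose peaks flank rather than center
#' on the active sequence.
#'
#' @param name assay label.
#' @param peak_count number of peaks.
#' @param width_mean,width_sd peak width distribution (truncated normal).
#' @param signal_strength fraction of peaks carrying planted motifs.
#' @param motifs_per_peak motif instances written into each signal peak.
#' @param summit_offset_bp signed displacement of the planted-motif block
#'   from the summit.
#' @param seed integer seed.
#' @return a validated list of class `assay_sim_spec`.
#' @export
assay_sim_spec <- function(name, peak_count = 1000, width_mean = 150,
                           width_sd = 40, signal_strength = 1,
                           motifs_per_peak = 2, summit_offset_bp = 0,
                           seed = 1L) {
  if (peak_count < 1) stop("peak_count must be >= 1")
  if (signal_strength < 0 || signal_strength > 1) {
    stop("signal_strength must be in [0,1]")
  }
  structure(list(name = name, peak_count = as.integer(peak_count),
                 width_mean = width_mean, width_sd = width_sd,
                 signal_strength = signal_strength,
                 motifs_per_peak = as.integer(motifs_per_peak),
                 summit_offset_bp = as.integer(summit_offset_bp),
                 seed = as.integer(seed)),
            class = "assay_sim_spec")
}

#' Plant assay-like peaks with motif signal into a genome
#'
#' Draws peak locations (mutually non-overlapping, avoiding `exclusions`
#' and arm ends), records the summit at each peak's midpoint, and for a
#' `signal_strength` fraction of peaks overwrites the reference bases with
#' PWM-sampled motif instances centered at `summit + summit_offset_bp`.
#' Substitution only -- no indels -- so all coordinates stay stable. Every
#' planted instance is recorded in a ledger so downstream window extraction
#' can be audited exactly.
#'
#' @param sequences `DNAStringSet` genome (from [simulate_genome()]).
#' @param genome [genome_table()].
#' @param spec an [assay_sim_spec()].
#' @param motifs list of [motif_model()]; default [default_motifs()].
#' @param exclusions optional `GRanges` that peaks must avoid.
#' @return list with `sequences` (mutated genome), `peaks` (`GRanges` with
#'   `summit` and `name`), and `ledger` (tibble of planted instances:
#'   chrom, start0, end0, motif, peak).
#' @export
plant_peaks <- function(sequences, genome, spec, motifs = default_motifs(),
                        exclusions = NULL) {
  genome <- genome_table(genome)
  if (is.null(names(sequences)) ||
      length(setdiff(names(genome), names(sequences)))) {
    stop("genome sequences must be named by chromosome")
  }
  motif_w <- vapply(motifs, function(m) nrow(m$pwm), integer(1))
  spacing <- max(motif_w) + 4
  block_span <- spec$motifs_per_peak * spacing
  if (spec$width_mean <= max(motif_w)) {
    stop("width_mean must exceed the widest motif")
  }
  widths <- with_seed(derive_seed(spec$seed, 11L), {
    w <- round(stats::rnorm(spec$peak_count, spec$width_mean, spec$width_sd))
    bad <- w <= max(motif_w)
    while (any(bad)) {  # truncate the width distribution at motif width
      w[bad] <- round(stats::rnorm(sum(bad), spec$width_mean, spec$width_sd))
      bad <- w <= max(motif_w)
    }
    w
  })
  # Pad each placement footprint so that a peak's planted-motif block
  # (possibly offset beyond the called interval) can never collide with a
  # neighbouring peak's block.
  half_span <- ceiling(block_span / 2) + 1
  rel_low <- widths %/% 2 + spec$summit_offset_bp - half_span
  rel_high <- widths %/% 2 + spec$summit_offset_bp + half_span
  pad_left <- pmax(0, -rel_low)
  pad_right <- pmax(0, rel_high - (widths - 1))
  placed <- place_intervals(widths + pad_left + pad_right, genome,
                            exclusions = exclusions, margin = 300,
                            seed = derive_seed(spec$seed, 12L))
  peaks <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(placed),
    IRanges::IRanges(GenomicRanges::start(placed) + pad_left,
                     width = widths),
    seqinfo = genome_seqinfo(genome))
  summit <- as.integer(GenomicRanges::start(peaks) +
                         GenomicRanges::width(peaks) %/% 2)
  S4Vectors::mcols(peaks)$summit <- summit
  S4Vectors::mcols(peaks)$name <- sprintf("%s_peak_%d", spec$name,
                                          seq_along(peaks))
  ledger <- list()
  plant_at <- list()
  with_seed(derive_seed(spec$seed, 13L), {
    has_signal <- stats::runif(spec$peak_count) < spec$signal_strength
    for (i in which(has_signal)) {
      center <- summit[i] + spec$summit_offset_bp
      m <- spec$motifs_per_peak
      # adjacent non-overlapping blocks centered (as a group) on `center`
      block_start <- center - (m * spacing) %/% 2
      for (j in seq_len(m)) {
        motif <- motifs[[sample(length(motifs), 1)]]
        wm <- nrow(motif$pwm)
        s1 <- block_start + (j - 1) * spacing +
          (spacing - wm) %/% 2  # 1-based start
        inst <- sample_motif_instance(motif)
        ch <- as.character(GenomicRanges::seqnames(peaks))[i]
        plant_at[[length(plant_at) + 1]] <-
          list(chrom = ch, s1 = s1, e1 = s1 + wm - 1, inst = inst)
        ledger[[length(ledger) + 1]] <- tibble::tibble(
          chrom = ch, start0 = s1 - 1, end0 = s1 + wm - 1,
          motif = motif$name,
          peak = S4Vectors::mcols(peaks)$name[i])
      }
    }
  })
  if (length(plant_at)) {
    by_chrom <- split(plant_at,
                      vapply(plant_at, `[[`, "", "chrom"))
    for (ch in names(by_chrom)) {
      at <- IRanges::IRanges(
        vapply(by_chrom[[ch]], function(p) p$s1, numeric(1)),
        vapply(by_chrom[[ch]], function(p) p$e1, numeric(1)))
      vals <- vapply(by_chrom[[ch]], `[[`, "", "inst")
      sequences[[ch]] <- Biostrings::replaceAt(
        sequences[[ch]], at, Biostrings::DNAStringSet(vals))
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    tibble::tibble(chrom = character(0), start0 = integer(0),
                   end0 = integer(0), motif = character(0),
                   peak = character(0))
  list(sequences = sequences, peaks = peaks, ledger = ledger)
}

#' Simulate a dual-luciferase replicate table
#'
#' Emits per-replicate firefly and renilla luminescence for `n_fragments`
#' test fragments plus one negative-control fragment whose true relative
#' activity is 1. A fixed number `round(active_fraction * n_fragments)` of
#' fragments are truly active with expected relative activity
#' `mean_fold_activity`; replicate noise is log-normal on the
#' firefly/renilla ratio with coefficient of variation `replicate_cv`.
#'
#' @param n_fragments number of test fragments.
#' @param active_fraction fraction of fragments that are truly active.
#' @param mean_fold_activity expected relative activity of active fragments.
#' @param replicate_cv coefficient of variation of the replicate ratios.
#' @param replicates technical replicates per fragment (default 6).
#' @param seed integer seed.
#' @return list with `table` (tibble: fragment_id, replicate, firefly,
#'   renilla, is_negative_control) and `truth` (tibble: fragment_id,
#'   is_active, true_fold).
#' @export
simulate_luciferase <- function(n_fragments = 20, active_fraction = 0.45,
                                mean_fold_activity = 4, replicate_cv = 0.15,
                                replicates = 6, seed = 1L) {
  if (replicates < 2) stop("need >= 2 replicates")
  if (active_fraction < 0 || active_fraction > 1) {
    stop("active_fraction must be in [0,1]")
  }
  n_active <- round(active_fraction * n_fragments)
  sigma <- sqrt(log(1 + replicate_cv^2))
  base_ratio <- 0.8  # arbitrary instrument-scale firefly/renilla baseline
  with_seed(seed, {
    active <- rep(FALSE, n_fragments)
    active[sample.int(n_fragments, n_active)] <- TRUE
    ids <- c(sprintf("frag_%02d", seq_len(n_fragments)), "neg_control")
    fold <- c(ifelse(active, mean_fold_activity, 1), 1)
    is_neg <- c(rep(FALSE, n_fragments), TRUE)
    rows <- lapply(seq_along(ids), function(i) {
      ratio <- fold[i] * base_ratio *
        stats::rlnorm(replicates, meanlog = -sigma^2 / 2, sdlog = sigma)
      renilla <- stats::rlnorm(replicates, meanlog = log(2e5), sdlog = 0.1)
      tibble::tibble(fragment_id = ids[i], replicate = seq_len(replicates),
                     firefly = ratio * renilla, renilla = renilla,
                     is_negative_control = is_neg[i])
    })
    list(table = do.call(rbind, rows),
         truth = tibble::tibble(fragment_id = ids,
                                is_active = c(active, FALSE),
                                true_fold = fold))
  })
}
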