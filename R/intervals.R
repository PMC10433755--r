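#' Genome table
#'
#' Validates an ordered mapping of chromosome name to length. This is the
#' coordinate space for all interval arithmetic; synthetic genomes use the
#' same structure as a real assembly's chromosome-size table.
#'
#' @param lengths named numeric/integer vector of chromosome lengths (bp).
#' @return named integer vector of lengths.
#' @export
#' @examples
#' genome_table(c(`2L` = 1e5, `2R` = 1e5))
genome_table <- function(lengths) {
  nm <- names(lengths)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("genome table requires unique, non-empty chromosome names")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  stats::setNames(as.integer(lengths), nm)
}

genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = unname(as.integer(genome)))
}

#' Convert a whole genome to an interval set
#'
#' @param genome named vector from [genome_table()].
#' @return `GRanges` covering every chromosome end to end.
#' @export
genome_granges <- function(genome) {
  genome <- genome_table(genome)
  GenomicRanges::GRanges(names(genome),
                         IRanges::IRanges(1L, unname(genome)),
                         seqinfo = genome_seqinfo(genome))
}

# Put two GRanges on a shared seqlevel set so set operations are defined.
harmonize_seqlevels <- function(a, b) {
  lev <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lev
  GenomeInfoDb::seqlevels(b) <- lev
  list(a = a, b = b)
}

#' Merge an interval set
#'
#' Sorts and collapses overlapping *and adjacent* intervals so that coverage
#' sums are well defined. Strand is ignored.
#'
#' @param x a `GRanges`.
#' @return merged `GRanges`, sorted, pairwise disjoint and non-adjacent.
#' @export
merge_intervals <- function(x) {
  GenomicRanges::reduce(x, ignore.strand = TRUE)
}

#' Intersect two interval sets
#'
#' Base pairs present in both `a` and `b`, as merged intervals. The
#' BEDTools-intersect analogue used when computing how much of each genomic
#' element class the peaks cover.
#'
#' @param a,b `GRanges`.
#' @return merged `GRanges` of shared base pairs.
#' @export
intersect_intervals <- function(a, b) {
  h <- harmonize_seqlevels(a, b)
  GenomicRanges::intersect(h$a, h$b, ignore.strand = TRUE)
}

#' Subtract one interval set from another
#'
#' Base pairs in `a` and not in `b` (BEDTools-subtract analogue; used to
#' derive intergenic space from the annotated element classes).
#'
#' @param a,b `GRanges`.
#' @return merged `GRanges` of `a`'s private base pairs.
#' @export
subtract_intervals <- function(a, b) {
  h <- harmonize_seqlevels(a, b)
  GenomicRanges::setdiff(h$a, h$b, ignore.strand = TRUE)
}

#' Total merged length of an interval set
#'
#' @param x `GRanges`.
#' @return total number of covered base pairs.
#' @export
total_length <- function(x) {
  sum(as.numeric(IRanges::width(merge_intervals(x))))
}

#' Fraction of an element set covered by peaks
#'
#' Summed intersection length divided by the summed element length, both
#' operands merged first.
#'
#' @param peaks `GRanges` of peaks.
#' @param element `GRanges` of a genomic element class.
#' @return coverage ratio in \[0, 1\].
#' @export
coverage_fraction <- function(peaks, element) {
  denom <- total_length(element)
  if (denom == 0) stop("zero-length denominator: element set is empty")
  total_length(intersect_intervals(peaks, element)) / denom
}

#' Per-query overlap flags against a reference set
#'
#' `TRUE` where at least one base pair of the query intersects any reference
#' interval. Half-open adjacency does not count as overlap.
#'
#' @param query `GRanges` of query intervals (e.g. assay peaks).
#' @param reference `GRanges` reference set.
#' @return logical vector, one flag per query.
#' @export
overlaps_any <- function(query, reference) {
  h <- harmonize_seqlevels(query, reference)
  IRanges::overlapsAny(h$a, h$b, ignore.strand = TRUE)
}

## ---- narrowPeak / BED I/O (0-based half-open on disk, GRanges in memory) ----

parse_int_field <- function(x, line, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)) || any(v != floor(v))) {
    stop("malformed ", what, " at line ", line)
  }
  v
}

#' Read a narrowPeak or 3-column BED file of peaks
#'
#' narrowPeak (BED6+4, MACS2 dialect) requires >= 10 tab-separated columns;
#' column 10 is the summit offset from the peak start. Plain 3-column BED is
#' accepted, with the summit defaulting to the interval midpoint. File
#' coordinates are 0-based half-open; the returned `GRanges` is 1-based
#' closed with an absolute 1-based `summit` metadata column.
#'
#' @param path file path.
#' @param genome optional [genome_table()]; when given, records are bound
#'   checked against chromosome lengths.
#' @return `GRanges` with metadata columns `name`, `score`, `signalValue`,
#'   `pValue`, `qValue`, `summit`, in file order.
#' @export
read_narrowpeak <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(GenomicRanges::GRanges(summit = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(!(ncols == 3 | ncols >= 10))
  if (length(bad)) {
    stop("malformed record (expected 3 or >=10 tab-separated columns) at line ",
         bad[1])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- numeric(length(fields)); end0 <- numeric(length(fields))
  summit_off <- numeric(length(fields))
  name <- character(length(fields)); score <- rep(NA_real_, length(fields))
  strand <- rep("*", length(fields))
  signal <- rep(NA_real_, length(fields)); pval <- rep(NA_real_, length(fields))
  qval <- rep(NA_real_, length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    start0[i] <- parse_int_field(f[2], i, "start coordinate")
    end0[i] <- parse_int_field(f[3], i, "end coordinate")
    if (start0[i] < 0 || end0[i] <= start0[i]) {
      stop("malformed interval (need 0 <= start < end) at line ", i)
    }
    w <- end0[i] - start0[i]
    if (ncols[i] >= 10) {
      name[i] <- f[4]
      score[i] <- suppressWarnings(as.numeric(f[5]))
      strand[i] <- if (f[6] %in% c("+", "-")) f[6] else "*"
      signal[i] <- suppressWarnings(as.numeric(f[7]))
      pval[i] <- suppressWarnings(as.numeric(f[8]))
      qval[i] <- suppressWarnings(as.numeric(f[9]))
      summit_off[i] <- parse_int_field(f[10], i, "summit offset")
      if (summit_off[i] < 0 || summit_off[i] >= w) {
        stop("summit offset outside peak (offset ", summit_off[i],
             ", width ", w, ") at line ", i)
      }
    } else {
      name[i] <- sprintf("peak_%d", i)
      summit_off[i] <- w %/% 2
    }
  }
  gr <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand,
    name = name, score = score, signalValue = signal,
    pValue = pval, qValue = qval,
    summit = as.integer(start0 + summit_off + 1)
  )
  if (!is.null(genome)) {
    genome <- genome_table(genome)
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown)) {
      stop("chromosome(s) absent from genome table: ",
           paste(unknown, collapse = ", "))
    }
    if (any(end0 > genome[chrom])) {
      stop("interval exceeds chromosome length at line ",
           which(end0 > genome[chrom])[1])
    }
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(genome)
  }
  gr
}

#' Write peaks as a narrowPeak file
#'
#' Emits 10 tab-separated columns with 0-based half-open coordinates and the
#' summit offset in column 10. Missing numeric metadata is written as -1,
#' the conventional placeholder.
#'
#' @param peaks `GRanges`, ideally with a `summit` metadata column
#'   (defaults to the midpoint when absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- length(peaks)
  mc <- S4Vectors::mcols(peaks)
  start0 <- GenomicRanges::start(peaks) - 1
  end0 <- GenomicRanges::end(peaks)
  summit <- if ("summit" %in% names(mc)) mc$summit else
    as.integer(start0 + (end0 - start0) %/% 2 + 1)
  num_or <- function(x, default) {
    if (is.null(x)) rep(default, n) else ifelse(is.na(x), default, x)
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = start0,
    end = end0,
    name = if (!is.null(mc$name)) mc$name else sprintf("peak_%d", seq_len(n)),
    score = num_or(mc$score, 0),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(peaks))),
    signalValue = num_or(mc$signalValue, -1),
    pValue = num_or(mc$pValue, -1),
    qValue = num_or(mc$qValue, -1),
    peak = summit - 1 - start0
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an interval set as BED
#'
#' @param x `GRanges`.
#' @param path output path.
#' @param strand write 6 columns including strand (BED6) instead of BED3.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, strand = FALSE) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1,
    end = GenomicRanges::end(x)
  )
  if (strand) {
    df$name <- if (!is.null(S4Vectors::mcols(x)$name))
      S4Vectors::mcols(x)$name else sprintf("iv_%d", seq_along(x))
    df$score <- 0
    df$strand <- sub("\\*", ".", as.character(GenomicRanges::strand(x)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file as an interval set
#'
#' @param path file path.
#' @return `GRanges` (strand kept when present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- vapply(seq_along(fields), function(i)
    parse_int_field(fields[[i]][2], i, "start coordinate"), numeric(1))
  end0 <- vapply(seq_along(fields), function(i)
    parse_int_field(fields[[i]][3], i, "end coordinate"), numeric(1))
  strand <- vapply(fields, function(f)
    if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "*", "")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strand)
}

## ---- exclusion-aware shuffle --------------------------------------------

# Sorted disjoint blocklist utilities on 0-based half-open coordinates.
bl_insert <- function(bl, s, e) {
  starts <- c(bl$starts, s); ends <- c(bl$ends, e)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      if (starts[i] <= me) {
        me <- max(me, ends[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
  }
  list(starts = c(out_s, ms), ends = c(out_e, me))
}

bl_overlaps <- function(bl, s, e) {
  n <- length(bl$starts)
  if (n == 0) return(FALSE)
  idx <- findInterval(s, bl$starts)
  (idx >= 1 && bl$ends[idx] > s) || (idx < n && bl$starts[idx + 1] < e)
}

# Free gaps between blocked intervals on a chromosome of length L,
# as a 2-column matrix of 0-based half-open [start, end).
bl_gaps <- function(bl, L) {
  gs <- c(0, bl$ends)
  ge <- c(bl$starts, L)
  keep <- ge > gs
  cbind(gs[keep], ge[keep])
}

# Draw one start position uniformly over all feasible placements of a
# width-w interval in the free gaps. Returns NA when no placement exists.
bl_draw_start <- function(bl, L, w) {
  gaps <- bl_gaps(bl, L)
  room <- pmax(0, (gaps[, 2] - gaps[, 1]) - w + 1)
  total <- sum(room)
  if (total == 0) return(NA_real_)
  u <- floor(stats::runif(1, 0, total))
  if (u >= total) u <- total - 1
  g <- which(cumsum(room) > u)[1]
  gaps[g, 1] + (u - if (g > 1) sum(room[seq_len(g - 1)]) else 0)
}

#' Sample width-matched control intervals avoiding exclusions
#'
#' Exclusion-aware shuffle (the BEDTools-shuffle analogue): each input
#' peak is relocated, in input order, to a start position drawn uniformly
#' over all placements that keep its width, stay on the chromosome, and do
#' not intersect the exclusion set (nor, by default, any already-placed
#' output). The draw is made directly over the feasible gap structure, so
#' a placement fails only when no feasible position exists at all. Used to
#' draw the negative (control) regions for sequence models, with
#' exclusions set to coding sequence plus the assay's own peaks.
#'
#' @param peaks `GRanges` of source intervals (widths are preserved).
#' @param genome [genome_table()] giving placement space.
#' @param exclusions `GRanges` that outputs must not intersect.
#' @param same_chrom keep each control on its source peak's chromosome
#'   (default `TRUE`, keeping chromosome folds balanced).
#' @param forbid_mutual_overlap forbid controls overlapping each other
#'   (default `TRUE`).
#' @param max_tries chromosome re-draw attempts per peak when
#'   `same_chrom = FALSE` (a chromosome can be drawn and turn out full).
#' @param seed integer seed; output is deterministic given the seed.
#' @return `GRanges` of control intervals, one per input peak, in input
#'   order.
#' @export
shuffle_with_exclusions <- function(peaks, genome, exclusions = NULL,
                                    same_chrom = TRUE,
                                    forbid_mutual_overlap = TRUE,
                                    max_tries = 10000L, seed = 1L) {
  genome <- genome_table(genome)
  widths <- GenomicRanges::width(peaks)
  src_chrom <- as.character(GenomicRanges::seqnames(peaks))
  if (same_chrom && length(setdiff(unique(src_chrom), names(genome)))) {
    stop("peak chromosome absent from genome table")
  }
  blocked <- stats::setNames(
    rep(list(list(starts = numeric(0), ends = numeric(0))), length(genome)),
    names(genome))
  if (!is.null(exclusions) && length(exclusions)) {
    ex <- merge_intervals(exclusions)
    ex_chr <- as.character(GenomicRanges::seqnames(ex))
    for (ch in intersect(unique(ex_chr), names(genome))) {
      sel <- ex_chr == ch
      blocked[[ch]] <- list(starts = GenomicRanges::start(ex)[sel] - 1,
                            ends = as.numeric(GenomicRanges::end(ex)[sel]))
    }
  }
  out_chrom <- character(length(peaks))
  out_start0 <- numeric(length(peaks))
  with_seed(seed, {
    for (i in seq_along(peaks)) {
      w <- widths[i]
      s <- NA_real_
      ch <- NA_character_
      if (same_chrom) {
        ch <- src_chrom[i]
        # When controls may overlap each other, feasibility ignores
        # already-placed outputs, so draw against the exclusion list only.
        s <- bl_draw_start(blocked[[ch]], genome[[ch]], w)
      } else {
        for (try in seq_len(max_tries)) {
          room <- pmax(genome - w + 1, 0)
          ch <- sample(names(genome), 1, prob = room / sum(room))
          s <- bl_draw_start(blocked[[ch]], genome[[ch]], w)
          if (!is.na(s)) break
        }
      }
      if (is.na(s)) {
        stop("could not place control for peak ", i, " (width ", w,
             "): no feasible position remains")
      }
      out_chrom[i] <- ch
      out_start0[i] <- s
      if (forbid_mutual_overlap) {
        blocked[[ch]] <- bl_insert(blocked[[ch]], s, s + w)
      }
    }
  })
  GenomicRanges::GRanges(out_chrom,
                         IRanges::IRanges(out_start0 + 1, width = widths),
                         seqinfo = genome_seqinfo(genome))
}
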