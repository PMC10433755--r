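test_that("simulated genomes hit the requested GC and are reproducible", {
  arms <- stats::setNames(rep(1e5, 5), c("2L", "2R", "3L", "3R", "X"))
  g1 <- simulate_genome(arms, gc_content = 0.5, seed = 21)
  g2 <- simulate_genome(arms, gc_content = 0.5, seed = 21)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_equal(names(g1$genome), c("2L", "2R", "3L", "3R", "X"))
  freq <- Biostrings::alphabetFrequency(g1$sequences[["2L"]])
  gc <- sum(freq[c("C", "G")]) / 1e5
  # within 3 binomial standard deviations of the target
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e5))
  # FASTA round-trip at 60 columns
  path <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g1$sequences, path)
  expect_equal(nchar(readLines(path)[2]), 60L)
  back <- read_genome_fasta(path)
  expect_identical(as.character(back), as.character(g1$sequences))
})

test_that("annotation geometry: strand-aware TSS, in-bounds elements", {
  arms <- stats::setNames(rep(1e5, 5), c("2L", "2R", "3L", "3R", "X"))
  genome <- genome_table(arms)
  ann <- simulate_annotation(genome, gene_count = 50, seed = 31)
  # genes non-overlapping
  expect_equal(total_length(ann$genes),
               sum(as.numeric(GenomicRanges::width(ann$genes))))
  # every element inside its arm
  for (part in c("genes", "cds", "exon", "intron", "tss")) {
    gr <- ann[[part]]
    if (!length(gr)) next
    L <- genome[as.character(GenomicRanges::seqnames(gr))]
    expect_true(all(GenomicRanges::start(gr) >= 1))
    expect_true(all(GenomicRanges::end(gr) <= L))
  }
  # TSS is immediately upstream of the gene body, strand-aware
  plus <- which(as.character(GenomicRanges::strand(ann$genes)) == "+")
  if (length(plus)) {
    g <- plus[1]
    t <- ann$tss[as.character(GenomicRanges::seqnames(ann$tss)) ==
                   as.character(GenomicRanges::seqnames(ann$genes))[g] &
                 GenomicRanges::end(ann$tss) ==
                   GenomicRanges::start(ann$genes)[g] - 1]
    expect_equal(length(t), 1L)
    expect_equal(GenomicRanges::width(t), 500L)
  }
  minus <- which(as.character(GenomicRanges::strand(ann$genes)) == "-")
  if (length(minus)) {
    g <- minus[1]
    t <- ann$tss[GenomicRanges::start(ann$tss) ==
                   GenomicRanges::end(ann$genes)[g] + 1]
    expect_gte(length(t), 1L)
  }
  # exons plus introns tile each gene body exactly
  expect_equal(total_length(ann$genes),
               total_length(ann$exon) + total_length(ann$intron))
})

test_that("planted peaks carry signal at the configured geometry", {
  w <- tiny_world(n = 40, signal_strength = 1, offset = 0, seed = 51)
  pl <- w$planted
  expect_equal(length(pl$peaks), 40L)
  # ledger instances land inside the 501-bp summit window of their peak
  summit0 <- S4Vectors::mcols(pl$peaks)$summit - 1
  names(summit0) <- S4Vectors::mcols(pl$peaks)$name
  win_lo <- summit0[pl$ledger$peak] - 250
  win_hi <- summit0[pl$ledger$peak] + 251
  expect_true(all(pl$ledger$start0 >= win_lo & pl$ledger$end0 <= win_hi))
  # the planted sequence is really in the mutated genome
  for (i in seq_len(5)) {
    row <- pl$ledger[i, ]
    written <- as.character(Biostrings::subseq(
      pl$sequences[[row$chrom]], row$start0 + 1, row$end0))
    expect_equal(nchar(written), row$end0 - row$start0)
  }

  # zero signal: the genome is untouched
  w0 <- tiny_world(n = 20, signal_strength = 0, seed = 52)
  expect_identical(as.character(w0$planted$sequences),
                   as.character(w0$sim$sequences))
  expect_equal(nrow(w0$planted$ledger), 0L)

  # offset beyond the window: no instance inside the summit window
  wo <- tiny_world(n = 30, signal_strength = 1, offset = 400, seed = 53)
  s0 <- S4Vectors::mcols(wo$planted$peaks)$summit - 1
  names(s0) <- S4Vectors::mcols(wo$planted$peaks)$name
  led <- wo$planted$ledger
  inside <- led$end0 > (s0[led$peak] - 250) & led$start0 < (s0[led$peak] + 251)
  expect_false(any(inside))
})

test_that("planted peaks avoid exclusions and are reproducible", {
  arms <- stats::setNames(rep(6e4, 5), c("2L", "2R", "3L", "3R", "X"))
  sim <- simulate_genome(arms, seed = 61)
  excl <- GenomicRanges::GRanges(c("2L", "3R"),
                                 IRanges::IRanges(c(10000, 20000),
                                                  width = 15000))
  spec <- assay_sim_spec("t", peak_count = 50, width_mean = 120,
                         width_sd = 20, seed = 62)
  p1 <- plant_peaks(sim$sequences, sim$genome, spec, exclusions = excl)
  p2 <- plant_peaks(sim$sequences, sim$genome, spec, exclusions = excl)
  expect_identical(as.data.frame(p1$peaks), as.data.frame(p2$peaks))
  expect_identical(as.character(p1$sequences), as.character(p2$sequences))
  expect_false(any(overlaps_any(p1$peaks, excl)))
  # peaks mutually non-overlapping
  expect_equal(total_length(p1$peaks),
               sum(as.numeric(GenomicRanges::width(p1$peaks))))
})

test_that("luciferase simulator matches its noiseless and null limits", {
  # no active fragments in the truth at active_fraction 0
  s0 <- simulate_luciferase(10, active_fraction = 0, seed = 71)
  expect_false(any(s0$truth$is_active))
  # near-noiseless: relative activity of active fragments approaches fold
  s <- simulate_luciferase(12, active_fraction = 0.5, mean_fold_activity = 2,
                           replicate_cv = 1e-4, seed = 72)
  res <- luciferase_analysis(s$table)
  act <- res$mean_activity[match(
    s$truth$fragment_id[s$truth$is_active], res$fragment_id)]
  expect_true(all(abs(act - 2) < 0.01))
  ina <- res$mean_activity[match(
    setdiff(s$truth$fragment_id[!s$truth$is_active], "neg_control"),
    res$fragment_id)]
  expect_true(all(abs(ina - 1) < 0.01))
  # determinism
  s2 <- simulate_luciferase(12, active_fraction = 0.5, mean_fold_activity = 2,
                            replicate_cv = 1e-4, seed = 72)
  expect_identical(s$table, s2$table)
})
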