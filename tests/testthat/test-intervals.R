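test_that("narrowPeak parsing maps fields and validates records", {
  path <- write_temp_narrowpeak(c(
    "2L\t100\t601\tp1\t0\t.\t5.0\t10.0\t8.0\t250",
    "X\t0\t10"
  ))
  gr <- read_narrowpeak(path)
  expect_equal(length(gr), 2L)
  expect_equal(GenomicRanges::start(gr)[1], 101L)  # 0-based file, 1-based GRanges
  expect_equal(GenomicRanges::end(gr)[1], 601L)
  expect_equal(S4Vectors::mcols(gr)$summit[1], 100L + 250L + 1L)
  # 3-column BED: summit defaults to the midpoint
  expect_equal(S4Vectors::mcols(gr)$summit[2], 0L + 5L + 1L)

  bad_summit <- write_temp_narrowpeak(
    "2L\t100\t200\tp1\t0\t.\t1\t1\t1\t150")
  expect_error(read_narrowpeak(bad_summit), "summit offset.*line 1")
  bad_cols <- write_temp_narrowpeak("2L\t100\t200\tp1")
  expect_error(read_narrowpeak(bad_cols), "line 1")
  bad_coord <- write_temp_narrowpeak("2L\t200\t100\tp\t0\t.\t1\t1\t1\t5")
  expect_error(read_narrowpeak(bad_coord), "line 1")
})

test_that("narrowPeak writer round-trips records in file order", {
  genome <- five_arm_table()
  set.seed(41)
  n <- 137
  gr <- random_granges(n, genome, max_width = 400)
  S4Vectors::mcols(gr)$summit <- as.integer(
    GenomicRanges::start(gr) + GenomicRanges::width(gr) %/% 2)
  S4Vectors::mcols(gr)$name <- sprintf("p%03d", seq_len(n))
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(gr, path)
  back <- read_narrowpeak(path, genome)
  expect_equal(length(back), n)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(S4Vectors::mcols(back)$summit, S4Vectors::mcols(gr)$summit)
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(gr)$name)
})

test_that("merge/intersect/subtract match small worked cases", {
  a <- GenomicRanges::GRanges("2L", IRanges::IRanges(c(1, 6), c(10, 20)))
  expect_equal(GenomicRanges::width(merge_intervals(a)), 20L)
  expect_equal(length(merge_intervals(GenomicRanges::GRanges())), 0L)

  x <- GenomicRanges::GRanges("2L", IRanges::IRanges(1, 100))
  y <- GenomicRanges::GRanges("2L", IRanges::IRanges(51, 150))
  ix <- intersect_intervals(x, y)
  expect_equal(GenomicRanges::start(ix), 51L)
  expect_equal(GenomicRanges::end(ix), 100L)

  z <- GenomicRanges::GRanges("2L", IRanges::IRanges(51, 60))
  sub <- subtract_intervals(x, z)
  expect_equal(GenomicRanges::start(sub), c(1L, 61L))
  expect_equal(GenomicRanges::end(sub), c(50L, 100L))
  expect_equal(length(subtract_intervals(z, x)), 0L)
})

test_that("interval algebra agrees with the per-base bitmap oracle", {
  genome <- five_arm_table(1e4)
  set.seed(11)
  for (rep in 1:4) {
    a <- random_granges(200, genome, max_width = 300)
    b <- random_granges(150, genome, max_width = 500)
    ba <- oracle_bitmap(a, genome); bb <- oracle_bitmap(b, genome)
    expect_equal(total_length(merge_intervals(a)), bitmap_total(ba))
    expect_equal(total_length(intersect_intervals(a, b)),
                 bitmap_total(bitmap_op(ba, bb, `&`)))
    expect_equal(total_length(subtract_intervals(a, b)),
                 bitmap_total(bitmap_op(ba, bb, function(x, y) x & !y)))
    # conservation: |A| = |A∩B| + |A\B|
    expect_equal(total_length(a),
                 total_length(intersect_intervals(a, b)) +
                   total_length(subtract_intervals(a, b)))
    expect_equal(coverage_fraction(a, b),
                 bitmap_total(bitmap_op(ba, bb, `&`)) / bitmap_total(bb))
    q <- random_granges(50, genome, max_width = 100)
    bq <- lapply(seq_along(q), function(i)
      any(oracle_bitmap(q[i], genome)[[
        as.character(GenomicRanges::seqnames(q))[i]]] &
          bb[[as.character(GenomicRanges::seqnames(q))[i]]]))
    expect_equal(overlaps_any(q, b), unlist(bq))
  }
})

test_that("half-open adjacency neither overlaps nor intersects", {
  a <- GenomicRanges::GRanges("2L", IRanges::IRanges(1, 10))    # [0,10)
  b <- GenomicRanges::GRanges("2L", IRanges::IRanges(11, 20))   # [10,20)
  expect_false(overlaps_any(a, b))
  expect_equal(length(intersect_intervals(a, b)), 0L)
  c <- GenomicRanges::GRanges("2L", IRanges::IRanges(10, 20))   # [9,20)
  expect_true(overlaps_any(a, c))
})

test_that("coverage_fraction handles identity and empty denominators", {
  peaks <- GenomicRanges::GRanges("2L", IRanges::IRanges(1, 50))
  el <- GenomicRanges::GRanges("2L", IRanges::IRanges(1, 100))
  expect_equal(coverage_fraction(peaks, el), 0.5)
  expect_equal(coverage_fraction(el, el), 1.0)
  expect_error(coverage_fraction(peaks, GenomicRanges::GRanges()),
               "zero-length denominator")
})

test_that("shuffle respects exclusions, widths, and determinism", {
  genome <- genome_table(c(chrA = 20))
  peak <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 10))
  excl <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 10))
  # only feasible placement is [10,20) (0-based)
  out <- shuffle_with_exclusions(peak, genome, excl, seed = 3)
  expect_equal(GenomicRanges::start(out), 11L)
  expect_equal(GenomicRanges::end(out), 20L)

  genome5 <- five_arm_table(3e4)
  set.seed(5)
  peaks <- random_granges(300, genome5, max_width = 150)
  excl <- random_granges(100, genome5, max_width = 400)
  s1 <- shuffle_with_exclusions(peaks, genome5, excl, seed = 99)
  s2 <- shuffle_with_exclusions(peaks, genome5, excl, seed = 99)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_equal(GenomicRanges::width(s1), GenomicRanges::width(peaks))
  expect_false(any(overlaps_any(s1, excl)))
  # non-overlap among outputs
  expect_equal(total_length(s1),
               sum(as.numeric(GenomicRanges::width(s1))))
  # same-chromosome placement by default
  expect_equal(as.character(GenomicRanges::seqnames(s1)),
               as.character(GenomicRanges::seqnames(peaks)))
})

test_that("shuffle errors when no feasible placement exists", {
  genome <- genome_table(c(chrA = 20))
  peak <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 15))
  excl <- GenomicRanges::GRanges("chrA", IRanges::IRanges(8, 12))
  expect_error(shuffle_with_exclusions(peak, genome, excl, seed = 1),
               "no feasible position")
})

test_that("shuffle can span chromosomes and allow mutual overlap", {
  genome <- five_arm_table(3e4)
  set.seed(6)
  peaks <- random_granges(100, genome, max_width = 100)
  s <- shuffle_with_exclusions(peaks, genome, same_chrom = FALSE,
                               forbid_mutual_overlap = FALSE, seed = 42)
  expect_equal(length(s), 100L)
  expect_equal(GenomicRanges::width(s), GenomicRanges::width(peaks))
})
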