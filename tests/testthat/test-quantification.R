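test_that("read counting is start-based and unstranded", {
  ann <- makeAnn("chr1", 100L, 200L, "pgA")
  mk <- function(starts, strands = "+", contig = "chr1") {
    gr <- GRanges(contig, IRanges(starts, width = 10L),
                  rep_len(strands, length(starts)))
    mcols(gr)$read_id <- paste0("r", seq_along(starts))
    gr
  }
  # 5 hits starting inside, 2 outside
  hits <- mk(c(100L, 150L, 191L, 200L, 120L, 95L, 300L),
             c("+", "-", "+", "-", "+", "+", "-"))
  counts <- countReadsPerFeature(hits, ann)
  expect_identical(counts, c(pgA = 5L))
  # a hit starting before the interval but overlapping it is NOT counted
  edge <- mk(95L)   # covers 95..104, start outside
  expect_identical(countReadsPerFeature(edge, ann), c(pgA = 0L))
  # no annotations -> empty counts
  expect_length(countReadsPerFeature(hits, makeAnn(character(0), integer(0),
                                                   integer(0),
                                                   character(0))), 0L)
  # overlap tie-break: smallest interval, then lexicographic id; warning
  ov <- c(makeAnn("chr1", 100L, 300L, "pgBig"),
          makeAnn("chr1", 120L, 180L, "pgSmall"))
  expect_warning(c2 <- countReadsPerFeature(mk(130L), ov), "overlap")
  expect_identical(c2, c(pgBig = 0L, pgSmall = 1L))
  tie <- c(makeAnn("chr1", 100L, 200L, "pgB"),
           makeAnn("chr1", 100L, 200L, "pgA"))
  expect_warning(c3 <- countReadsPerFeature(mk(130L), tie), "overlap")
  expect_identical(c3[["pgA"]], 1L)
  expect_identical(c3[["pgB"]], 0L)
})

test_that("summed feature counts never exceed the number of hits", {
  set.seed(5)
  ann <- c(makeAnn("chr1", 50L, 120L, "a"), makeAnn("chr1", 200L, 280L, "b"))
  for (i in 1:10) {
    starts <- sample(300L, 40L, replace = TRUE)
    gr <- GRanges("chr1", IRanges(starts, width = 10L), "+")
    mcols(gr)$read_id <- paste0("r", seq_along(starts))
    expect_lte(sum(countReadsPerFeature(gr, ann)), length(gr))
  }
})

test_that("effective length is the unique-start mass inside the feature", {
  # 0-based [100,200) with unique starts {150..179} -> 30
  track <- makeTrack(list(chr1 = 151:180), c(chr1 = 1000L), 10L)
  feat <- GRanges("chr1", IRanges(101L, 200L))
  expect_equal(effectiveLength(feat, track), 30L)
  # fully mappable feature of length 467
  full <- makeTrack(list(chr1 = 1:900), c(chr1 = 1000L), 75L)
  expect_equal(effectiveLength(GRanges("chr1", IRanges(10L, 476L)), full),
               467L)
  none <- makeTrack(list(chr1 = integer(0)), c(chr1 = 1000L), 10L)
  expect_equal(effectiveLength(feat, none), 0L)
  expect_lte(effectiveLength(feat, full), width(feat))
})

test_that("rpkm follows the reads-per-kilobase-per-million formula", {
  expect_equal(rpkm(10L, 500L, 1e6), 20)
  expect_equal(rpkm(0L, 500L, 1e6), 0)
  expect_equal(rpkm(0L, 0L, 1e6), 0)
  expect_equal(rpkm(4L, 468L, 3e7), 4 / 0.468 / 30, tolerance = 1e-12)
  expect_equal(round(rpkm(4L, 468L, 3e7), 4), 0.2849)
  expect_error(rpkm(3L, 0L, 1e6), "zero effective length")
  expect_error(rpkm(3L, 100L, 0), "positive")
  # invariant under duplicating reads and doubling the library
  expect_equal(rpkm(14L, 333L, 2.5e6), rpkm(28L, 333L, 5e6))
})

test_that("coverage fraction counts bases covered by at least one read", {
  feat <- GRanges("chr1", IRanges(101L, 300L))          # 200 bp = 2L
  one <- GRanges("chr1", IRanges(151L, width = 100L), "+")
  expect_equal(coverageFraction(one, feat), 0.5)
  expect_equal(coverageFraction(GRanges(), feat), 0)
  tiling <- GRanges("chr1", IRanges(seq(101L, 281L, by = 20L),
                                    width = 100L), "+")
  expect_equal(coverageFraction(tiling, feat), 1)
  # overlapping reads do not double-count bases; clipped at feature edges
  stack <- GRanges("chr1", IRanges(c(51L, 61L), width = 100L), "+")
  expect_equal(coverageFraction(stack, feat), 60 / 200)
  expect_true(coverageFraction(stack, feat) >= 0 &&
                coverageFraction(stack, feat) <= 1)
})

test_that("composite ratios reproduce published arithmetic", {
  expect_equal(compositeRatio(708L, 22613L), 0.03)
  expect_equal(compositeRatio(2439L, 22280L), 0.11)
  expect_equal(compositeRatio(17L, 17L), 1.00)
  expect_true(is.na(compositeRatio(5L, 0L)))
})

test_that("threshold summaries compute exceedance percentages", {
  expect_equal(unname(thresholdSummary(c(0, 6, 12), 5)), 100 * 2 / 3)
  expect_equal(unname(thresholdSummary(rep(0, 8), c(1, 5, 15))),
               c(0, 0, 0))
  expect_error(thresholdSummary(numeric(0)), "empty")
})

test_that("quantifySample assembles consistent expression records", {
  ann <- c(makeAnn("chr1", 101L, 200L, "pgA", "g1"),
           makeAnn("chr1", 401L, 500L, "pgB", "g2"))
  track <- makeTrack(list(chr1 = c(101:191, 401:410)), c(chr1 = 1000L), 10L)
  hits <- GRanges("chr1", IRanges(c(120L, 150L, 405L), width = 10L),
                  c("+", "-", "+"))
  mcols(hits)$read_id <- c("r1", "r2", "r3")
  rec <- quantifySample(hits, ann, track, totalMapped = 1e6, sample = "s")
  expect_equal(rec$read_count, c(2L, 1L))
  expect_equal(rec$effective_length, c(91L, 10L))
  expect_equal(rec$rpkm, rpkm(c(2L, 1L), c(91L, 10L), 1e6))
  expect_true(all(rec$coverage >= 0 & rec$coverage <= 1))
  expect_true(all(rec$effective_length <= width(ann)))
  # zero-count features report zero rpkm and coverage
  rec0 <- quantifySample(GRanges(), ann, track, 1e6)
  expect_true(all(rec0$read_count == 0L))
  expect_true(all(rec0$rpkm == 0))
  expect_true(all(rec0$coverage == 0))
})

test_that("expressionSE assembles a pseudogene x sample container", {
  ann <- c(makeAnn("chr1", 101L, 200L, "pgA", "g1"),
           makeAnn("chr1", 401L, 500L, "pgB", "g2"))
  track <- makeTrack(list(chr1 = 1:900), c(chr1 = 1000L), 10L)
  h1 <- GRanges("chr1", IRanges(150L, width = 10L), "+")
  mcols(h1)$read_id <- "r1"
  recs <- list(quantifySample(h1, ann, track, 1e6, "t1"),
               quantifySample(GRanges(), ann, track, 1e6, "t2"))
  se <- expressionSE(recs, ann)
  expect_s4_class(se, "SummarizedExperiment")
  expect_identical(dim(se), c(2L, 2L))
  m <- SummarizedExperiment::assay(se, "rpkm")
  expect_gt(m["pgA", "t1"], 0)
  expect_equal(m["pgA", "t2"], 0)
  expect_equal(m["pgB", "t1"], 0)
})
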