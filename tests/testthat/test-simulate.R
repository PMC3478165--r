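test_that("genome simulation is deterministic and structurally correct", {
  cfg <- simulationConfig(seed = 3L, nGenes = 2L, exonsPerGene = 3L,
                          exonLength = 120L, nPseudogenes = 0L,
                          chromLength = 20000L)
  a <- simulateGenome(cfg)
  b <- simulateGenome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.character(a$mrnas), as.character(b$mrnas))
  # 2 genes x 3 exons -> 2 mRNAs of summed exon length
  expect_length(a$mrnas, 2L)
  expect_true(all(width(a$mrnas) == 3L * 120L))
  expect_length(a$exons, 6L)
  # 0 genes -> genome only
  none <- simulateGenome(simulationConfig(seed = 3L, nGenes = 0L,
                                          nPseudogenes = 0L))
  expect_length(none$mrnas, 0L)
  # mRNAs really are the spliced exon sequence
  g1 <- a$exons[mcols(a$exons)$gene_id == "gene1"]
  resplice <- spliceTranscript(a$genome, g1,
                               as.character(strand(g1))[1L], "gene1")
  expect_identical(as.character(resplice[[1L]]),
                   as.character(a$mrnas[["gene1"]]))
})

test_that("plantPseudogene copies the mRNA with the requested divergence", {
  set.seed(9)
  sim <- simulateGenome(simulationConfig(seed = 9L, nGenes = 1L,
                                         nPseudogenes = 0L,
                                         chromLength = 10000L))
  mrna <- sim$mrnas[1L]
  len <- width(mrna)
  locus <- GRanges("chr1", IRanges(5000L, width = len))

  perfect <- plantPseudogene(sim$genome, mrna, 1.0, locus, id = "pgP",
                             parent = "gene1")
  planted <- as.character(subseq(perfect$genome[["chr1"]], 5000L,
                                 5000L + len - 1L))
  expect_identical(planted, as.character(mrna[[1L]]))
  expect_identical(mcols(perfect$annotation)$klass, "processed")
  expect_equal(width(perfect$annotation), len)

  # identity 0.9: substitution count is Binomial(len, 0.1)
  nsub <- replicate(30, {
    p <- plantPseudogene(sim$genome, mrna, 0.9, locus)
    copy <- as.character(subseq(p$genome[["chr1"]], 5000L, 5000L + len - 1L))
    sum(strsplit(copy, "")[[1L]] != strsplit(as.character(mrna[[1L]]),
                                             "")[[1L]])
  })
  expect_gt(mean(nsub), 0.1 * len * 0.6)
  expect_lt(mean(nsub), 0.1 * len * 1.4)

  expect_error(plantPseudogene(sim$genome, mrna, 0.9, locus,
                               occupied = locus), "collision")
  expect_error(plantPseudogene(sim$genome, mrna, 0.9,
                               GRanges("chr1", IRanges(9990L, width = len))),
               "bounds")
})

test_that("divergent sites create unique starts at a planted pseudogene", {
  sim <- simulateGenome(simulationConfig(seed = 13L, nGenes = 1L,
                                         nPseudogenes = 0L,
                                         chromLength = 10000L))
  mrna <- sim$mrnas[1L]
  len <- width(mrna)
  locus <- GRanges("chr1", IRanges(5000L, width = len))
  L <- 75L; m <- 4L
  inLocus <- function(track)
    sum(uniqueStarts(track, "chr1") >= 5000L &
          uniqueStarts(track, "chr1") <= 5000L + len - L)
  set.seed(101)
  p95 <- plantPseudogene(sim$genome, mrna, 0.95, locus)
  ref95 <- buildComposite(p95$genome, sim$mrnas)
  expect_gt(inLocus(computeUniqueStarts(ref95, L, m)), 0L)
  # a perfect copy leaves no unique window inside the locus
  p100 <- plantPseudogene(sim$genome, mrna, 1.0, locus)
  ref100 <- buildComposite(p100$genome, sim$mrnas)
  expect_equal(inLocus(computeUniqueStarts(ref100, L, m)), 0L)
})

test_that("read simulation respects expression design and is reproducible", {
  sources <- DNAStringSet(c(f1 = strrep("ACGT", 50), f2 = strrep("GGCA", 50)))
  expr <- matrix(c(1, 0, 0, 1), nrow = 2,
                 dimnames = list(c("f1", "f2"), c("tA", "tB")))
  r1 <- simulateReads(sources, expr, 50L, 25L, seed = 4L)
  r2 <- simulateReads(sources, expr, 50L, 25L, seed = 4L)
  expect_identical(as.character(r1$reads$tA), as.character(r2$reads$tA))
  # all mass on one feature -> all reads originate there
  expect_true(all(r1$truth$feature[r1$truth$tissue == "tA"] == "f1"))
  expect_true(all(r1$truth$feature[r1$truth$tissue == "tB"] == "f2"))
  expect_length(r1$reads$tA, 50L)
  expect_true(all(width(r1$reads$tA) == 25L))
  # n_reads = 0 -> empty read set
  r0 <- simulateReads(sources, expr, 0L, 25L)
  expect_length(r0$reads$tA, 0L)
  # features shorter than L are skipped with a warning
  shorty <- DNAStringSet(c(f1 = strrep("ACGT", 50), f2 = "ACGT"))
  expect_warning(simulateReads(shorty, expr, 10L, 25L), "shorter than L")
})

test_that("pseudogene read survival decreases with identity to the parent", {
  # the closer the copy is to its parent, the more of its reads also match
  # the decoy mRNA and are discarded as multi-mapped; a 75 bp read survives
  # iff it covers at least one substitution, so P(survive) = 1 - identity^75
  # (~98% at 0.95, ~53% at 0.99, 0 at 1.0)
  survival <- vapply(c(0.95, 0.99, 1.0), function(idy) {
    cfg <- simulationConfig(seed = 17L, nGenes = 1L, nPseudogenes = 1L,
                            identity = idy, tissues = "t1", nReads = 600L,
                            chromLength = 15000L,
                            expression = matrix(1, 1, 1,
                                                dimnames = list("pg1", "t1")))
    fx <- endToEndFixture(cfg)
    idx <- buildIndex(fx$composite, 75L)
    res <- mapUnique(idx, fx$reads$t1)
    res$stats$uniquely_mapped / res$stats$total_reads
  }, numeric(1))
  expect_gt(survival[1L], survival[2L])
  expect_gt(survival[2L], survival[3L])
  expect_equal(survival[3L], 0)   # a perfect copy never survives
})

test_that("parent-only reads never yield pseudogene counts", {
  cfg <- simulationConfig(seed = 23L, tissues = c("t1", "t2"),
                          nReads = 1200L,
                          expression = matrix(0, 0, 0))
  fx <- endToEndFixture(cfg)
  # resimulate reads from parent mRNAs only
  parentExpr <- matrix(1, nrow = length(fx$mrnas), ncol = 2,
                       dimnames = list(names(fx$mrnas), c("t1", "t2")))
  rd <- simulateReads(fx$mrnas, parentExpr, 1200L, 75L, seed = 24L)
  idx <- buildIndex(fx$composite, 75L)
  track <- computeUniqueStarts(fx$composite, 75L, 4L)
  for (t in c("t1", "t2")) {
    hits <- intersectHits(mapUnique(idx, rd$reads[[t]])$hits, track)
    counts <- countReadsPerFeature(hits, fx$annotations)
    expect_true(all(counts == 0L))   # hard zero false positives
  }
})

test_that("fixture files are written as plain text with a manifest", {
  dir <- file.path(tempdir(), "fixture-out")
  cfg <- simulationConfig(seed = 29L, tissues = c("t1", "t2"), nReads = 100L)
  fx <- endToEndFixture(cfg, dir = dir)
  expect_true(all(file.exists(unlist(fx$paths))))
  man <- jsonlite::read_json(fx$paths$manifest)
  expect_equal(man$read_length, 75L)
  expect_equal(man$seed, 29L)
  # FASTQ round-trips
  back <- readReadsFASTQ(fx$paths$reads[["t1"]])
  expect_identical(as.character(back), as.character(fx$reads$t1))
  # composite FASTA round-trips
  ref <- readComposite(fx$paths$composite)
  expect_identical(as.character(refSequences(ref)),
                   as.character(refSequences(fx$composite)))
  unlink(dir, recursive = TRUE)
})
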