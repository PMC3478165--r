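test_that("occurrences enumerates exact placements on both strands", {
  ref <- buildComposite(DNAStringSet(c(chr1 = "ACGTACGT")))
  idx <- buildIndex(ref, 4L)
  occ <- hitsToDf(occurrences(idx, "ACGT"))
  expect_equal(occ$start[occ$strand == "+"], c(1L, 5L))
  # CGTA occurs forward at 2 and reverse at 4 (revcomp of TACG)
  occ2 <- hitsToDf(occurrences(idx, "CGTA"))
  expect_equal(occ2[occ2$strand == "+", "start"], 2L)
  expect_equal(occ2[occ2$strand == "-", "start"], 4L)
  expect_length(occurrences(idx, "AAAA"), 0L)       # absent L-mer
  expect_length(occurrences(idx, "ACGN"), 0L)       # N never matches
  expect_error(occurrences(idx, "ACGTA"), "length")
  expect_error(buildIndex(ref, 100L), "exceeds")
})

test_that("mapRead reports all exact hits and rejects bad reads", {
  g <- DNAStringSet(c(chr1 = "TTTTACGTACTTTTT"))
  d <- DNAStringSet(c(m1 = "GGACGTACGG"))
  idx <- buildIndex(buildComposite(g, d), 6L)
  one <- mapRead(idx, "TTACGT", id = "r1")
  expect_length(one, 1L)
  expect_identical(mcols(one)$read_id, "r1")
  # a read present in a genome locus AND in a decoy mRNA contig: 2 hits
  two <- mapRead(idx, "ACGTAC")
  expect_length(two, 2L)
  expect_setequal(as.character(seqnames(two)), c("chr1", "m1"))
  expect_length(mapRead(idx, "ACGTNN"), 0L)
  expect_error(mapRead(idx, "ACGT"), "length")
})

test_that("mapUnique retains single-locus reads and tallies statistics", {
  g <- DNAStringSet(c(chr1 = "TTTTACGTACTTTTTGGGGGG"))
  d <- DNAStringSet(c(m1 = "GGACGTACGG"))
  idx <- buildIndex(buildComposite(g, d), 6L)
  reads <- DNAStringSet(c(u = "TTACGT",      # unique genome locus
                          dup = "ACGTAC",    # genome + decoy -> dropped
                          um = "AAAAAA"))    # unmapped on either strand
  res <- mapUnique(idx, reads, sample = "s1")
  expect_equal(res$stats$total_reads, 3L)
  expect_equal(res$stats$mapped, 2L)
  expect_equal(res$stats$uniquely_mapped, 1L)
  expect_identical(mcols(res$hits)$read_id, "u")

  empty <- mapUnique(idx, DNAStringSet())
  expect_length(empty$hits, 0L)
  expect_equal(unlist(empty$stats[, -1L], use.names = FALSE), c(0L, 0L, 0L))
})

test_that("palindromic reads hit one locus on both strands and are dropped", {
  # GTAC is its own reverse complement and occurs once forward
  g <- DNAStringSet(c(chr1 = "TTTGTACTTTAAACC"))
  idx <- buildIndex(buildComposite(g), 4L)
  hits <- mapRead(idx, "GTAC")
  expect_length(hits, 2L)
  expect_setequal(as.character(strand(hits)), c("+", "-"))
  expect_equal(unique(start(hits)), 4L)
  res <- mapUnique(idx, DNAStringSet(c(p = "GTAC")))
  expect_length(res$hits, 0L)
  expect_equal(res$stats$uniquely_mapped, 0L)
})

test_that("mapRead agrees with a naive full scan on random instances", {
  for (seed in 1:25) {
    ref <- randomReference(seed, nContigs = 2L, len = 120L,
                           nDecoys = seed %% 3L, decoyLen = 40L,
                           withN = seed %% 5L == 0L)
    idx <- buildIndex(ref, 10L)
    set.seed(seed + 1000L)
    seqs <- as.character(refSequences(ref))
    reads <- c(
      # reads sampled from the reference (guaranteed hits)
      vapply(1:4, function(i) {
        ctg <- sample(names(seqs), 1L)
        at <- sample(nchar(seqs[[ctg]]) - 9L, 1L)
        substr(seqs[[ctg]], at, at + 9L)
      }, character(1)),
      # random reads (mostly absent)
      vapply(1:3, function(i)
        paste0(sample(c("A", "C", "G", "T"), 10L, TRUE), collapse = ""),
        character(1)))
    for (r in reads) {
      got <- hitsToDf(mapRead(idx, r))
      want <- naiveScanHits(ref, r)
      want <- want[order(want$contig, want$start, want$strand), ,
                   drop = FALSE]
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                   info = paste("seed", seed, "read", r))
    }
  }
})

test_that("mapping the reverse complement flips strands, same loci", {
  for (seed in 1:10) {
    ref <- randomReference(seed, nContigs = 1L, len = 200L)
    idx <- buildIndex(ref, 12L)
    s <- as.character(refSequences(ref))[[1L]]
    at <- sample(189L, 1L)
    r <- substr(s, at, at + 11L)
    rc <- as.character(reverseComplement(DNAString(r)))
    a <- hitsToDf(mapRead(idx, r))
    b <- hitsToDf(mapRead(idx, rc))
    expect_equal(a$contig, b$contig)
    expect_equal(a$start, b$start)
    expect_equal(sort(a$strand), sort(chartr("+-", "-+", b$strand)))
  }
})

test_that("reads retained against the composite persist in the plain genome", {
  # composite filtering only removes reads; a read retained on a genome
  # contig of the composite is retained at the same locus genome-only
  for (seed in 1:8) {
    ref <- randomReference(seed, nContigs = 2L, len = 150L, nDecoys = 2L,
                           decoyLen = 50L)
    idxC <- buildIndex(ref, 12L)
    idxG <- buildIndex(genomeOnly(ref), 12L)
    set.seed(seed + 2000L)
    seqs <- as.character(refSequences(ref))
    reads <- DNAStringSet(vapply(1:30, function(i) {
      ctg <- sample(names(seqs), 1L)
      at <- sample(nchar(seqs[[ctg]]) - 11L, 1L)
      substr(seqs[[ctg]], at, at + 11L)
    }, character(1)))
    names(reads) <- paste0("r", 1:30)
    hc <- mapUnique(idxC, reads)
    hg <- mapUnique(idxG, reads)
    genomeHits <- hc$hits[!as.character(seqnames(hc$hits)) %in%
                            names(seqs)[isDecoy(ref)]]
    for (i in seq_along(genomeHits)) {
      rid <- mcols(genomeHits)$read_id[i]
      match <- hg$hits[mcols(hg$hits)$read_id == rid]
      expect_length(match, 1L)
      expect_identical(as.character(seqnames(match)),
                       as.character(seqnames(genomeHits)[i]))
      expect_equal(start(match), start(genomeHits)[i])
    }
    # genome-contig retentions are a subset, so they can never outnumber
    # the plain-genome retentions
    expect_lte(length(genomeHits), hg$stats$uniquely_mapped)
  }
})
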