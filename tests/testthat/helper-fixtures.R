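suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

# random composite reference: uniform ACGT genome contigs, optionally with
# decoy contigs copied (with a few substitutions) from genome stretches so
# that genuine near-duplicates exist
randomReference <- function(seed, nContigs = 2L, len = 150L, nDecoys = 0L,
                            decoyLen = 60L, withN = FALSE) {
  set.seed(seed)
  rand <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  g <- vapply(seq_len(nContigs), function(i) rand(len), character(1))
  if (withN) {
    # sprinkle a few N bases into the first contig
    v <- strsplit(g[1L], "")[[1L]]
    v[sample(len, max(1L, len %/% 40L))] <- "N"
    g[1L] <- paste0(v, collapse = "")
  }
  names(g) <- paste0("chr", seq_len(nContigs))
  d <- character(0)
  if (nDecoys > 0L) {
    d <- vapply(seq_len(nDecoys), function(i) {
      src <- sample(nContigs, 1L)
      at <- sample(len - decoyLen + 1L, 1L)
      v <- strsplit(substr(g[src], at, at + decoyLen - 1L), "")[[1L]]
      nmut <- sample(0:2, 1L)
      if (nmut > 0L) {
        pos <- sample(decoyLen, nmut)
        for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
      }
      paste0(v, collapse = "")
    }, character(1))
    names(d) <- paste0("mrna", seq_len(nDecoys))
  }
  buildComposite(DNAStringSet(g), DNAStringSet(d))
}

# independent exact-mapping oracle: scan every placement on both strands
# with plain substring comparison (no Biostrings matching machinery)
naiveScanHits <- function(ref, readSeq) {
  L <- nchar(readSeq)
  rc <- function(s) {
    v <- rev(strsplit(s, "")[[1L]])
    paste0(c(A = "T", C = "G", G = "C", T = "A", N = "N")[v], collapse = "")
  }
  if (grepl("[^ACGT]", readSeq))
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0)))
  readRC <- rc(readSeq)
  seqs <- as.character(refSequences(ref))
  out <- list()
  for (ctg in names(seqs)) {
    s <- seqs[[ctg]]
    n <- nchar(s)
    if (n < L) next
    for (p in seq_len(n - L + 1L)) {
      w <- substr(s, p, p + L - 1L)
      if (w == readSeq)
        out[[length(out) + 1L]] <- data.frame(contig = ctg, start = p,
                                              strand = "+")
      if (w == readRC)
        out[[length(out) + 1L]] <- data.frame(contig = ctg, start = p,
                                              strand = "-")
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0)))
  do.call(rbind, out)
}

hitsToDf <- function(gr) {
  df <- data.frame(contig = as.character(seqnames(gr)), start = start(gr),
                   strand = as.character(strand(gr)))
  df[order(df$contig, df$start, df$strand), , drop = FALSE]
}

# mappability track from explicit starts (test construction convenience)
makeTrack <- function(starts, seqlengths, L, m = 0L) {
  pseudoquant:::.makeTrack(starts, seqlengths, L, m)
}

# annotation GRanges builder
makeAnn <- function(contig, start, end, id, parent = "geneX",
                    klass = "processed") {
  GRanges(contig, IRanges(start, end), rep_len("+", length(start)),
          id = id, parent = rep_len(parent, length(start)),
          klass = rep_len(klass, length(start)))
}

# compact fixture for pipeline-level tests: 4 tissues, fewer reads
smallFixtureConfig <- function(seed = 11L) {
  simulationConfig(seed = seed, tissues = sprintf("tissue%02d", 1:4),
                   nReads = 1500L)
}
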