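# Exact, gapless read mapping on both strands with single-locus filtering.
#
# A hit is a placement (contig, start, strand) such that the reference
# substring (or its reverse complement for '-') equals the read exactly.
# Reads containing N never align.  Only reads with exactly one hit across
# the whole reference (both strands, genome and decoys) are retained, which
# removes both repeat-derived reads and reads shared with parent-mRNA
# decoys.

.emptyHits <- function(L) {
  gr <- GRanges()
  mcols(gr)$read_id <- character(0)
  gr
}

.hasN <- function(seqs) {
  grepl("[^ACGT]", as.character(seqs))
}

#' Build an exact-matching index
#'
#' @param ref A [CompositeReference-class].
#' @param L Read length (bp) the index will answer queries for.
#' @return An [ExactIndex-class].
#' @export
buildIndex <- function(ref, L) {
  stopifnot(is(ref, "CompositeReference"))
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be a positive integer")
  if (!any(width(ref@sequences) >= L))
    stop("L = ", L, " exceeds the length of every contig")
  new("ExactIndex", reference = ref, L = L)
}

#' Enumerate all exact occurrences of an L-mer
#'
#' Scans every contig on both strands and returns the deduplicated set of
#' placements `(contig, start, strand)`.  A `'-'`-strand occurrence at
#' start `s` means the reverse complement of the query equals the forward
#' reference substring starting at `s`.  Queries containing N have no
#' occurrences.
#'
#' @param index An [ExactIndex-class].
#' @param lmer Character or `DNAString` of length `L`.
#' @return `GRanges` of occurrences (width `L`), strand set accordingly.
#' @export
occurrences <- function(index, lmer) {
  stopifnot(is(index, "ExactIndex"))
  lmer <- as.character(lmer)
  L <- index@L
  if (nchar(lmer) != L)
    stop("query length ", nchar(lmer), " != index L = ", L)
  if (grepl("[^ACGT]", lmer)) return(.emptyHits(L))
  pat <- DNAString(lmer)
  rcp <- reverseComplement(pat)
  seqs <- index@reference@sequences
  out <- list()
  for (ctg in names(seqs)) {
    subject <- seqs[[ctg]]
    if (length(subject) < L) next
    fs <- start(matchPattern(pat, subject, fixed = TRUE))
    rs <- start(matchPattern(rcp, subject, fixed = TRUE))
    if (length(fs))
      out[[length(out) + 1L]] <- GRanges(ctg, IRanges(fs, width = L), "+")
    if (length(rs))
      out[[length(out) + 1L]] <- GRanges(ctg, IRanges(rs, width = L), "-")
  }
  if (length(out) == 0L) return(.emptyHits(L))
  gr <- suppressWarnings(do.call(c, out))
  mcols(gr)$read_id <- rep(NA_character_, length(gr))
  unique(gr)
}

#' Map one read
#'
#' Returns all exact hits of the read on both strands of every contig.
#' Reads containing N yield no hits.
#'
#' @param index An [ExactIndex-class].
#' @param read Character or `DNAString` of length `L`; may be named (the
#'   name becomes the hit `read_id`).
#' @param id Read identifier stored in the hits.
#' @return `GRanges` of hits with metadata column `read_id`.
#' @export
mapRead <- function(index, read, id = "read") {
  if (!is.null(names(read)) && length(names(read)) == 1L) id <- names(read)
  if (nchar(as.character(read)) != index@L)
    stop("read length ", nchar(as.character(read)),
         " != index L = ", index@L)
  hits <- occurrences(index, as.character(read))
  if (length(hits)) mcols(hits)$read_id <- id
  hits
}

#' Map a read set and retain single-locus alignments
#'
#' Maps every read exactly (no mismatches, both strands) against the whole
#' reference and keeps only reads with exactly one alignment locus;
#' multi-mapped reads (including reads shared between a genomic locus and a
#' parent-mRNA decoy, and palindromic reads hitting one locus on both
#' strands) and unmapped reads are dropped.
#'
#' @param index An [ExactIndex-class].
#' @param reads Named `DNAStringSet` (or named character vector) of reads,
#'   all of length `L`.  Quality strings, if any, are ignored.
#' @param sample Sample label recorded in the statistics row.
#' @return A list with elements
#'   \describe{
#'     \item{hits}{`GRanges`, one hit per retained read (`read_id` mcol).}
#'     \item{stats}{One-row `data.frame` with columns `sample`,
#'       `total_reads`, `mapped` (>= 1 hit), `uniquely_mapped` (exactly 1).}
#'   }
#' @export
mapUnique <- function(index, reads, sample = "sample") {
  stopifnot(is(index, "ExactIndex"))
  reads <- .asDNAStringSet(reads, "reads")
  L <- index@L
  n <- length(reads)
  stats <- function(mapped, uniq)
    data.frame(sample = sample, total_reads = n, mapped = mapped,
               uniquely_mapped = uniq, stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(hits = .emptyHits(L), stats = stats(0L, 0L)))
  if (any(width(reads) != L))
    stop("all reads must have length L = ", L)
  if (is.null(names(reads)))
    names(reads) <- paste0("read", seq_len(n))

  clean <- !.hasN(reads)                      # reads with N never align
  cseq <- as.character(reads[clean])
  if (length(cseq) == 0L)
    return(list(hits = .emptyHits(L), stats = stats(0L, 0L)))

  useq <- unique(cseq)                        # map each sequence once
  pd <- PDict(DNAStringSet(useq))
  pdrc <- PDict(reverseComplement(DNAStringSet(useq)))
  nh <- integer(length(useq))                 # hits per unique sequence
  hit_ctg <- character(length(useq))
  hit_start <- integer(length(useq))
  hit_strand <- character(length(useq))
  seqs <- index@reference@sequences
  for (ctg in names(seqs)) {
    subject <- seqs[[ctg]]
    if (length(subject) < L) next
    for (strnd in c("+", "-")) {
      mi <- matchPDict(if (strnd == "+") pd else pdrc, subject, fixed = TRUE)
      si <- Biostrings::startIndex(mi)
      cnt <- lengths(si)
      found <- which(cnt > 0L)
      if (length(found)) {
        nh[found] <- nh[found] + cnt[found]
        hit_ctg[found] <- ctg
        hit_start[found] <- vapply(si[found], `[[`, integer(1), 1L)
        hit_strand[found] <- strnd
      }
    }
  }
  keep <- nh == 1L
  # expand back to reads: a read is retained iff its sequence hit once
  idx <- match(cseq, useq)
  rkeep <- keep[idx]
  rid <- names(reads)[clean][rkeep]
  ki <- idx[rkeep]
  hits <- if (length(ki)) {
    gr <- GRanges(hit_ctg[ki], IRanges(hit_start[ki], width = L),
                  hit_strand[ki])
    mcols(gr)$read_id <- rid
    gr
  } else .emptyHits(L)
  mapped_reads <- sum(nh[idx] >= 1L)
  list(hits = hits, stats = stats(mapped_reads, sum(rkeep)))
}
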