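# Extended uniqueome: genome start positions whose L-mer window is unique
# within m mismatches against the whole composite reference.

.makeTrack <- function(starts, seqlengths, L, m) {
  new("MappabilityTrack", L = as.integer(L), m = as.integer(m),
      starts = IntegerList(starts), seqlengths = seqlengths)
}

#' Compute the extended uniqueome of a composite reference
#'
#' Marks, on every genome contig, the start positions whose L-bp window is
#' unique within `m` mismatches against all other placements in the
#' reference: every contig (genome and decoys unless `genomeOnly = TRUE`),
#' both strands.  The `'+'` placement at the queried position itself is not
#' counted; the `'-'` placement at the same start (a reverse-complement
#' palindrome self-match) is, mirroring the mapper's multi-hit rule.
#' Windows containing N are never unique.
#'
#' @param ref A [CompositeReference-class].
#' @param L Window (read) length in bp.
#' @param m Mismatch budget, `0 <= m < L`.
#' @param genomeOnly If `TRUE`, uniqueness is evaluated against the genome
#'   contigs only, reproducing a genome-wide uniqueome that ignores decoys.
#' @return A [MappabilityTrack-class].
#' @export
computeUniqueStarts <- function(ref, L, m, genomeOnly = FALSE) {
  stopifnot(is(ref, "CompositeReference"))
  L <- as.integer(L); m <- as.integer(m)
  if (is.na(L) || L < 1L) stop("L must be a positive integer")
  if (is.na(m) || m < 0L || m >= L) stop("need 0 <= m < L")
  seqs <- ref@sequences
  dec <- ref@isDecoy
  if (genomeOnly) { seqs <- seqs[!dec]; dec <- dec[!dec] }
  res <- cpp_unique_starts(as.character(seqs), dec, L, m)
  names(res) <- names(seqs)
  gnames <- names(seqs)[!dec]
  .makeTrack(res[gnames],
             stats::setNames(width(seqs)[!dec], gnames), L, m)
}

#' Brute-force uniqueome (reference oracle)
#'
#' Same contract as [computeUniqueStarts()], computed by exhaustive all-pairs
#' Hamming comparison of every window in plain R.  Intended for small
#' references (total length up to roughly 20 kb) and as an independent
#' correctness oracle in tests.
#'
#' @inheritParams computeUniqueStarts
#' @return A [MappabilityTrack-class].
#' @export
bruteForceUniqueStarts <- function(ref, L, m, genomeOnly = FALSE) {
  stopifnot(is(ref, "CompositeReference"))
  L <- as.integer(L); m <- as.integer(m)
  if (is.na(m) || m < 0L || m >= L) stop("need 0 <= m < L")
  seqs <- ref@sequences
  dec <- ref@isDecoy
  if (genomeOnly) { seqs <- seqs[!dec]; dec <- dec[!dec] }
  chars <- lapply(as.character(seqs), function(s) strsplit(s, "")[[1L]])
  rcmap <- c(A = "T", C = "G", G = "C", T = "A")

  # every N-free window as a character matrix row, tagged with provenance
  win <- list(); ctg <- integer(0); st <- integer(0); mins <- logical(0)
  for (i in seq_along(chars)) {
    v <- chars[[i]]; len <- length(v)
    if (len < L) next
    vr <- rev(unname(rcmap[v]))          # reverse complement, NA for non-ACGT
    vr[is.na(vr)] <- "N"
    for (p in seq_len(len - L + 1L)) {
      wf <- v[p:(p + L - 1L)]
      if (all(wf %in% c("A", "C", "G", "T"))) {
        win[[length(win) + 1L]] <- wf
        ctg <- c(ctg, i); st <- c(st, p); mins <- c(mins, FALSE)
      }
      wr <- vr[p:(p + L - 1L)]
      if (all(wr %in% c("A", "C", "G", "T"))) {
        win[[length(win) + 1L]] <- wr
        # reverse-strand window p corresponds to forward start len - L - p + 2
        ctg <- c(ctg, i); st <- c(st, len - L - p + 2L); mins <- c(mins, TRUE)
      }
    }
  }
  n <- length(win)
  starts <- lapply(which(!dec), function(i) integer(0))
  names(starts) <- names(seqs)[!dec]
  if (n > 0L) {
    W <- do.call(rbind, win)
    uniq <- !mins & !dec[ctg]
    for (a in which(uniq)) {
      for (b in seq_len(n)) {
        if (b == a) next
        if (sum(W[a, ] != W[b, ]) <= m) { uniq[a] <- FALSE; break }
      }
    }
    for (i in which(!dec)) {
      nm <- names(seqs)[i]
      starts[[nm]] <- sort(st[uniq & ctg == i])
    }
  }
  .makeTrack(starts, stats::setNames(width(seqs)[!dec], names(seqs)[!dec]),
             L, m)
}

#' Filter alignment hits by a mappability track
#'
#' Retains exactly the hits whose (contig, start) placement is a unique
#' start of the track.  Because the track only lists genome positions, all
#' hits on decoy contigs are removed here, as are hits at positions whose
#' window is duplicated within the mismatch budget (SNP/editing guard).
#' The hit strand is ignored: the uniqueome is strand-agnostic and marks
#' leftmost start positions.
#'
#' @param hits `GRanges` of alignment hits (width `L`).
#' @param track A [MappabilityTrack-class] with the same `L`.
#' @return The retained subset of `hits`.
#' @export
intersectHits <- function(hits, track) {
  stopifnot(is(track, "MappabilityTrack"))
  if (length(hits) == 0L) return(hits)
  if (any(BiocGenerics::width(hits) != track@L))
    stop("hit width does not match track L = ", track@L)
  ctg <- as.character(seqnames(hits))
  st <- start(hits)
  keep <- logical(length(hits))
  for (nm in intersect(unique(ctg), names(track@starts))) {
    sel <- ctg == nm
    keep[sel] <- st[sel] %in% track@starts[[nm]]
  }
  hits[keep]
}

#' Export a mappability track as BED3
#'
#' One record per unique start, as a width-1 interval `[s, s+1)` in 0-based
#' half-open BED coordinates on the positive strand.
#'
#' @param track A [MappabilityTrack-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportTrackBED <- function(track, path) {
  stopifnot(is(track, "MappabilityTrack"))
  rows <- lapply(names(track@starts), function(ctg) {
    st <- track@starts[[ctg]]
    if (length(st) == 0L) return(NULL)
    data.frame(ctg, st - 1L, st)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    file.create(path)
  } else {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Import a mappability track from BED
#'
#' Reads a BED file of width-1 unique-start records (gzip transparently
#' supported), e.g. an externally supplied uniqueome.
#'
#' @param path BED path (plain or gzip).
#' @param L,m Window length and mismatch budget the track was computed with
#'   (BED carries no header, so the parameters must be supplied).
#' @param seqlengths Named integer vector of genome contig lengths.  When
#'   omitted, a per-contig lower bound (`max(start) + L - 1`) is inferred
#'   from the records themselves; that is sufficient for
#'   [intersectHits()] and [effectiveLength()], which only consult the
#'   start positions.
#' @return A [MappabilityTrack-class].
#' @export
importTrackBED <- function(path, L, m, seqlengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  ctg <- character(0)
  s0 <- integer(0)
  if (length(lines)) {
    f <- strsplit(lines, "[ \t]+")
    ctg <- vapply(f, `[[`, character(1), 1L)
    s0 <- as.integer(vapply(f, `[[`, character(1), 2L))
  }
  if (is.null(seqlengths)) {
    if (!length(ctg)) stop("cannot infer 'seqlengths' from an empty track")
    seqlengths <- vapply(split(s0, ctg), max, integer(1)) + L
  }
  starts <- lapply(names(seqlengths), function(x) integer(0))
  names(starts) <- names(seqlengths)
  for (nm in unique(ctg)) {
    if (!nm %in% names(starts))
      stop("contig '", nm, "' not present in 'seqlengths'")
    starts[[nm]] <- sort(s0[ctg == nm] + 1L)
  }
  .makeTrack(starts, seqlengths, L, m)
}
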