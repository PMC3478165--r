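#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement PDict
#'   matchPDict matchPattern readDNAStringSet writeXStringSet subseq
#'   BStringSet width
#' @importFrom BiocGenerics start end strand strand<- width
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom IRanges IRanges IntegerList reduce
#' @importFrom GenomicRanges GRanges seqnames findOverlaps
#' @importFrom Rcpp evalCpp
#' @useDynLib pseudoquant, .registration = TRUE
NULL

#' Composite reference: genome contigs plus spliced-mRNA decoy contigs
#'
#' A composite reference concatenates the genome with spliced parent-gene
#' mRNA sequences ("decoys").  Reads originating from parent mRNAs then map
#' both to the genomic parent locus and to the decoy contig, become
#' multi-mapped, and are discarded by the exact-unique mapper, so that reads
#' surviving at a pseudogene locus cannot come from the parent transcript.
#'
#' Genome contigs always precede decoy contigs and contig names are unique
#' across the whole reference.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of all contigs, genome first.
#' @slot isDecoy Logical vector parallel to `sequences`; `TRUE` for
#'   spliced-mRNA decoy contigs.
#' @export
setClass("CompositeReference",
  slots = c(sequences = "DNAStringSet", isDecoy = "logical"))

setValidity("CompositeReference", function(object) {
  s <- object@sequences
  d <- object@isDecoy
  if (length(s) != length(d))
    return("'sequences' and 'isDecoy' must have the same length")
  if (length(s) == 0L || !any(!d))
    return("a composite reference needs at least one genome contig")
  nm <- names(s)
  if (is.null(nm) || any(!nzchar(nm)))
    return("every contig must have a non-empty name")
  if (anyDuplicated(nm))
    return(sprintf("duplicate contig id: '%s'", nm[duplicated(nm)][1L]))
  if (any(width(s) < 1L))
    return("contigs must have length >= 1")
  # genome block first, decoy block second
  if (is.unsorted(d))
    return("genome contigs must precede decoy contigs")
  TRUE
})

setMethod("show", "CompositeReference", function(object) {
  ng <- sum(!object@isDecoy); nd <- sum(object@isDecoy)
  cat("CompositeReference with", ng, "genome contig(s) and",
      nd, "decoy contig(s)\n")
  cat("  genome:", paste(utils::head(names(object@sequences)[!object@isDecoy], 5L),
                         collapse = ", "),
      if (ng > 5L) "..." else "", "\n")
  if (nd > 0L)
    cat("  decoys:", paste(utils::head(names(object@sequences)[object@isDecoy], 5L),
                           collapse = ", "),
        if (nd > 5L) "..." else "", "\n")
  cat("  total length:", sum(width(object@sequences)), "bp\n")
})

#' Exact-matching read index over a composite reference
#'
#' Opaque handle produced by [buildIndex()].  Supports enumeration of all
#' exact, gapless occurrences of any L-mer on both strands of every contig.
#'
#' @slot reference A [CompositeReference-class].
#' @slot L Integer read length the index answers queries for.
#' @export
setClass("ExactIndex",
  slots = c(reference = "CompositeReference", L = "integer"))

setValidity("ExactIndex", function(object) {
  if (length(object@L) != 1L || is.na(object@L) || object@L < 1L)
    return("'L' must be a single positive integer")
  if (!any(width(object@reference@sequences) >= object@L))
    return("L exceeds the length of every contig")
  TRUE
})

setMethod("show", "ExactIndex", function(object) {
  cat("ExactIndex (exact, gapless, both strands), L =", object@L, "\n")
  show(object@reference)
})

#' Mappability track (extended uniqueome)
#'
#' For each genome contig, the set of start positions (1-based) whose L-mer
#' window is unique within `m` mismatches against the whole reference
#' (genome and decoys, both strands).  Decoy contigs never carry unique
#' starts, so intersecting alignment hits with the track also removes every
#' decoy hit.
#'
#' @slot L Integer window (read) length in bp.
#' @slot m Integer mismatch budget.
#' @slot starts Named [S4Vectors::IntegerList]; per genome contig, sorted
#'   1-based unique start positions.
#' @slot seqlengths Named integer vector of genome contig lengths.
#' @export
setClass("MappabilityTrack",
  slots = c(L = "integer", m = "integer",
            starts = "IntegerList", seqlengths = "integer"))

setValidity("MappabilityTrack", function(object) {
  if (object@m < 0L || object@m >= object@L)
    return("need 0 <= m < L")
  if (is.null(names(object@starts)) || is.null(names(object@seqlengths)))
    return("'starts' and 'seqlengths' must be named by contig")
  if (!all(names(object@starts) %in% names(object@seqlengths)))
    return("every starts contig needs a seqlength")
  for (ctg in names(object@starts)) {
    st <- object@starts[[ctg]]
    if (length(st) && (min(st) < 1L ||
        max(st) + object@L - 1L > object@seqlengths[[ctg]]))
      return(sprintf("start out of bounds on contig '%s'", ctg))
  }
  TRUE
})

setMethod("show", "MappabilityTrack", function(object) {
  cat("MappabilityTrack: L =", object@L, "bp, m =", object@m, "mismatches\n")
  n <- sum(lengths(object@starts))
  cat(" ", n, "unique start position(s) over",
      length(object@starts), "genome contig(s)\n")
})

# ---- accessors ------------------------------------------------------------

#' Contig sequences of a composite reference
#' @param x A `CompositeReference`.
#' @return A `DNAStringSet` (all contigs, genome first).
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname refSequences
#' @export
setMethod("refSequences", "CompositeReference", function(x) x@sequences)

#' Decoy flags of a composite reference
#' @param x A `CompositeReference`.
#' @return Named logical vector, `TRUE` for decoy contigs.
#' @export
setGeneric("isDecoy", function(x) standardGeneric("isDecoy"))

#' @rdname isDecoy
#' @export
setMethod("isDecoy", "CompositeReference", function(x) {
  stats::setNames(x@isDecoy, names(x@sequences))
})

#' Genome-only view of a composite reference
#' @param x A `CompositeReference`.
#' @return A `CompositeReference` containing only the genome contigs.
#' @export
setGeneric("genomeOnly", function(x) standardGeneric("genomeOnly"))

#' @rdname genomeOnly
#' @export
setMethod("genomeOnly", "CompositeReference", function(x) {
  new("CompositeReference", sequences = x@sequences[!x@isDecoy],
      isDecoy = rep(FALSE, sum(!x@isDecoy)))
})

#' Unique start positions of a mappability track
#' @param x A `MappabilityTrack`.
#' @param contig Optional single contig name; if given, returns the integer
#'   vector for that contig, otherwise the full `IntegerList`.
#' @return `IntegerList` or integer vector of 1-based unique starts.
#' @export
setGeneric("uniqueStarts", function(x, contig = NULL) standardGeneric("uniqueStarts"))

#' @rdname uniqueStarts
#' @export
setMethod("uniqueStarts", "MappabilityTrack", function(x, contig = NULL) {
  if (is.null(contig)) return(x@starts)
  if (!contig %in% names(x@starts)) return(integer(0))
  x@starts[[contig]]
})

#' Window parameters of a mappability track
#' @param x A `MappabilityTrack`.
#' @return Named integer vector `c(L = , m = )`.
#' @export
setGeneric("trackParams", function(x) standardGeneric("trackParams"))

#' @rdname trackParams
#' @export
setMethod("trackParams", "MappabilityTrack", function(x) c(L = x@L, m = x@m))
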