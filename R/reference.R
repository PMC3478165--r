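# Composite-reference construction, transcript splicing and pseudogene
# annotation handling.

.asDNAStringSet <- function(x, what = "sequences") {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x)) return(DNAStringSet(x))
  stop("'", what, "' must be a DNAStringSet or a named character vector")
}

#' Build a composite reference from a genome and spliced transcripts
#'
#' Concatenates the genome contigs with spliced parent-gene mRNA sequences
#' used as decoys.  Sequences are taken as-is; genome contigs come first.
#'
#' @param genome Named `DNAStringSet` (or named character vector) of genome
#'   contigs.  Must be non-empty.
#' @param transcripts Named `DNAStringSet` of spliced mRNA decoy sequences;
#'   may be empty, in which case the composite degenerates to the plain
#'   genome.
#' @return A [CompositeReference-class].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC", chr2 = "TTTTCCCC"))
#' t <- Biostrings::DNAStringSet(c(RPL1 = "ACGTAC"))
#' buildComposite(g, t)
#' @export
buildComposite <- function(genome, transcripts = Biostrings::DNAStringSet()) {
  genome <- .asDNAStringSet(genome, "genome")
  transcripts <- .asDNAStringSet(transcripts, "transcripts")
  if (length(genome) == 0L)
    stop("genome must contain at least one contig")
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("all genome contigs must be named")
  if (length(transcripts) &&
      (is.null(names(transcripts)) || any(!nzchar(names(transcripts)))))
    stop("all transcript records must be named")
  clash <- intersect(names(genome), names(transcripts))
  if (length(clash))
    stop("id collision between genome and transcripts: '", clash[1L], "'")
  new("CompositeReference",
      sequences = c(genome, transcripts),
      isDecoy = c(rep(FALSE, length(genome)), rep(TRUE, length(transcripts))))
}

#' Splice a transcript out of a genome
#'
#' Concatenates the exon substrings (ascending genomic order) and
#' reverse-complements the concatenation when the gene is on the minus
#' strand, yielding the mature spliced mRNA sequence.
#'
#' @param genome Named `DNAStringSet` of contigs.
#' @param exons A `GRanges` of exons, all on one contig, non-overlapping,
#'   sorted in ascending genomic order.
#' @param strand `"+"` or `"-"`; gene orientation.
#' @param id Name to give the resulting record.
#' @return A named `DNAStringSet` of length 1.
#' @export
spliceTranscript <- function(genome, exons, strand = c("+", "-"),
                             id = "transcript") {
  genome <- .asDNAStringSet(genome, "genome")
  strand <- match.arg(strand)
  if (!is(exons, "GRanges")) stop("'exons' must be a GRanges")
  if (length(exons) == 0L) stop("need at least one exon")
  ctg <- unique(as.character(seqnames(exons)))
  if (length(ctg) != 1L) stop("all exons must lie on one contig")
  if (!ctg %in% names(genome)) stop("unknown contig '", ctg, "'")
  st <- start(exons); en <- end(exons)
  o <- order(st)
  st <- st[o]; en <- en[o]
  if (any(st[-1L] <= en[-length(en)]))
    stop("exons must be non-overlapping")
  if (min(st) < 1L || max(en) > width(genome[ctg]))
    stop("exon out of contig bounds on '", ctg, "'")
  pieces <- vapply(seq_along(st), function(i)
    as.character(subseq(genome[[ctg]], st[i], en[i])), character(1))
  mrna <- DNAString(paste0(pieces, collapse = ""))
  if (strand == "-") mrna <- reverseComplement(mrna)
  out <- DNAStringSet(list(mrna))
  names(out) <- id
  out
}

#' Load pseudogene annotations from a BED file
#'
#' Reads a BED4+ file (0-based half-open coordinates, converted to the
#' 1-based closed convention of `GRanges` on input) whose name field encodes
#' the pseudogene id, its parent gene and its class as
#' `"<id>|<parent>|<class>"` with class one of `processed` or `duplicated`.
#' Duplicated-class entries are retained but flagged; downstream
#' quantification uses only processed pseudogenes (see [filterProcessed()]).
#'
#' @param path Path to the BED file (fields separated by tabs or spaces; a
#'   sixth column, if present, is taken as the strand).
#' @return A `GRanges` with metadata columns `id`, `parent` and `klass`.
#' @export
loadAnnotations <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(id = character(0),
                                      parent = character(0),
                                      klass = character(0))
    return(gr)
  }
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) < 4L)
      stop("malformed BED line ", lineno[i], ": fewer than 4 fields")
    s0 <- suppressWarnings(as.integer(f[2L]))
    e0 <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s0) || is.na(e0) || s0 < 0L || e0 <= s0)
      stop("malformed BED line ", lineno[i],
           ": need integer 0 <= start < end")
    name <- strsplit(f[4L], "|", fixed = TRUE)[[1L]]
    if (length(name) != 3L || !name[3L] %in% c("processed", "duplicated"))
      stop("malformed BED line ", lineno[i],
           ": name field must be '<id>|<parent>|<class>' with class ",
           "'processed' or 'duplicated'")
    strand <- if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "*"
    list(contig = f[1L], start = s0 + 1L, end = e0,
         id = name[1L], parent = name[2L], klass = name[3L], strand = strand)
  })
  GRanges(
    seqnames = vapply(recs, `[[`, character(1), "contig"),
    ranges = IRanges(vapply(recs, `[[`, integer(1), "start"),
                     vapply(recs, `[[`, integer(1), "end")),
    strand = vapply(recs, `[[`, character(1), "strand"),
    id = vapply(recs, `[[`, character(1), "id"),
    parent = vapply(recs, `[[`, character(1), "parent"),
    klass = vapply(recs, `[[`, character(1), "klass"))
}

#' Write pseudogene annotations to a normalized BED file
#'
#' Inverse of [loadAnnotations()]: emits tab-separated BED6 with the
#' `"<id>|<parent>|<class>"` name convention and 0-based half-open
#' coordinates.
#'
#' @param ann `GRanges` with `id`, `parent`, `klass` metadata columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(ann, path) {
  strands <- as.character(strand(ann))
  strands[strands == "*"] <- "."
  df <- data.frame(as.character(seqnames(ann)), start(ann) - 1L, end(ann),
                   paste(mcols(ann)$id, mcols(ann)$parent, mcols(ann)$klass,
                         sep = "|"),
                   0L, strands)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep only processed pseudogenes
#'
#' Duplicated (non-processed) pseudogenes arise by segmental duplication and
#' are excluded from quantification; only retrotransposed, intronless
#' processed pseudogenes are analysed.
#'
#' @param ann `GRanges` from [loadAnnotations()].
#' @return The subset with `klass == "processed"`.
#' @export
filterProcessed <- function(ann) {
  if (length(ann) == 0L) return(ann)
  ann[mcols(ann)$klass == "processed"]
}

#' Parse a browser-style location string
#'
#' Converts `"chr8:134084035-134084502"` (1-based inclusive display
#' convention) to a `GRanges`.
#'
#' @param x Character vector of `"contig:start-end"` strings.
#' @return A `GRanges`.
#' @export
parseLocation <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed location string: '", x[bad][1L], "'")
  GRanges(vapply(m, `[[`, character(1), 2L),
          IRanges(as.integer(vapply(m, `[[`, character(1), 3L)),
                  as.integer(vapply(m, `[[`, character(1), 4L))))
}

#' Format genomic ranges as browser-style location strings
#' @param gr A `GRanges`.
#' @return Character vector `"contig:start-end"` (1-based inclusive).
#' @export
formatLocation <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr), end(gr))
}

# reserved FASTA name prefix that marks decoy contigs on disk
.DECOY_PREFIX <- "decoy|"

#' Serialize a composite reference to FASTA
#'
#' Decoy contigs are written with a reserved `decoy|` id prefix so that
#' downstream stages (and other tools) can recognize them without a side
#' table.
#'
#' @param ref A [CompositeReference-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeComposite <- function(ref, path) {
  stopifnot(is(ref, "CompositeReference"))
  s <- ref@sequences
  names(s)[ref@isDecoy] <- paste0(.DECOY_PREFIX, names(s)[ref@isDecoy])
  writeXStringSet(s, path)
  invisible(path)
}

#' Read a composite reference from FASTA
#'
#' Contigs whose ids carry the reserved `decoy|` prefix are flagged as
#' decoys (the prefix is stripped); all others are genome contigs.
#'
#' @param path FASTA path written by [writeComposite()] (or any FASTA; a
#'   file without `decoy|` ids is read as a plain genome).
#' @return A [CompositeReference-class].
#' @export
readComposite <- function(path) {
  s <- readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))   # drop FASTA descriptions
  dec <- startsWith(names(s), .DECOY_PREFIX)
  names(s)[dec] <- substring(names(s)[dec], nchar(.DECOY_PREFIX) + 1L)
  new("CompositeReference",
      sequences = c(s[!dec], s[dec]),
      isDecoy = c(rep(FALSE, sum(!dec)), rep(TRUE, sum(dec))))
}
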