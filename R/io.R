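# Plain-text interchange: hits as BED6, reads as FASTQ.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export alignment hits as BED6
#'
#' Columns: contig, 0-based start, end, read id, score 0, strand.
#'
#' @param hits `GRanges` with a `read_id` metadata column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportHitsBED <- function(hits, path) {
  if (length(hits) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(as.character(seqnames(hits)), start(hits) - 1L,
                   end(hits), mcols(hits)$read_id %||% ".", 0L,
                   as.character(strand(hits)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import alignment hits from BED6
#'
#' @param path BED path written by [exportHitsBED()].
#' @return `GRanges` with a `read_id` metadata column.
#' @export
importHitsBED <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) return(.emptyHits(0L))
  f <- strsplit(lines, "\t")
  gr <- GRanges(
    vapply(f, `[[`, character(1), 1L),
    IRanges(as.integer(vapply(f, `[[`, character(1), 2L)) + 1L,
            as.integer(vapply(f, `[[`, character(1), 3L))),
    vapply(f, `[[`, character(1), 6L))
  mcols(gr)$read_id <- vapply(f, `[[`, character(1), 4L)
  gr
}

#' Read single-end reads from FASTQ
#'
#' Base qualities are read but ignored: the mapper matches bases exactly.
#'
#' @param path FASTQ path (gzip transparently supported).
#' @return Named `DNAStringSet`.
#' @export
readReadsFASTQ <- function(path) {
  readDNAStringSet(path, format = "fastq", with.qualities = FALSE)
}

#' Write reads to FASTQ
#'
#' Simulated reads are error-free and carry uniform placeholder qualities.
#'
#' @param reads Named `DNAStringSet`.
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
writeReadsFASTQ <- function(reads, path) {
  quals <- BStringSet(vapply(width(reads),
                             function(w) strrep("I", w), character(1)))
  names(quals) <- names(reads)
  writeXStringSet(reads, path, format = "fastq", qualities = quals,
                  compress = endsWith(path, ".gz"))
  invisible(path)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
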