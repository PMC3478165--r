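# RPKM quantification over mappable effective length, coverage fractions,
# composite/plain ratios and threshold summaries.

#' Count uniqueome-filtered reads per pseudogene
#'
#' A hit is assigned to a pseudogene iff its (leftmost) start position lies
#' within the pseudogene interval; counting is unstranded (random-primed
#' libraries carry no strand information).  Each hit is assigned to at most
#' one feature: on overlap, the smallest interval wins, then the
#' lexicographically smallest id.  Overlapping annotations trigger a warning.
#'
#' @param hits `GRanges` of uniqueome-filtered alignment hits.
#' @param annotations `GRanges` of processed pseudogenes with an `id`
#'   metadata column (see [loadAnnotations()], [filterProcessed()]).
#' @return Named integer vector of read counts, one entry per annotation
#'   (zeros included), in annotation order.
#' @export
countReadsPerFeature <- function(hits, annotations) {
  ids <- mcols(annotations)$id
  counts <- stats::setNames(integer(length(annotations)), ids)
  if (length(annotations) == 0L || length(hits) == 0L) return(counts)
  annU <- annotations
  strand(annU) <- "*"
  if (any(GenomicRanges::countOverlaps(annU, annU) > 1L))
    warning("overlapping pseudogene annotations; ties broken by smallest ",
            "interval, then id")
  pts <- GRanges(seqnames(hits), IRanges(start(hits), width = 1L), "*")
  # hits on decoy contigs share no seqlevels with genome annotations; that
  # is expected, not a mismatch worth warning about
  ov <- suppressWarnings(findOverlaps(pts, annU, ignore.strand = TRUE))
  if (length(ov) == 0L) return(counts)
  df <- data.frame(hit = S4Vectors::queryHits(ov),
                   feat = S4Vectors::subjectHits(ov))
  df$w <- BiocGenerics::width(annU)[df$feat]
  df$id <- ids[df$feat]
  df <- df[order(df$hit, df$w, df$id), ]
  df <- df[!duplicated(df$hit), ]
  tab <- table(df$id)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Effective (uniquely mappable) length of a feature
#'
#' The number of uniqueome start positions that fall inside the feature
#' interval; this is the exon length used as the RPKM denominator length,
#' processed pseudogenes being single-exon.
#'
#' @param feature A length-1 `GRanges`.
#' @param track A [MappabilityTrack-class].
#' @return Integer count of unique starts within the feature.
#' @export
effectiveLength <- function(feature, track) {
  stopifnot(is(track, "MappabilityTrack"), length(feature) == 1L)
  ctg <- as.character(seqnames(feature))
  st <- uniqueStarts(track, ctg)
  sum(st >= start(feature) & st <= end(feature))
}

#' Reads per kilobase of mappable exon per million mapped reads
#'
#' `rpkm = count / (effLength / 1000) / (totalMapped / 1e6)`.  A zero count
#' gives 0 regardless of length; a positive count over a zero effective
#' length is an inconsistency (a counted read implies at least one unique
#' start inside the feature) and raises an error.
#'
#' @param count Read count(s) assigned to the feature.
#' @param effLength Effective (uniquely mappable) length(s) in bp.
#' @param totalMapped Library-size denominator: total reads mapped for the
#'   sample (must be positive).
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count, effLength, totalMapped) {
  if (any(totalMapped <= 0)) stop("totalMapped must be positive")
  n <- max(length(count), length(effLength))
  count <- rep_len(count, n); effLength <- rep_len(effLength, n)
  if (any(count > 0 & effLength == 0))
    stop("positive read count over zero effective length: a counted read ",
         "implies at least one unique start within the feature")
  out <- numeric(n)
  pos <- count > 0
  out[pos] <- count[pos] / (effLength[pos] / 1000) / (totalMapped / 1e6)
  out
}

#' Fraction of a feature covered by retained reads
#'
#' Reads occupy `[start, start + L)`; the coverage fraction is the number of
#' feature bases covered by at least one retained read divided by the
#' feature length.
#'
#' @param hits `GRanges` of hits assigned to the feature (width `L`).
#' @param feature A length-1 `GRanges`.
#' @return Numeric in `[0, 1]`.
#' @export
coverageFraction <- function(hits, feature) {
  stopifnot(length(feature) == 1L)
  if (length(hits) == 0L) return(0)
  hits <- hits[as.character(seqnames(hits)) == as.character(seqnames(feature))]
  if (length(hits) == 0L) return(0)
  covered <- IRanges::intersect(
    reduce(IRanges(start(hits), end(hits))),
    IRanges(start(feature), end(feature)))
  sum(BiocGenerics::width(covered)) / BiocGenerics::width(feature)
}

#' Composite-to-plain read-count ratio
#'
#' Ratio of reads uniquely mapped to a region class in the composite
#' reference over the count in the unaltered genome; decoy absorption of
#' parent-mRNA reads makes this below 1 for pseudogenes.
#'
#' @param countComposite,countPlain Integer counts.
#' @return Ratio rounded to 2 decimals; `NA` when `countPlain` is zero.
#' @export
compositeRatio <- function(countComposite, countPlain) {
  ifelse(countPlain == 0, NA_real_, round(countComposite / countPlain, 2))
}

#' Percentage of expression values exceeding thresholds
#'
#' @param values Numeric expression values (RPKM/FPKM); must be non-empty.
#' @param thresholds Numeric thresholds.
#' @return Named numeric vector: for each threshold `t`, `100 * |{v > t}| / N`.
#' @export
thresholdSummary <- function(values, thresholds = c(1, 2, 5, 10, 15)) {
  if (length(values) == 0L) stop("empty value set")
  stats::setNames(
    vapply(thresholds, function(t) 100 * mean(values > t), numeric(1)),
    paste0("% > ", thresholds))
}

#' Quantify pseudogene expression in one sample
#'
#' Combines read counting, effective length, RPKM and coverage fraction for
#' every processed pseudogene.  `hits` must already be uniqueome-filtered
#' (see [intersectHits()]).
#'
#' @param hits Filtered `GRanges` of hits.
#' @param annotations Processed pseudogene `GRanges` (`id`, `parent` mcols).
#' @param track The [MappabilityTrack-class] used for filtering.
#' @param totalMapped RPKM library-size denominator for the sample.
#' @param sample Sample label.
#' @return A `data.frame` with one row per pseudogene: `pseudogene_id`,
#'   `parent`, `location`, `sample`, `read_count`, `effective_length`,
#'   `rpkm`, `coverage`.
#' @export
quantifySample <- function(hits, annotations, track, totalMapped,
                           sample = "sample") {
  counts <- countReadsPerFeature(hits, annotations)
  ids <- mcols(annotations)$id
  eff <- vapply(seq_along(annotations), function(i)
    effectiveLength(annotations[i], track), integer(1))
  pts <- if (length(hits))
    GRanges(seqnames(hits), IRanges(start(hits), width = 1L), "*")
  else GRanges()
  cov <- vapply(seq_along(annotations), function(i) {
    if (counts[i] == 0L) return(0)
    sel <- S4Vectors::queryHits(suppressWarnings(
      findOverlaps(pts, annotations[i], ignore.strand = TRUE)))
    coverageFraction(hits[sel], annotations[i])
  }, numeric(1))
  data.frame(
    pseudogene_id = ids,
    parent = mcols(annotations)$parent,
    location = formatLocation(annotations),
    sample = rep_len(sample, length(ids)),
    read_count = as.integer(counts),
    effective_length = eff,
    rpkm = rpkm(as.integer(counts), eff, totalMapped),
    coverage = cov,
    stringsAsFactors = FALSE)
}

#' Assemble per-sample quantifications into a SummarizedExperiment
#'
#' @param records List of per-sample `data.frame`s from [quantifySample()],
#'   one per sample, covering the same pseudogenes.
#' @param annotations The processed pseudogene `GRanges` (row ranges).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assays
#'   `counts`, `rpkm` and `coverage` (pseudogene x sample) and the
#'   annotations as row ranges.
#' @export
expressionSE <- function(records, annotations) {
  ids <- mcols(annotations)$id
  samples <- names(records) %||%
    vapply(records, function(r) r$sample[1L], character(1))
  asMat <- function(col) {
    m <- vapply(records, function(r) r[[col]][match(ids, r$pseudogene_id)],
                numeric(length(ids)))
    matrix(m, nrow = length(ids), ncol = length(records),
           dimnames = list(ids, samples))
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = asMat("read_count"), rpkm = asMat("rpkm"),
                  coverage = asMat("coverage")),
    rowRanges = stats::setNames(annotations, ids),
    colData = S4Vectors::DataFrame(sample = samples, row.names = samples))
}
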