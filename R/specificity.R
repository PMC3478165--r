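# Jensen-Shannon tissue-specificity scoring of RPKM profiles.

.entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence (base 2)
#'
#' `JSD(p, q) = H((p + q)/2) - (H(p) + H(q))/2` with Shannon entropy `H`
#' in bits, so the divergence is bounded by 1; `0 * log 0` is taken as 0.
#'
#' @param p,q Probability vectors of equal length (non-negative, each
#'   summing to 1 within `1e-9`).
#' @return The divergence, a number in `[0, 1]`.
#' @export
jsDivergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("p and q must each sum to 1 (within 1e-9)")
  m <- (p + q) / 2
  d <- .entropyBits(m) - (.entropyBits(p) + .entropyBits(q)) / 2
  min(max(d, 0), 1)   # clamp floating-point residue
}

#' Tissue-specificity score of an expression profile
#'
#' A pseudocount `eps` is added to every RPKM value before normalization to
#' avoid zero probabilities.  The score is
#' `max_t (1 - sqrt(JSD(p, e_t)))` over single-tissue unit profiles `e_t`
#' (the square root of the divergence is the metric JS distance), so a
#' profile expressed in exactly one tissue scores 1 and a uniform profile
#' over 16 tissues scores about 0.090.  Ties go to the first tissue in
#' profile order.
#'
#' @param rpkm Numeric vector of RPKM values across tissues (length >= 2),
#'   optionally named by tissue.
#' @param tissues Tissue names (defaults to `names(rpkm)` or `tissue<i>`).
#' @param eps Pseudocount added to every value (default `1e-10`).
#' @return A list with `score` (in `[0, 1]`), `tissue` (argmax tissue) and
#'   `unexpressed` (`TRUE` when the whole profile is zero, in which case the
#'   score is that of the pure-pseudocount uniform profile).
#' @export
specificityScore <- function(rpkm, tissues = NULL, eps = 1e-10) {
  if (length(rpkm) < 2L) stop("need at least 2 tissues")
  if (any(rpkm < 0)) stop("RPKM values must be non-negative")
  if (is.null(tissues)) tissues <- names(rpkm)
  if (is.null(tissues)) tissues <- paste0("tissue", seq_along(rpkm))
  Tn <- length(rpkm)
  p <- (rpkm + eps) / sum(rpkm + eps)
  scores <- vapply(seq_len(Tn), function(t) {
    e <- numeric(Tn); e[t] <- 1
    1 - sqrt(jsDivergence(p, e))
  }, numeric(1))
  best <- which.max(scores)   # first index on ties
  list(score = scores[best], tissue = tissues[best],
       unexpressed = all(rpkm == 0))
}

#' Specificity table for an RPKM matrix
#'
#' @param mat Numeric matrix of RPKM values, pseudogenes in rows, tissues in
#'   columns (or a `SummarizedExperiment` with an `rpkm` assay).
#' @param eps Pseudocount, see [specificityScore()].
#' @return A `data.frame` with columns `pseudogene_id`, `max_tissue`,
#'   `max_rpkm`, `total_rpkm`, `specificity`, `unexpressed`.
#' @export
specificityTable <- function(mat, eps = 1e-10) {
  if (is(mat, "SummarizedExperiment"))
    mat <- SummarizedExperiment::assay(mat, "rpkm")
  if (nrow(mat) == 0L)
    return(data.frame(pseudogene_id = character(0),
                      max_tissue = character(0), max_rpkm = numeric(0),
                      total_rpkm = numeric(0), specificity = numeric(0),
                      unexpressed = logical(0)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("tissue", seq_len(ncol(mat)))
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("feature", seq_len(nrow(mat)))
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    s <- specificityScore(v, colnames(mat), eps = eps)
    data.frame(pseudogene_id = rownames(mat)[i],
               max_tissue = colnames(mat)[which.max(v)],
               max_rpkm = max(v),
               total_rpkm = sum(v),
               specificity = s$score,
               unexpressed = s$unexpressed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Distribution of specificity scores
#'
#' Bins the scores and counts how many exceed each threshold, for
#' histogram-style summaries of how tissue-specific a gene set is.
#'
#' @param scores Numeric specificity scores in `[0, 1]`.
#' @param breaks Histogram bin breaks (default width 0.1 over `[0, 1]`).
#' @param thresholds Thresholds for exceedance counts.
#' @return A list with `histogram` (`data.frame` of `bin`, `count`) and
#'   `above` (named integer vector of counts exceeding each threshold).
#' @export
specificityDistribution <- function(scores, breaks = seq(0, 1, by = 0.1),
                                    thresholds = c(0.5, 0.8)) {
  if (length(scores) == 0L) {
    return(list(histogram = data.frame(bin = character(0),
                                       count = integer(0)),
                above = stats::setNames(integer(length(thresholds)),
                                        paste0("> ", thresholds))))
  }
  h <- graphics::hist(scores, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(
    histogram = data.frame(
      bin = sprintf("(%.1f,%.1f]", utils::head(h$breaks, -1L),
                    h$breaks[-1L]),
      count = h$counts),
    above = stats::setNames(
      vapply(thresholds, function(t) sum(scores > t), integer(1)),
      paste0("> ", thresholds)))
}
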