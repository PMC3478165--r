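# Synthetic genomes, parent genes, planted processed pseudogenes and
# tissue-resolved unstranded read sets with recorded ground truth.
#
# The generator emulates the study design the pipeline targets: multi-exon
# parent genes constitutively expressed in every tissue, processed
# (intronless, retrotransposed) pseudogene copies at 89-95% sequence
# identity to their parent expressed tissue-specifically, and fixed-length
# unstranded reads sampled uniformly within their feature of origin.

#' Simulation configuration
#'
#' Defaults describe the package's standard end-to-end fixture: one 50 kb
#' chromosome, 3 parent genes of 3 x 160 bp exons, 4 processed pseudogenes
#' at identities 0.89/0.92/0.95/1.00 (the 1.00 copy is a built-in negative
#' control: every read from it also matches the parent decoy and is
#' discarded), 16 tissues, 10,000 error-free unstranded 75 bp reads per
#' tissue, parents expressed everywhere and pseudogene j expressed only in
#' tissue j.
#'
#' @slot seed Integer RNG seed; every generator is deterministic given it.
#' @slot nChromosomes,chromLength Genome shape.
#' @slot nGenes,exonsPerGene,exonLength Parent-gene shape (bp).
#' @slot nPseudogenes Number of planted processed pseudogenes.
#' @slot identity Per-pseudogene fraction of bases matching the parent mRNA
#'   (recycled to `nPseudogenes`).
#' @slot tissues Tissue (sample) names.
#' @slot expression Relative-abundance matrix, features x tissues; empty
#'   matrix means "use the default design" (parents 1 everywhere,
#'   pseudogene j weight 3 in tissue j only).
#' @slot nReads Reads per tissue.
#' @slot readLength Read length L in bp.
#' @slot errorRate Per-base sequencing error probability (0 = error-free).
#' @export
setClass("SimulationConfig",
  slots = c(seed = "integer", nChromosomes = "integer",
            chromLength = "integer", nGenes = "integer",
            exonsPerGene = "integer", exonLength = "integer",
            nPseudogenes = "integer", identity = "numeric",
            tissues = "character", expression = "matrix",
            nReads = "integer", readLength = "integer",
            errorRate = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (any(object@identity <= 0) || any(object@identity > 1))
    return("identity must be in (0, 1]")
  if (length(object@expression) && any(object@expression < 0))
    return("expression must be non-negative")
  if (object@chromLength < 1L || object@exonLength < 1L ||
      object@readLength < 1L)
    return("all lengths must be positive")
  if (object@errorRate < 0 || object@errorRate >= 1)
    return("errorRate must be in [0, 1)")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed", object@seed, "\n")
  cat(" ", object@nChromosomes, "chromosome(s) x", object@chromLength, "bp;",
      object@nGenes, "gene(s) x", object@exonsPerGene, "exon(s) x",
      object@exonLength, "bp\n")
  cat(" ", object@nPseudogenes, "pseudogene(s), identity",
      paste(object@identity, collapse = "/"), "\n")
  cat(" ", length(object@tissues), "tissue(s),", object@nReads,
      "reads x", object@readLength, "bp per tissue, error rate",
      object@errorRate, "\n")
})

#' @describeIn SimulationConfig-class Constructor with fixture defaults.
#' @param seed,nChromosomes,chromLength,nGenes,exonsPerGene,exonLength
#'   See slots.
#' @param nPseudogenes,identity,tissues,expression,nReads,readLength,errorRate
#'   See slots.
#' @export
simulationConfig <- function(seed = 1L, nChromosomes = 1L,
                             chromLength = 50000L, nGenes = 3L,
                             exonsPerGene = 3L, exonLength = 160L,
                             nPseudogenes = 4L,
                             identity = c(0.89, 0.92, 0.95, 1.00),
                             tissues = sprintf("tissue%02d", 1:16),
                             expression = matrix(numeric(0), 0, 0),
                             nReads = 10000L, readLength = 75L,
                             errorRate = 0) {
  new("SimulationConfig", seed = as.integer(seed),
      nChromosomes = as.integer(nChromosomes),
      chromLength = as.integer(chromLength), nGenes = as.integer(nGenes),
      exonsPerGene = as.integer(exonsPerGene),
      exonLength = as.integer(exonLength),
      nPseudogenes = as.integer(nPseudogenes),
      identity = rep_len(identity, max(as.integer(nPseudogenes), 1L)),
      tissues = tissues, expression = expression,
      nReads = as.integer(nReads), readLength = as.integer(readLength),
      errorRate = errorRate)
}

.randomDNA <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with planted multi-exon genes and their spliced mRNAs
#'
#' Chromosomes are i.i.d. uniform ACGT.  Genes are laid out left to right
#' with random intron and intergenic gaps, on random strands; mRNAs are
#' produced with [spliceTranscript()].  Deterministic given `config@seed`.
#'
#' @param config A [SimulationConfig-class].
#' @return A list: `genome` (`DNAStringSet`), `exons` (`GRanges` with
#'   `gene_id` mcol), `mrnas` (`DNAStringSet`, one per gene), `occupied`
#'   (`GRanges` of gene footprints, for collision-free pseudogene
#'   placement).
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  genome <- DNAStringSet(vapply(seq_len(config@nChromosomes),
                                function(i) .randomDNA(config@chromLength),
                                character(1)))
  names(genome) <- sprintf("chr%d", seq_len(config@nChromosomes))
  exonList <- list(); mrnaList <- list()
  cursor <- stats::setNames(rep(1L, config@nChromosomes), names(genome))
  if (config@nGenes > 0L) {
    for (g in seq_len(config@nGenes)) {
      chrom <- names(genome)[((g - 1L) %% config@nChromosomes) + 1L]
      gap <- sample(200:500, 1L)
      pos <- cursor[[chrom]] + gap
      st <- integer(config@exonsPerGene)
      for (e in seq_len(config@exonsPerGene)) {
        st[e] <- pos
        pos <- pos + config@exonLength +
          (if (e < config@exonsPerGene) sample(100:300, 1L) else 0L)
      }
      en <- st + config@exonLength - 1L
      if (max(en) > config@chromLength)
        stop("gene g", g, " does not fit in chromosome ", chrom)
      cursor[[chrom]] <- max(en) + 1L
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("gene%d", g)
      ex <- GRanges(chrom, IRanges(st, en), strand, gene_id = gid)
      exonList[[gid]] <- ex
      mrnaList[[gid]] <- spliceTranscript(genome, ex, strand, id = gid)
    }
  }
  exons <- if (length(exonList)) suppressWarnings(do.call(c, unname(exonList)))
           else GRanges()
  mrnas <- if (length(mrnaList)) do.call(c, unname(mrnaList))
           else DNAStringSet()
  occupied <- if (length(exons)) {
    rng <- lapply(unique(mcols(exons)$gene_id), function(g) {
      e <- exons[mcols(exons)$gene_id == g]
      GRanges(seqnames(e)[1L], IRanges(min(start(e)), max(end(e))))
    })
    suppressWarnings(do.call(c, rng))
  } else GRanges()
  list(genome = genome, exons = exons, mrnas = mrnas, occupied = occupied)
}

#' Plant a processed pseudogene into a genome
#'
#' Writes a retrotransposed (intronless) copy of a spliced mRNA at `locus`,
#' substituting bases so the copy has approximately the requested sequence
#' identity to the parent: the number of substitutions is Binomial(length,
#' 1 - identity), positions are drawn without replacement, and each
#' substituted base becomes a uniformly chosen different base.
#'
#' @param genome Named `DNAStringSet`.
#' @param mrna Length-1 `DNAStringSet` (the parent spliced mRNA).
#' @param identity Fraction of matching bases, in `(0, 1]`.
#' @param locus Length-1 `GRanges` of width `length(mrna)`; must not collide
#'   with `occupied`.
#' @param occupied Optional `GRanges` of already-used loci.
#' @param id,parent Identifier and parent-gene name for the annotation.
#' @return A list: `genome` (modified) and `annotation` (`GRanges` with
#'   `id`, `parent`, `klass = "processed"`).
#' @export
plantPseudogene <- function(genome, mrna, identity, locus,
                            occupied = GRanges(), id = "pg1",
                            parent = names(mrna) %||% "gene") {
  stopifnot(length(locus) == 1L, identity > 0, identity <= 1)
  ctg <- as.character(seqnames(locus))
  if (!ctg %in% names(genome)) stop("unknown contig '", ctg, "'")
  len <- length(mrna[[1L]])
  if (BiocGenerics::width(locus) != len)
    stop("locus width must equal mRNA length (", len, ")")
  if (end(locus) > width(genome[ctg]) || start(locus) < 1L)
    stop("locus out of contig bounds")
  if (length(occupied) &&
      length(findOverlaps(locus, occupied, ignore.strand = TRUE)))
    stop("locus collision with an existing feature")
  copy <- strsplit(as.character(mrna[[1L]]), "")[[1L]]
  nsub <- stats::rbinom(1L, len, 1 - identity)
  if (nsub > 0L) {
    at <- sample.int(len, nsub)
    for (p in at)
      copy[p] <- sample(setdiff(c("A", "C", "G", "T"), copy[p]), 1L)
  }
  seqchar <- as.character(genome[[ctg]])
  substr(seqchar, start(locus), end(locus)) <- paste0(copy, collapse = "")
  genome[[ctg]] <- DNAString(seqchar)
  ann <- GRanges(ctg, IRanges(start(locus), end(locus)), "+",
                 id = id, parent = parent, klass = "processed")
  list(genome = genome, annotation = ann)
}

#' Simulate tissue-resolved unstranded read sets
#'
#' Reads are drawn feature-proportionally to the tissue's expression column,
#' start positions uniform within the feature, strand uniform (the library
#' is unstranded), error-free unless `errorRate > 0`.  Parent reads are
#' sampled from the spliced mRNA sequence (splice-aware origin), pseudogene
#' reads from the genomic pseudogene sequence, so `sources` should contain
#' both kinds.  Every read's origin is recorded in the truth table.
#'
#' @param sources Named `DNAStringSet` of feature sequences to sample from.
#' @param expression Numeric matrix, rownames = feature names covering
#'   `sources`, colnames = tissues, of relative abundances per tissue.
#' @param nReads Reads per tissue.
#' @param L Read length; features shorter than `L` are skipped with a
#'   warning.
#' @param seed RNG seed.
#' @param errorRate Per-base substitution error probability.
#' @return A list: `reads` (named list of `DNAStringSet` per tissue) and
#'   `truth` (`data.frame`: `tissue`, `read_id`, `feature`, `start`,
#'   `strand`).
#' @export
simulateReads <- function(sources, expression, nReads, L, seed = 1L,
                          errorRate = 0) {
  set.seed(seed)
  feats <- rownames(expression)
  if (is.null(feats) || !all(feats %in% names(sources)))
    stop("expression rows must name sequences present in 'sources'")
  tooShort <- feats[width(sources)[match(feats, names(sources))] < L]
  if (length(tooShort)) {
    warning("feature(s) shorter than L skipped: ",
            paste(tooShort, collapse = ", "))
    expression[tooShort, ] <- 0
  }
  tissues <- colnames(expression)
  reads <- list(); truthRows <- list()
  srcChar <- as.character(sources)
  for (t in tissues) {
    w <- expression[, t]
    if (nReads == 0L || sum(w) == 0) {
      rs <- DNAStringSet()
      names(rs) <- character(0)
      reads[[t]] <- rs
      next
    }
    origin <- sample(feats, nReads, replace = TRUE, prob = w)
    flen <- nchar(srcChar[origin])
    st <- 1L + floor(stats::runif(nReads) * (flen - L + 1L))
    strand <- sample(c("+", "-"), nReads, replace = TRUE)
    seqs <- substr(srcChar[origin], st, st + L - 1L)
    rc <- strand == "-"
    if (any(rc))
      seqs[rc] <- as.character(reverseComplement(DNAStringSet(seqs[rc])))
    if (errorRate > 0) {
      seqs <- vapply(seqs, function(s) {
        v <- strsplit(s, "")[[1L]]
        err <- which(stats::runif(L) < errorRate)
        for (p in err)
          v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
        paste0(v, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    ids <- sprintf("%s_r%d", t, seq_len(nReads))
    rs <- DNAStringSet(seqs)
    names(rs) <- ids
    reads[[t]] <- rs
    truthRows[[t]] <- data.frame(tissue = t, read_id = ids,
                                 feature = unname(origin), start = st,
                                 strand = strand, stringsAsFactors = FALSE)
  }
  truth <- if (length(truthRows)) do.call(rbind, c(truthRows,
                                                   make.row.names = FALSE))
           else data.frame(tissue = character(0), read_id = character(0),
                           feature = character(0), start = integer(0),
                           strand = character(0))
  list(reads = reads, truth = truth)
}

#' Default expression design for a fixture
#'
#' Parents get weight 1 in every tissue (constitutive); pseudogene `j` gets
#' weight 3 in tissue `j` only (tissue-specific) and 0 elsewhere.
#'
#' @param geneIds,pgIds Feature identifiers.
#' @param tissues Tissue names.
#' @return Numeric matrix, features x tissues.
#' @export
defaultExpression <- function(geneIds, pgIds, tissues) {
  m <- matrix(0, nrow = length(geneIds) + length(pgIds),
              ncol = length(tissues),
              dimnames = list(c(geneIds, pgIds), tissues))
  if (length(geneIds)) m[geneIds, ] <- 1
  for (j in seq_along(pgIds))
    if (j <= length(tissues)) m[pgIds[j], tissues[j]] <- 3
  m
}

#' Build a complete end-to-end fixture
#'
#' Wires the generators together: genome + genes + spliced mRNAs, planted
#' pseudogenes at the configured identities, composite reference, and
#' tissue-resolved read sets with ground truth.  With `dir` set, all inputs
#' are written as plain-text files (FASTA/BED/FASTQ/TSV) plus a JSON
#' manifest.
#'
#' @param config A [SimulationConfig-class].
#' @param dir Optional output directory.
#' @return A list: `genome`, `exons`, `mrnas`, `annotations`, `composite`,
#'   `expression`, `reads`, `truth`, `config`, and (with `dir`) `paths`.
#' @export
endToEndFixture <- function(config = simulationConfig(), dir = NULL) {
  sim <- simulateGenome(config)
  genome <- sim$genome
  occupied <- sim$occupied
  anns <- list()
  if (config@nPseudogenes > 0L) {
    if (config@nGenes == 0L)
      stop("pseudogenes need at least one parent gene")
    for (j in seq_len(config@nPseudogenes)) {
      parent <- sprintf("gene%d", ((j - 1L) %% config@nGenes) + 1L)
      mrna <- sim$mrnas[parent]
      len <- width(mrna)
      chrom <- names(genome)[((j - 1L) %% length(genome)) + 1L]
      onChrom <- occupied[as.character(seqnames(occupied)) == chrom]
      base <- if (length(onChrom)) max(end(onChrom)) else 0L
      st <- base + sample(200:500, 1L)
      if (st + len - 1L > width(genome[chrom]))
        stop("pseudogene pg", j, " does not fit in chromosome ", chrom)
      locus <- GRanges(chrom, IRanges(st, width = len))
      planted <- plantPseudogene(genome, mrna, config@identity[j], locus,
                                 occupied = occupied,
                                 id = sprintf("pg%d", j), parent = parent)
      genome <- planted$genome
      anns[[j]] <- planted$annotation
      occupied <- suppressWarnings(c(occupied, locus))
    }
  }
  annotations <- if (length(anns)) suppressWarnings(do.call(c, anns))
                 else {
                   gr <- GRanges()
                   mcols(gr) <- S4Vectors::DataFrame(id = character(0),
                                                     parent = character(0),
                                                     klass = character(0))
                   gr
                 }
  composite <- buildComposite(genome, sim$mrnas)
  expr <- if (length(config@expression)) config@expression
          else defaultExpression(names(sim$mrnas), mcols(annotations)$id,
                                 config@tissues)
  # pseudogene reads come from the (mutated) genomic copy
  pgSeq <- if (length(annotations)) {
    s <- DNAStringSet(vapply(seq_along(annotations), function(i) {
      as.character(subseq(genome[[as.character(seqnames(annotations)[i])]],
                          start(annotations)[i], end(annotations)[i]))
    }, character(1)))
    names(s) <- mcols(annotations)$id
    s
  } else DNAStringSet()
  sources <- c(sim$mrnas, pgSeq)
  rd <- simulateReads(sources, expr, config@nReads, config@readLength,
                      seed = config@seed + 1L, errorRate = config@errorRate)
  out <- list(genome = genome, exons = sim$exons, mrnas = sim$mrnas,
              annotations = annotations, composite = composite,
              expression = expr, reads = rd$reads, truth = rd$truth,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(
      genome = file.path(dir, "genome.fa"),
      transcripts = file.path(dir, "transcripts.fa"),
      composite = file.path(dir, "composite.fa"),
      annotations = file.path(dir, "pseudogenes.bed"),
      truth = file.path(dir, "truth.tsv"),
      manifest = file.path(dir, "manifest.json"))
    writeXStringSet(genome, p$genome)
    writeXStringSet(sim$mrnas, p$transcripts)
    writeComposite(composite, p$composite)
    writeAnnotations(annotations, p$annotations)
    .writeTSV(rd$truth, p$truth)
    p$reads <- stats::setNames(
      file.path(dir, sprintf("%s.fastq", config@tissues)), config@tissues)
    for (t in config@tissues) writeReadsFASTQ(rd$reads[[t]], p$reads[[t]])
    manifest <- list(
      seed = config@seed, read_length = config@readLength,
      n_reads_per_tissue = config@nReads, tissues = config@tissues,
      identity = config@identity, error_rate = config@errorRate,
      pseudogenes = as.list(stats::setNames(mcols(annotations)$parent,
                                            mcols(annotations)$id)),
      files = lapply(p[names(p) != "reads"], basename))
    jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
    out$paths <- p
  }
  out
}
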