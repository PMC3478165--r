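---
title: "Methods: detecting transcribed processed pseudogenes with pseudoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting transcribed processed pseudogenes with pseudoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoquant)
library(Biostrings)
library(GenomicRanges)
```

## The problem

Processed pseudogenes are retrotransposed, intron-less copies of mRNAs.
Because a processed pseudogene is nearly identical to the spliced transcript
of its parent gene, a short RNA-seq read drawn from the abundantly expressed
*parent* will often align perfectly inside the pseudogene locus. Naive
alignment therefore reports spurious "pseudogene expression" wherever the
parent is transcribed. `pseudoquant` implements a conservative pipeline that
only credits a pseudogene with reads that could not have come from the
parent transcript, then quantifies and scores the tissue distribution of the
survivors.

The pipeline has four stages, each exposed as ordinary R functions and as a
command-line wrapper (`inst/scripts/pseudoquant.R`):

1. **Composite reference** (`buildComposite`): the genome plus one decoy
   contig per parent mRNA (the spliced exon sequence). A read that matches
   both a pseudogene locus and the parent decoy now has two placements.
2. **Exact unique mapping** (`buildIndex`, `mapUnique`): reads are placed by
   exact, gapless, both-strand matching; only reads with *exactly one*
   placement in the whole composite are retained. Parent-derived reads that
   also fit the pseudogene are absorbed by the decoy and discarded as
   multi-mapped.
3. **Extended uniqueome** (`computeUniqueStarts`, `intersectHits`): retained
   hits must additionally start at a position whose L-mer window is unique
   in the reference even allowing up to `m` mismatches against any other
   window on either strand. This guards against near-identical paralogues
   that exact matching alone cannot separate.
4. **Quantification and specificity** (`quantifySample`, `expressionSE`,
   `specificityTable`): RPKM over the *mappable* length of each pseudogene,
   and a Jensen–Shannon tissue-specificity score of the resulting profile.

## Mapping model

A read of length $L$ maps at position $(c, s, \sigma)$ iff it equals the
substring of contig $c$ starting at $s$ (1-based) on strand $\sigma$ with
zero mismatches. Reads containing `N` never align. A biological palindrome
(a read equal to its own reverse complement) that occurs once in the genome
produces **two** placements — one per strand — and is therefore discarded by
the single-placement rule. This is deliberate: strand identity of such a
read is undecidable, and the conservative choice is exclusion.

```{r palindrome}
idx <- buildIndex(buildComposite(DNAStringSet(c(chr1 = "TTTGTACTTTAAACC"))), 4L)
mapRead(idx, "GTAC")   # two hits at one locus -> dropped by mapUnique
```

## The extended uniqueome

A genome start $s$ on contig $c$ is *uniquely mappable* iff no other window
of length $L$ anywhere in the composite reference — either strand, decoys
included — lies within Hamming distance $m$ of the window at $(c, s, +)$.
Only the forward self-match is exempt; a reverse-strand self-match at the
same start (a revcomp-palindromic window) counts as a second occurrence and
disqualifies the position, mirroring the read-level palindrome rule.
Windows containing `N` are never occurrences and never uniquely mappable.

The production implementation is a pigeonhole seed filter in C++: any two
windows within Hamming distance $m$ must agree exactly on at least one of
$m + 1$ disjoint seeds of length $\lfloor L/(m+1) \rfloor$, so candidate
pairs are generated by hashing each seed slice and verified by direct
Hamming comparison. An independent all-pairs oracle in plain R
(`bruteForceUniqueStarts`) is used by the test-suite to validate the fast
path across $L$, $m$, decoys and `N` content.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `L` | 75 | bp | read length; windows and reads share one length so "uniquely mappable" and "uniquely mapped" refer to the same object |
| `m` | 4 | mismatches | tolerance for near-paralogues: ~5% divergence over 75 bp; larger `m` shrinks the uniqueome and reduces sensitivity |
| `eps` | 1e-10 | RPKM | pseudocount added before normalising a profile, small enough not to perturb any expressed profile at 3-decimal reporting |
| `rpkmDenominator` | `pre_uniqueome` | reads | library size = reads uniquely mapped to the composite before uniqueome filtering; configurable to `post_uniqueome` |

## Quantification

For pseudogene $g$ in sample $t$ with $k$ retained reads, effective
(uniquely mappable) length $\ell$ — the number of uniqueome starts inside
the annotation interval — and library size $N$:

$$\mathrm{RPKM}(g,t) = \frac{k}{(\ell/1000)\,(N/10^6)}.$$

A zero count yields RPKM 0 regardless of $\ell$; a positive count over
$\ell = 0$ is impossible by construction and raises an error. The
composite-to-plain ratio (`compositeRatio`) — pseudogene-region reads
retained against the composite over the count against the unaltered genome —
measures how much apparent pseudogene signal the decoys absorb.

## Tissue specificity

Profiles are compared with the base-2 Jensen–Shannon divergence
$\mathrm{JSD}(p, q) = H\!\left(\tfrac{p+q}{2}\right) - \tfrac{H(p)+H(q)}{2}
\in [0, 1]$. After adding `eps` and normalising the RPKM profile $p$, the
specificity is

$$S(p) = \max_t \left(1 - \sqrt{\mathrm{JSD}(p, e_t)}\right),$$

the complement of the metric JS *distance* to the nearest single-tissue
corner $e_t$ of the simplex.

```{r anchors}
round(specificityScore(c(9.7, rep(0, 15)))$score, 3)  # one tissue of 16 -> 1.000
round(specificityScore(rep(1, 16))$score, 3)          # uniform          -> 0.090
round(specificityScore(c(2, 2, rep(0, 14)))$score, 3) # two tissues      -> 0.442
```

## Synthetic data generator

Since ground truth is unknowable for real tissue panels, validation uses a
generator (`simulateGenome`, `plantPseudogene`, `simulateReads`,
`endToEndFixture`) that plants pseudogenes of chosen sequence identity and
simulates error-free reads from a known expression design. The default
fixture — one 50 kb chromosome, 3 parent genes of 3 × 160 bp exons, 4
pseudogenes at identities 0.89/0.92/0.95/1.00, 16 tissues with 10,000 reads
each, parents expressed everywhere and pseudogene $j$ expressed only in
tissue $j$ — is sized so the full pipeline runs in seconds while still
exercising decoy absorption, uniqueome filtering and specificity scoring.

What the fixture tests **does** show: hard-zero false positives from
parent-only tissues, recovery of planted single-tissue expression with
specificity 1.000, monotone decrease of read survival as identity
approaches 1, and complete invisibility of a perfect (identity 1.0) copy.
What it does **not** show: behaviour under sequencing error, indels,
fragment-length effects, or genome-scale repeat structure — exact matching
of error-free reads is the model, not an approximation of a noisy aligner.

## Limitations

* Exact gapless matching discards any read with a sequencing error inside a
  diagnostic position; real-data sensitivity is therefore a lower bound.
* The uniqueome is computed against the composite reference only; unplaced
  haplotypes or unannotated duplications can inflate apparent uniqueness.
* RPKM with a pre-uniqueome library size slightly deflates values relative
  to a post-filter denominator; both are available and the choice is
  recorded in the pipeline's `config_used.yaml`.
* Specificity is computed on whatever samples are provided; with few
  tissues the floor of the score rises (a uniform profile over 2 tissues
  scores far above 0.090).
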