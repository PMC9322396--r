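---
title: "Full-length homology-based prediction of NB-LRR resistance genes: methods and design"
author: "hrpredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-length homology-based prediction of NB-LRR resistance genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrpredict)
```

## The problem

Plant disease-resistance genes of the NB-LRR (NLR) family sit in rapidly
evolving tandem clusters, are weakly expressed, and resemble transposable
elements closely enough that repeat masking frequently removes them before
automated gene prediction ever sees them. As a result, proteome-level domain
scans (a protein motif/domain-based search, PDS) systematically undercount the
NB-LRR repertoire and inherit every structural mistake of the input
annotation: genes missing entirely, two adjacent genes fused into one model,
or one gene split into two fragments.

`hrpredict` implements a two-pass remedy. Pass 1 runs a PDS over the existing
proteome to collect the full-length NB-LRR proteins the annotation *did*
capture; short motifs discovered in their NB domains rescue borderline
candidates that the domain scan alone misses. Pass 2 then uses each clean
full-length protein as a query for splice-aware homology prediction directly
against the genome assembly, re-modelling every locus from sequence rather
than trusting the annotation. Filters remove implausibly long models and
resolve same-strand overlaps, and every surviving model is re-annotated,
classified (CNL/TNL/RNL/NL or a partial label) and flagged as a pseudogene
when its CDS contains internal stops or a frameshift.

## Pass 1: domain scan and architecture classes

Domains are detected with three detectors:

* **PSSM profiles** for NB, TIR, the Rx-type N-terminal coiled-coil and RPW8.
  The profiles are position-specific scoring matrices (log-odds in bits
  against a uniform background) built from small synthetic seed alignments
  shipped with the package; the accession labels (NB: PF00931, CC/Rx-N:
  PF18052, TIR: PF01582) record which Pfam families they stand in for. They
  are self-contained substitutes for an external profile-HMM scanner, not
  calibrated Pfam models. Each profile's detection threshold is 35% of its
  maximum attainable score — calibrated once on the synthetic fixtures so
  that domain copies down to roughly 70% identity still score while random
  sequence essentially never does (empirical false-positive rate < 1% per
  200-residue protein).
* **An LRR repeat detector** scoring the degenerate consensus `LxxLxLxx`
  (L-type = L/I/V/F at positions 1, 4, 6, 8) in tiled 8-residue frames; at
  least 3 of the 4 consensus positions per frame and at least 3 consecutive
  frames are required.
* **A coiled-coil heuristic**: a 21-residue sliding window scored by the
  geometric mean of a bundled heptad propensity table over the best of the
  seven registers, mapped to a probability by a logistic curve. The logistic
  midpoint (geometric-mean propensity 1.5) was calibrated on synthetic
  fixtures to keep the false-positive rate on random protein near 0.5% while
  canonical heptad repeats score > 0.85. Coiled-coil evidence that lies
  entirely inside another domain's hit is discarded during architecture
  assembly: helical stretches inside the NB or TIR folds are not independent
  N-terminal domains.

Architecture classification is a pure function of the ordered domain tokens.
A protein is full-length when NB and LRR are both present with NB upstream;
the earliest of CC/TIR/RPW8 before the NB selects CNL, TNL or RNL, and NB-LRR
without a detected N-terminal domain is reported as the separate full-length
class `NL` (the input sets of interest require only NB and LRR). Everything
else is a partial architecture labelled by its ordered tokens (`NB`,
`TIR-NB`, `LRR`, ...). The complete truth table over all ordered subsets of
the five kinds is committed to the test suite and asserted exactly.

## Motif discovery and rescue

NB-domain subsequences of the pass-1 full-length proteins are decomposed into
up to 19 motifs of width 4–7 by ZOOPS (zero-or-one occurrence per sequence)
expectation-maximisation with sequential erasure: for each motif, EM runs at
every width, the width with the best BIC-penalised log-likelihood ratio wins
(each column pays \(\tfrac{1}{2}\,19\,\log n_\text{sites}\); the raw ratio
grows with every extra column because even a random flank fits noise, so
unpenalised selection overshoots the true width and can frame-shift the
motif), the
motif's sites are masked, and discovery repeats. Initialisation is from the
most frequent exact w-mer (ties broken towards the rarest composition under
the background, then lexicographically), which makes discovery fully
deterministic; convergence is declared when the log-likelihood-ratio
improvement falls below 1e-4 or after 50 iterations, with per-cell
pseudocounts of 0.01 x background. The background is the order-0 residue
frequency of the input set, keeping the module self-contained.

Motif scanning reports an exact p-value for every window: per-position
log-odds are rescaled to integers at 1/100 bit and the null score
distribution is built by staged convolution, so the p-value is an exact tail
probability rather than an approximation. Per-protein significance combines
the best p-value of each motif through the product-of-p-values (QFAST)
formula \(q\sum_{k=0}^{n-1}(-\ln q)^k/k!\), scaled by the proteome size into
an E-value. A protein missed by pass 1 is *rescued* when at least 3 distinct
motifs reach p < 1e-4 and the combined E-value is at most 10 (both
configurable). Rescued proteins are carried as partial candidates with their
own provenance; they become pass-2 queries only if their pass-1 architecture
is full-length (configurable via `rescue_as_query`), because a protein
without full domain evidence is not a reliable template for full-length gene
structure.

## Pass 2: splice-aware homology prediction

Each clean full-length pass-1 protein is aligned against both strands of the
genome:

1. **Seeding** — exact amino-acid 4-mer matches against all six translated
   frames, extended without gaps under BLOSUM62 with X-drop 20; HSPs below
   score 50 are discarded.
2. **Chaining** — maximum-score colinear chains (strictly increasing in both
   query and subject, subject gaps at most 10 kb, footprint at most the 20-kb
   span limit) by dynamic programming, extracted best-first.
3. **Spliced alignment** — codon-aware local dynamic programming of the
   protein against the genomic window around each chained locus. Introns are
   allowed only between codons (phase 0) at canonical `GT..AG` boundaries
   with lengths 40–2000 bp; gaps cost 11 to open and 1 to extend, an intron a
   flat 10 bits. A stop codon immediately following the alignment is included
   in the CDS, as annotations do.
4. **E-values** — \(E = K m n e^{-\lambda S}\) with the bundled ungapped
   BLOSUM62 Karlin parameters (\(\lambda = 0.3176\), \(K = 0.134\)), `m` the
   query length and `n` the genome length counted on both strands (keeping E
   comparable across assemblies). Candidates with E > 0.01 are removed.

Because NB-LRR genes sit in near-identical tandem arrays, a single maximal
alignment per locus is not enough: the aligner would model only the best
copy, or worse, bridge two copies through a spurious "intron" across the
intergenic spacer. Three design choices address this, each of which we
validated on the synthetic benchmark:

* **Iterated carving.** Within each locus window the aligner runs repeatedly:
  align, accept the best model, then recurse into the flanking sub-windows
  while they still contain HSP evidence. Every member of a tandem cluster is
  modelled, not only the best copy. Loci are carved with their best-scoring
  query; evidence not covered afterwards (a gene with no homology to that
  query) is re-carved with its own best query, and the next-best queries
  additionally re-align inside each model window so the overlap filter can
  choose the longest encoded protein among queries.
* **A realistic intron cost.** At the naive 2-bit cost an intron is cheaper
  than two conservative mismatches, and the optimal path skips
  mutation-dense stretches — or hops between paralogs — through fake
  mini-introns (we observed 18-exon chimeras). The default 10-bit flat cost
  restores sensible behaviour; it remains configurable (`intron_cost`).
* **Bridging-model removal and separate intron caps.** The aligner's intron
  cap (`max_intron_align`, 2 kb — the upper bound of plant NB-LRR intron
  lengths modelled here) is separate from the chaining gap limit
  (`max_intron`, 10 kb). Any model one of whose introns still covers 300 or
  more coding bases of another candidate is dropped before overlap
  resolution: genuine introns do not contain neighbouring genes.

Queries whose annotated CDS is pseudogenic (internal stops or a frameshift)
are excluded from pass 2: a defectively fused annotation protein literally
contains two genes and would seed chimeric two-gene models.

## Filters, re-annotation and reconciliation

Surviving candidates pass the published filters in this order: first the span
rule (models with a genomic footprint *strictly greater* than 20 kb are
dropped — the strict reading of "longer than 20 kb"), then strand-aware
single-linkage overlap clustering in which only the model encoding the
longest protein survives per cluster (ties: higher alignment score, then
smaller start). Overlaps on opposite strands are never merged. The span
filter is applied before overlap clustering, following the order of the
published procedure; the reverse order would differ only when an overlong
model overlaps a kept one, and such models are removed either way.

Every surviving model is translated, re-scanned with the full domain battery,
classified, and flagged `pseudogene` when its CDS carries internal stops or a
frameshift; models with no detectable R-protein domain at all are discarded.
Pseudogenes with complete architecture are retained and flagged, never
dropped.

Finally, pass-1 full-length loci are reconciled by precedence: where a pass-2
model overlaps the locus, the re-modelled gene stands (this is what allows a
fused annotation to become two models); a pass-1 locus with no surviving
pass-2 model is appended unchanged with provenance `PDS`, so no pass-1 locus
is ever lost — the package checks this conservation property on every run
(`check_conservation()`). Rescued proteins whose loci are not covered are
appended with provenance `motif-rescue`. Each output gene therefore carries
exactly one provenance: `PDS`, `motif-rescue` or `homology-pass`.

## The synthetic benchmark

`generate_genome_with_truth()` emulates the genomic situations the method is
designed to repair, with known truth:

* R-genes assembled from the bundled consensus blocks (a 200-aa NB block —
  the average NB domain length — plus CC/TIR/RPW8 and twelve LRR units) with
  point substitutions to a target identity; the generator closes the loop
  through the domain scanner, guaranteeing each protein classifies as its
  intended class. Defaults implant genes at 85–95% identity to the consensus
  (pairwise ~72–90%, a realistic paralog spread), in tandem clusters of 1–5
  genes spaced 1–5 kb apart, with 1–3 phase-0 `GT..AG` introns of 40–2000 bp.
* Transposon-like decoy ORFs with a composition depleted in leucine-type and
  coiled-coil core residues, implanted in the genome *and* listed in the
  automated annotation — they must never classify full-length.
* A deliberately defective annotation derived from the truth by logged
  defects only: omitted models, two adjacent genes fused into one, one gene
  split into two, and weakened genes whose NB region is mutated until it
  scores just below the profile threshold while the short conserved anchors
  (P-loop, kinase-2, GLPL) stay intact — the motif-rescue target.
* Background DNA is i.i.d. uniform ACGT (optional GC bias). Generation is
  bit-identical for identical seeds.

What the generator does *not* emulate: real intergenic sequence composition,
transposon taxonomy, alternative splicing, non-canonical splice sites,
assembly errors, and sequencing artefacts. Passing the synthetic benchmark
therefore demonstrates the pipeline's structural correctness (recovery of
masked genes, repair of fused/split models, decoy rejection), not calibrated
performance on real assemblies, which additionally depends on profile quality
and genome-specific intron statistics.

The benchmark scales used by the test suite and the acceptance script — a
500-kb genome with 30 implanted genes for the end-to-end run, 300 kb with 12
homologs for allele mining, 50 sequences for motif recovery — are desk-scale
choices that exercise every stage, including multi-gene clusters, within
seconds to minutes.

## Numerical choices and degenerate inputs

* Internal coordinates are 1-based inclusive throughout (the GFF3/IRanges
  convention), so no conversion happens anywhere in the package.
* Alphabet handling: `X` (and `*` treated as `X`) is score-neutral in PSSMs,
  excluded from seed words, and scored through the BLOSUM62 `X`/`*` columns
  in alignments.
* A frameshifted CDS never aborts translation: it is translated in frame 0,
  flagged, and the model is marked pseudogene.
* Tie-breaks are deterministic everywhere: hit merging prefers higher score
  then smaller start; the DP traceback prefers match over gaps over introns
  over a fresh start, and the shortest intron on ties; EM initialisation ties
  break towards rarer composition then lexicographic order.
* Profiles shorter than the protein window, proteins shorter than the
  coiled-coil window, and empty proteomes return empty results rather than
  errors; fewer than two motif-discovery sequences or single-residue
  composition are errors.
* The ZOOPS prior is clamped to [0.01, 0.99]; motif count matrices carry
  per-cell background pseudocounts so log-odds stay finite.
* The Karlin parameters are bundled constants for ungapped BLOSUM62 scoring;
  the test suite checks them against the score statistics of shuffled
  sequences instead of asserting them.

## Using the package

```{r example, eval = FALSE}
spec <- synth_spec(genome_length = 200000, n_genes = 8, n_te = 3,
                   n_omitted = 2, n_fused = 1, n_split = 1)
tr <- generate_genome_with_truth(spec, seed = 11)
res <- run_hrp(tr$genome, tr$proteome, tr$annotation)
res
tidy(res)      # one row per output gene model
glance(res)    # one-row summary
autoplot(res)  # class counts
write_hrp_outputs(res, "hrp_out")
```

A thin command-line wrapper with subcommands `run`, `mine`, `pds`, `compare`
and `simulate` is installed at `system.file("scripts", "hrp", package =
"hrpredict")`.

## Known limitations

* Introns are restricted to phase 0 between codons with canonical `GT..AG`
  boundaries; the synthetic generator implants exactly this class, so
  end-to-end truth is exact, but real phase-1/2 introns would shift predicted
  boundaries.
* The reciprocal-best-hit comparison uses a package-defined normalized
  confidence (best ungapped score over the smaller protein's self-score); it
  is not numerically comparable to external orthology tools' confidence
  scores, and in-paralog cluster expansion is out of scope.
* Gapped Karlin–Altschul parameter estimation, frameshift-tolerant
  alignment, and chromosome-scale performance engineering are out of scope;
  the package targets desk-scale genomes and extracted regions.
* Partial-gene discovery in pass 2 is limited to loci seeded by full-length
  queries; partial architectures enter the report through re-annotation of
  those models and through motif rescue, not through a dedicated
  partial-gene search.
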