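---
title: "Inferring condition-specific regulatory networks from co-expressed profiles and promoter motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring condition-specific regulatory networks from co-expressed profiles and promoter motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proTRN)
```

## The problem

Bacteria such as *Rhizobium etli* switch between radically different
physiological programs — free-living growth in minimal medium versus the
non-growing, nitrogen-fixing bacteroid inside a legume nodule. Proteomic
profiles of the two states list which proteins (including transcription
factors, TFs) are co-expressed, but say nothing about who regulates whom.
`proTRN` infers that wiring from two ingredients:

1. **Per-gene motif matrices.** Each gene carries one to five DNA motif
   count matrices (PSSMs) discovered from its own upstream region and its
   orthologs; a matrix identifier `RHE_RS13345_m5` names matrix 5 of gene
   RHE_RS13345. A gene's matrices recognise, by construction, at least one
   site in the gene's own promoter.
2. **Condition profiles.** The loci expressed in a condition, with a flag
   for regulators. Co-expression is the constraint: only TFs present in a
   profile are allowed to regulate the profile's genes.

The output is a directed TF-to-target network per condition, its
structural property profile against Erdős–Rényi nulls, a layered
regulatory hierarchy, and a report of condition-specific isoenzymes
(distinct loci sharing one KEGG Orthology number across conditions) with
their inferred regulators.

## Site scoring and exact p-values

A PSSM of width $w$ is regularised with a total pseudocount (default 1,
spread over bases in proportion to the background) and converted to
log-odds: entry $(b, j) = \log_2 p(b, j)/q(b)$ with background $q$. A
candidate site's *weight* is the sum of its log-odds entries in bits;
strand `R` scores the reverse complement.

The p-value of a weight $s$ is $P(\mathrm{score} \ge s)$ for a random
sequence drawn i.i.d. from the background — computed **exactly** by
column-wise dynamic programming over a discretized score lattice
(default cell: 0.01 bits). Rounding each entry moves a total score by at
most $w g / 2$, so threshold lookups carry that tolerance and halving the
granularity moves any p-value by less than the mass near the threshold;
both facts are asserted against exhaustive $4^w$ enumeration in the test
suite. The null is single-stranded; scanning handles the reverse strand
by scoring both orientations of each window and keeping per-strand
p-values, matching the matrix-scan convention the input matrices come
from.

Sites are banded into stringency tiers: low ($10^{-4}$ to
$9.9\times10^{-4}$), medium ($10^{-5}$ to $9.9\times10^{-5}$) and high
($\le 9.9\times10^{-6}$). The printed two-significant-figure endpoints
leave gaps (e.g. $9.95\times10^{-5}$), so the implemented intervals are
the enclosing half-open decades.

## The three-step network method

1. **Step 1 — scan.** Every matrix of every co-expressed TF is slid over
   the upstream region (both strands) of every profile locus, self-pairs
   included. Per (TF, target) pair the single most stringent hit is kept
   (the "auto" selection; ties: smaller start, strand D, lower matrix
   index), with a relation cutoff of $9.9\times10^{-4}$. Genes recognised
   by no TF, and TFs hitting nothing, drop out.
2. **Step 2 — clustered-TF filter.** The matrices of the step-1 genes are
   clustered by best ungapped alignment correlation (average linkage on
   $1-\mathrm{cor}$; a merge must keep average $\mathrm{cor} \ge 0.6$ and
   width-normalised $\mathrm{Ncor} \ge 0.4$, the clustering tool's
   published defaults). Only clusters spanning at least two genes and
   containing at least one TF matrix are retained; the retained gene set
   is their union. The rationale: a target whose own conserved motif
   resembles a co-expressed TF's motif is much less likely to be a chance
   hit.
3. **Step 3 — rebuild.** The network is rebuilt exactly as in step 1 but
   restricted to the retained genes.

On synthetic data this reproduces the intended behaviour: step 3 loses
almost no true relations, improves precision, and shifts the per-decade
p-value histogram (`pvalueRangeHistogram()`) towards the high-stringency
tiers.

A numerical note on the alignment: matrices with near-consensus columns
make short chance alignments correlate almost perfectly (a handful of
coincidentally equal consensus positions suffices), so the aligner
requires at least $\lceil \tfrac{2}{3}\min(w_a, w_b)\rceil$ (floor 5)
overlapping columns. Ncor, `cor` times aligned width over the larger
width, further penalises short overlaps.

## Structural properties and null models

`propertyProfile()` computes 13 normalized properties: regulator
fraction ($k_{out}>0$), self-regulation fraction, maximum
out-connectivity over $n$, weak giant-component fraction, density times
regulator fraction, FFL / complex-FFL / 3-feedback-loop counts divided by
the potential-motif number

$$\frac{n!}{(n-r)!}\cdot\left(\frac{TF_n}{n}\right)^{TF_m},\qquad r = 3,$$

with $TF_m = 3$ for 3-feedback loops and $2$ for (complex) feedforward
loops ($0^{TF_m} := 0$ when $TF_n = 0$), average directed shortest path
over reachable ordered pairs (unreachable pairs are excluded, not
infinite), diameter over $n-2$ clamped at 1, average clustering
coefficient of the undirected simplification, and the adjusted $R^2$ of
robust log–log fits to $P(k)$ and $C(k)$ (total degree by default; a
failed fit contributes 0 — no power-law signal). Triads are counted once
per unordered node set, self-loops ignored; a triple carrying a directed
3-cycle is a 3-feedback loop, an FFL triple with any extra internal edge
is "complex" — the latter term is pinned down here behind the `kind`
flag because usage varies. Degree-law exponents are available both from
the robust fit and by discrete maximum likelihood
(`fitDegreeLaw(method = "mle")`, $x_{min}=1$); $R^2_{adj}$ always comes
from the robust fit.

The null is $G(n, m)$: uniform simple directed graphs with exactly the
biological network's node and edge counts (`erEnsemble()`, default 1000
replicates, seeded). Profiles are min–max scaled per property across
networks (constant columns map to 0 to avoid 0/0), Ward-clustered
(`ward.D2`) in both directions, and Pearson-correlated (on the scaled
profiles by default; the raw-profile order is a flag, since either
reading of the procedure is defensible). Because the null graphs are
simple, planted networks — whose genes recognise their own promoters —
always exceed the null's self-regulation.

## Hierarchy

Structural genes ($k_{out}=0$) are stripped once — not iterated, since
iterating would change the out-connectivities the next step classifies
on. Each remaining edge $(a,b)$ is top-down iff
$k^{out}_a > k^{out}_b$; ties and inversions (including every self-loop,
which is a tie by definition) are bottom-up and removed, which provably
leaves a DAG (verified at run time; violation is an internal error).
Layered topological sorting then puts roots in layer 1 and every node one
layer below its deepest regulator, so regulation only points down.
Regulators stranded without edges are placed in the bottom layer and
flagged — the procedure itself does not say where they belong, and the
bottom is the conservative choice. The removed bottom-up edges and
structural genes reconstruct the input network exactly.

## Isoenzyme multiplicity

Loci are grouped by KEGG Orthology number; a KO expressed through
different loci in different conditions ("multiplicity") marks
condition-specific isoenzymes. Per-condition locus sets are classified
`identical` (same set everywhere — one shared gene, not an isoenzyme),
`disjoint`, `overlapping`, or `single-condition`. Because the counting
rule for partially overlapping sets is a judgement call, both an
inclusive (disjoint + overlapping) and a strict (disjoint only) count are
reported. `differentialRegulators()` joins groups with the per-condition
networks and flags groups whose regulator sets differ across conditions;
member loci with no inferred regulator are listed as uncovered. A curated
*R. etli* CFN42 minimal-medium / bacteroid table ships under `extdata`
as a regression fixture.

## The synthetic-data generator

`generateWorld()` builds a self-contained test world with full ground
truth. Defaults, chosen once as realistic study conditions:

- **Promoters:** 250 bp upstream regions ending immediately before the
  gene start, positions 1-based inclusive; i.i.d. background, default
  uniform (configurable GC).
- **Motifs:** width 12 ± 2 bp, per-column information content 1.8 bits —
  conserved footprint-derived motifs are close to consensus. Every gene
  gets a self-site in its own promoter (the emulated motif resource is
  built on self-recognition), so TF self-pairs are genuine truth edges.
- **Regulons:** sizes Zipf($\alpha=1.5$) truncated at $n/4$, inducing
  hubs; sites sampled from the TF's probability matrix, implanted on a
  uniformly chosen strand at non-overlapping positions where possible.
- **Matrices:** one to five per gene — the gene's own motif (a
  20-site multinomial sample of the generating matrix) plus
  Dirichlet-perturbed copies of the motifs of the TFs regulating it, so
  matrix clustering faces realistic near-duplicates; this is what makes
  the clustered-TF filter recover planted regulon members.
- **Profiles:** a locus is shared by all conditions with probability
  `overlap`, otherwise assigned to one condition; TFs enter each
  condition at rate `tfRate` (default 1). Two conditions are labelled
  MM / bacteroid. No effect-size or noise model is imposed on profile
  membership — the overlap parameter is an explicit free stand-in.
- **KO map:** exactly `nMultiplicityGroups` KOs with disjoint
  per-condition loci, `nIdentical` identical-pattern KOs (prefix `K9`),
  singleton KOs for everything else, one or two pathway labels per
  planted KO.

One integer seed drives every stochastic substep; regenerating with the
same seed reproduces the world bit for bit, and the RNG state of the
caller is restored.

What the generator does *not* emulate: mass-spectrometry intensities and
missingness, ortholog promoter sets across genomes, operon structure,
overlapping or competing sites beyond incidental placement, and any
correlation between expression level and motif strength. Passing tests
therefore demonstrate the machinery's correctness and the qualitative
behaviour of the filters — not calibrated performance on real proteomes.

## Design choices in open territory

- **Relation-level "auto" selection.** The most stringent hit is chosen
  per (TF, target) relation over all the TF's matrices; the winning
  matrix index is recorded in `Matrix_ID`. Whether the original
  procedure operates per relation or per round is underdetermined; the
  per-relation minimum is the deterministic reading and is documented.
- **Regulon-size tracking is measured on own-motif relations.** Under
  the default heavy-tail law most planted regulons have the minimum
  size, and the min-p rule lets the perturbed motif copies carried by
  co-regulated TF genes absorb other TFs' regulons — total per-TF edge
  counts are then dominated by those two effects. The test therefore
  plants spread-out regulon sizes (exponent 0.8), uses a strict cutoff
  ($10^{-6}$), and credits relations to each TF's own discovered motif
  (matrix index 1), where the measured rank correlation against planted
  sizes is ~0.97.
- **Significance** is $-\log_{10} p$ of the site p-value; the source
  convention prints the column without defining it.
- **Problem sizes.** The shipped tests and the acceptance script run the
  full pipeline on a 200-gene / 20-TF world (the planted-recovery
  condition), 10-replicate null ensembles per biological network for the
  segregation check, and a 60-gene world for KO planting; these sizes
  were chosen so the complete suite exercises every stage end to end at
  desk scale.

## Worked example

```{r example, eval = FALSE}
library(proTRN)
world <- generateWorld(nGenes = 60, nTfs = 6, seed = 11)
world <- generateProfiles(world, overlap = 0.5)
world <- generateKoMap(world, nMultiplicityGroups = 3)

mm <- worldProfiles(world)[["MM"]]
ts <- threeStep(mm, worldPromoters(world), worldMatrices(world),
                condition = "MM")
ts$step1
ts$step3
networkAccuracy(ts$step1, truthNetwork(world), universe = mm$loci)

propertyProfile(regGraph(ts$step1), label = "MM")
hierarchyDecompose(ts$step1)
detectIsoenzymes(world, worldKoMap(world))
```

## Known limitations

- Promoter scanning is windowed and ungapped; variable-spacing dyad
  motifs are only represented as far as a fixed-width matrix can.
- The p-value null is 0-order i.i.d. background; real promoters have
  composition structure that inflates significance for AT-rich motifs.
- The clustered-TF filter's thresholds are the clustering tool's
  defaults, not fitted to data; they are exposed as knobs.
- Hierarchy classification uses raw out-connectivity; near-ties flip
  edges between top-down and bottom-up, so dense noisy networks show
  large bottom-up fractions.
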