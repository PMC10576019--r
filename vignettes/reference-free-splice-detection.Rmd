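---
title: "Reference-free detection and typing of alternative splicing from transcript pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free detection and typing of alternative splicing from transcript pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbgsplice)
library(dplyr)
```

## The problem

Most alternative-splicing (AS) detectors align reads to an annotated genome.
For many organisms no usable reference exists, yet full-length transcripts —
from assembly or from long-read (Iso-Seq) sequencing — are easy to obtain.
Two isoforms of the same gene differ by the spliced regions themselves, so the
seven canonical AS event classes (exon skipping ES, alternative acceptor AA,
alternative donor AD, intron retention IR, alternative first/last exon AF/AL,
mutually exclusive exons MX) are in principle recoverable from the transcript
sequences alone. The obstacles are (i) distinguishing splicing from paralogy
— transcripts of two homologous genes also look like isoforms, but differ by
substitutions instead of clean insertions — and (ii) typing events without
exon/intron annotation.

`dbgsplice` addresses both with a per-pair **colored de Bruijn graph**
(cDBG): candidate transcript pairs are compared in a k-mer graph whose nodes
remember which transcript(s) contain them, differences surface as *bubbles*,
and bubble **topology** separates substitutions from splicing.

## The graph model

For a pair of transcripts the graph is $G = (V, E, C)$: nodes are the k-mers
of the two sequences, edges connect consecutive k-mer windows, and colors $C$
record per-node membership. Two design elements make the topology rules
exact:

* **Dynamic k.** `select_k()` returns the smallest $k$ (at or above
  `k_floor = 5`) at which every k-substring of a sequence is unique;
  `select_k_pair()` takes the maximum over the two transcripts. At this k each
  color traces exactly one acyclic source-to-sink path that spells its
  transcript, so bubbles are well defined. Uniqueness is monotone in k, which
  allows a binary search.
* **Sentinel padding.** Each sequence is padded with $Q^k$ and $P^k$
  (`pad_sequence()`). A single sentinel character cannot force a shared
  source node when the first bases differ, but a full k-block does; AF/AL
  bubbles are then recognizable by anchor nodes containing `Q` or `P`.

Bubbles are enumerated by walking both color paths in lockstep along their
anchor chain. Because every k-mer occurs at most once per path, the maximal
order-consistent chain of shared nodes is the longest increasing subsequence
of the shared k-mers' positions, computed in $O(n \log n)$; each gap between
consecutive anchors is one bubble. Arm length is counted in **interior
nodes**, which makes the three topology rules exact:

| arms (interior nodes) | category | cause |
|---|---|---|
| $(k, k)$ | SNV | one substituted base |
| shorter arm $= k-1$ | AS | clean insertion/deletion (splice junction) |
| both $> k$ | OTHER | AF/AL/MX, or variants merged within $< k$ |

Combinations outside these rules are conservatively assigned OTHER rather
than being guessed, and go to refinement.

## Mixed-k refinement

Two variants closer than $k$ merge into one OTHER bubble. `refine_bubble()`
spells the bubble's arms, strips sentinels, picks the smallest cycle-free
$k'$ for the arm pair, and rebuilds the arms as a padded sub-graph when
$k' < k$; `incorporate_refinement()` replaces the bubble with the
sub-graph's bubbles, coordinates translated to the full transcript. The
result is observationally a mixed-k graph $G' = (V', K, E', C)$. Two
substitutions separated by a gap of $g$ matching bases can be split exactly
when $k' \le g$; for this reason refinement has its own floor
(`refine_k_floor = 3`) below the construction floor — arm sequences are
short and local, so tiny k values are safe there, and a floor of 5 would
make gaps of 3–4 nt permanently unresolvable. Refinement is applied once
per bubble by default; `recursive_refine` enables recursion to depth 5.

## Event calling

On the original (pre-refinement) bubble inventory, AF/AL/MX are called when
(i) exactly one OTHER bubble exists, (ii) the arm belonging to the shorter
transcript spans less than `afalmx_arm_fraction` (default 0.30) of that
transcript's length, measured in spelled nucleotides with sentinels
excluded, and (iii) the pair's SNV-bubble count is within tolerance. The
position rule is sentinel adjacency: a bubble whose divergence node contains
`Q` is AF, whose reconvergence node contains `P` is AL, otherwise MX. The
fractional rule is deliberately evaluated in nucleotides (not nodes), since
the transcript length it is compared against is a nucleotide count.

Remaining AS-topology bubbles become `UNTYPED` events unless the pair's
final SNV count exceeds `snv_tolerance` (2 for assemblies — "fewer than
three" — and 5 for Iso-Seq), in which case the pair is rejected as putative
paralogs. The longer arm marks the inclusion transcript; the $(k-1)$-node
arm maps to an empty junction interval on the exclusion transcript. All
output coordinates are 1-based inclusive on the unpadded transcripts.

### Long-read errors

Iso-Seq errors are dominated by 1–2 nt gaps. In `isoseq` mode
`apply_isoseq_error_filter()` drops, before event calling, every non-SNV
bubble whose arms both have fewer than $k+2$ interior nodes — a single
1–2 nt gap gives arms $(k-1, k)$ or $(k-1, k+1)$, and gaps hitting *both*
transcripts within $k$ of each other merge into a slightly larger bubble
still under that bound. A second check catches merged gap pairs that reach
the bound: a pre-refinement OTHER bubble whose spelled arms differ by an
edit distance of at most 4 (two ≤2 nt gaps) is attributable to errors and
dropped, whereas genuine AF/AL/MX arms are unrelated sequences whose edit
distance scales with their length. SNV-shaped bubbles always survive the
filter so that the (raised) paralog tolerance still sees them. The price of
the gap rule is stated plainly: true alternative regions of 1–2 nt are
invisible in `isoseq` mode.

## Typing ES/AA/AD/IR

Graph topology cannot separate the four internal classes — each is one
inserted/deleted block. They are typed by sequence instead, exploiting the
GT–AG intron rule: the variable regions of the four classes are different
intron fragments (IR carries the complete intron, AA the donor end, AD the
acceptor end, ES none).

**Features (1982 per event).** From the event's coordinates, 7 windows per
transcript (14 total): 50 nt upstream/downstream of each region boundary,
50 nt centered on each boundary, and the full alternative region (empty on
the exclusion side; empty windows contribute zeros). Each window yields 96
values — length, length-divisible-by-3 flag, GT/GC/AT/AG/AC presence flags
at the 5' and 3' ends, and mono/di/trinucleotide frequencies — for 1344
values. A motif list (314 entries by default) contributes presence flags in
the two outer flanks (628), and 10 event-level summaries (region length and
GC, flank GC, relative position, motif hit counts) complete the vector.
The per-window layout is this package's reconstruction: the published
feature inventory fixes the three region roles, the 50-bp flanks, the
end-dinucleotide and motif flags, and the total dimension, but not the full
per-window breakdown; the layout here satisfies all of those constraints.
The shipped motif list is a **synthetic placeholder**
(`inst/extdata/motifs_synthetic_314.txt`): a core of canonical splicing
regulatory elements padded to 314 with deterministic filler words. Models
record a hash of their motif list and refuse prediction against a different
list.

**Classifier.** Features are standardized, ranked by
extremely-randomized-trees impurity importance (features above the mean
importance are kept — the published account fixes the selector but not its
threshold), and minority classes are balanced with Borderline-SMOTE-1
(m = 10, k = 5, the method's canonical defaults), implemented in-package as
no installed R package provides it. Oversampling touches only the training
portion of the stratified 7:3 split, so the held-out estimate stays clean;
the published order of operations does not state this, and leakage avoidance
decided it. Hyperparameters of the gradient-boosted-tree model (XGBoost) are
chosen by 10-fold cross-validated accuracy over a grid spanning the two
shipped per-kingdom optima (`default_hyperparams("animal")`: 0.6/0.2/8/4/0.8;
`"plant"`: 0.5/0.2/9/4/0.7 for colsample/learning rate/depth/child
weight/subsample). Training is fully seeded; two runs with the same seed
produce byte-identical serialized models.

## PSI and differential splicing

With transcript abundances (any quantifier), the percent-spliced-in of an
event in a sample is `incl / (incl + excl)` over its two transcripts, NA
when both are zero. `diff_splice()` tests the difference of mean PSI between
two conditions with a two-sided permutation test on condition labels, exact
(via full enumeration) whenever the number of label arrangements is at most
10,000, seeded Monte Carlo otherwise, with Benjamini–Hochberg correction
across events. This choice is deliberate at the replicate counts typical of
two-cell-line designs, where parametric assumptions are shaky.

The default p-value uses the **mid-p convention** (ties with the observed
statistic count half). The permutation null is very discrete at small n:
with 5 + 5 replicates there are only $\binom{10}{5} = 252$ arrangements and
the plain two-sided p-value cannot go below $2/252 \approx 0.0079$; BH over
a few hundred events then needs more discoveries at that floor than true
events typically exist, and *no* event can ever be rejected at FDR 0.05 —
the plain convention makes small-replicate FDR analysis structurally
impossible, not merely underpowered. Mid-p halves the floor and restores
usable resolution while remaining a standard convention for discrete tests;
`midp = FALSE` gives the plain definition. Note one visible consequence:
for completely constant data the mid-p is 0.5 rather than 1.

## The simulator and what passing tests mean

`gen_event_pair()` builds one ground-truthed pair per event type: random
exon blocks, the alternative region carrying the boundary dinucleotides of
its class (IR `GT..AG`, AA `GT..`, AD `..AG`, ES neutral), optional isolated
substitutions in shared exons (paralog mimics), and exact truth coordinates.
Rejection sampling enforces two study conditions: pairs are repeat-free at a
small k (`select_k_pair()` ≤ 15) so graph oracles stay exact, and the bases
adjacent to each junction differ across it, so the planted coordinates are
the *unique* excision solution — without this, coordinate recovery is
ill-posed, not merely hard. `corrupt_tgs()` adds Poisson-placed 1–2 nt
deletions and substitutions away from truth boundaries;
`gen_psi_dataset()` plants PSI shifts under ~20% multiplicative lognormal
abundance noise. Default sizes (60 nt regions, 120 nt exons, 300 nt shared
blocks, 2 conditions × 5 replicates) are ordinary values for plant/animal
transcripts and small RNA-seq designs.

The generator emulates clean, two-isoform, same-strand comparisons. It does
not emulate repeat-rich transcripts, isoform families larger than two,
expression-dependent coverage, or reverse-complemented contigs — so passing
tests demonstrate correctness of the graph calculus and calibration of the
statistics under the stated conditions, not performance on adversarial real
transcriptomes. Known limitations, stated as such: `N`-containing
transcripts are rejected at graph construction; strandedness is assumed
(a reverse-complemented pair yields one giant unresolved bubble and is not
called); per-pair reporting means events shared by transcript families are
reported once per pair.

## Numerical and scale choices

Exactness drives most numeric policy: coordinates are integers; permutation
tests enumerate exactly when feasible; ties in the grid search break toward
the earliest grid entry; standardization guards zero-variance features by
unit scale. Test-suite problem sizes — 20 fixtures per event type for
end-to-end runs, 200 events per class for the classifier (with a reduced
2×2×2 hyperparameter grid around the shipped optima), 200 events (20
shifted) for the differential module and 1000 for its null calibration —
were chosen as the smallest sizes at which the corresponding rates are
stable, and are the package's own reporting conditions.
```
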