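---
title: "Dating a gene fusion: models, surrogates and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating a gene fusion: models, surrogates and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionclock)
```

## The problem

`fusionclock` reconstructs and dates the evolutionary history of a
bi-modular gene fusion on a species phylogeny. The worked scenario is the
poppy (*Papaver*) fusion gene that joins a cytochrome P450 module to an
oxidoreductase module through a short (9-13 amino acid) linker; the fused
protein epimerizes (S)- to (R)-reticuline, the gateway reaction of
morphinan alkaloid biosynthesis. The inference chain is:

1. date the species tree with a calibrated strict molecular clock;
2. build gene trees for the two module families, test whether the
   fusion-derived sequences form monophyletic orthologous subgroups;
3. detect and classify fusion genes from sequence (full fusion, truncated
   fusion, unfused gene pair);
4. reconcile gene trees with the species tree (LCA mapping), infer losses
   under Dollo parsimony, and bracket the fusion origin in absolute time;
5. compare gene order across contigs (reciprocal best hits, cluster
   presence) to date the assembly of the surrounding biosynthetic gene
   cluster; and
6. call metabolite presence from LOD-thresholded peak areas, linking
   genotype to chemistry.

Every stage runs on synthetic data with known ground truth, produced by
the package's own simulator, so the whole chain is testable end to end
without any external downloads.

## The default study scenario

`papaver_chronogram()` encodes the dated species tree the analyses run
on: eight *Papaver* species with sequenced genomes (Pnu, Pca, Prh, Pat,
Par, Pbr, Pso, Pse) plus two outgroups. Five node ages are fixed by the
study context: the Ranunculales crown (110 MY) and Papaveraceae crown
(77 MY) calibration nodes, the split of *P. nudicaule* from the Clade 2
species (24.1 MY), the Clade 2 crown where *P. californicum* branches
(16.8 MY), and the *P. bracteatum* / *P. somniferum* split (9.7 MY). The
remaining internal ages (14, 12, 10.5 and 3 MY) are not printed anywhere;
they are plausible fill-ins chosen once to respect those brackets, and
nothing downstream depends on their exact values.

`study_event_plan()` encodes the gene-family history: a linked
P450-like/oxidoreductase-like gene pair born on the *Papaver* stem (the
"Ln" pair, about 1 kb apart, which *P. nudicaule* still carries), a
segmental duplication on the Clade 2 stem whose source pair continues as
"La", the single fusion event on the same stem (between 24.1 and 16.8
MY), lineage-specific losses of the fusion gene in *P. atlanticum* and
*P. rhoeas*, and a pair-order rearrangement in *P. armeniacum*.

```{r plan}
papaver_chronogram()
str(study_event_plan()[[3]])
```

## Models and surrogates

Published analyses of this system rest on Bayesian machinery
(BEAST/MrBayes: GTR+Gamma, MCMC, posterior probabilities). Those
components are not desk-scale reproducible, and this package deliberately
replaces each with a declared deterministic surrogate with the same
semantics:

| field-standard component   | surrogate here                              |
|----------------------------|---------------------------------------------|
| Bayesian chronogram        | strict-clock least squares with the same calibration means/sds as quadratic penalties |
| posterior probabilities    | nonparametric bootstrap proportions on NJ trees |
| BLASTN module search       | exact Smith-Waterman local alignment        |
| E-value cutoff (RBH)       | normalized self-score ratio `q` (default 0.9) |
| Gblocks                    | per-column gap-fraction / majority-conservation filter |

### Sequence evolution

Simulation and estimation both use JC69 and nothing richer. The closed
form is invertible (`d = -(3/4) log(1 - (4/3) p)`), which keeps every
recovery test analytic. No indels are simulated, so multiple alignment is
positional identity and the out-of-scope aligner never enters the tested
core; real data would be aligned externally before entering the same
functions. Rate heterogeneity and codon models are out of scope.

Two clock rates matter and they are deliberately different:

* **Species-tree genes**: 1.396e-8 substitutions/site/year, the
  published LTR-insertion dating rate for these genomes. At this rate the
  110 MY calibration depth corresponds to ~3.1 substitutions/site - close
  to JC saturation, which is exactly the regime the dating machinery has
  to survive.
* **Module (gene-family) genes**: 3.4e-9 substitutions/site/year by
  default. This is derived once from the published data for this system:
  fusion-gene nucleotide identities span 89.4-99.9%, and 89.4% identity
  at the deepest carrier split (2 x 16.8 MY of separation) implies
  d = 0.114 and r = 3.4e-9. Simulating the modules at the repeat rate
  would produce ~65% identity, contradicting the data the scan
  thresholds describe.

### Dating

Two least-squares daters are provided.

`ls_date()` implements the per-branch objective: minimize
`sum_e (b_e - rate * (t_parent - t_child))^2 +
sum_c ((t_c - mean_c)/sd_c)^2` subject to parent > child >= 0, with
`sd = 0` treated as a hard equality. The problem is biconvex, so the
package alternates a linear solve for the ages with the closed-form rate
update, initialized from mean-path-length ages scaled to the
calibrations; convergence tolerance is 1e-8 on the objective. Because
rooting on an outgroup splits the outgroup edge arbitrarily, the two
root-child branches contribute one pooled residual.

`ls_date_distances()` fits the same model directly to the pairwise
distance matrix: each tip pair contributes `d_ij - 2 rate t_lca(i,j)`,
weighted by the inverse delta-method variance of the JC estimate,
`w = (1 - 4p/3)^2 n / (p (1 - p))`. The pipeline uses this fitter. The
reason is empirical and worth stating: NJ/BIONJ branch lengths near a
deep, nearly saturated root are poorly determined, and the unweighted
per-branch objective lets those edges bias the fitted rate by 5-10%;
fitting the full matrix with variance weights recovers every node of the
default chronogram within ~4% under the default simulation conditions.
Both fitters break exact parent/child age ties with an epsilon of 1e-6
MY and report that they did so.

For topology, `nj_tree()` offers standard neighbor joining (the default,
and the subject of the additive-matrix exactness tests) and BIONJ. The
pipeline's species-tree stage uses BIONJ
(`default_config()$species_tree_method`): the Ranunculales-level JC
distances sit at p close to 0.75 where the estimator variance explodes, and
plain NJ then misplaces short ingroup edges in roughly a quarter of
simulation replicates, while the variance-weighted agglomeration is
stable. Negative branch lengths are clamped to zero with a warning,
never silently.

### Ks paralog dating

`ks_nei_gojobori()` implements Nei-Gojobori counting: per-position
synonymous-site fractions (a change to a stop codon is never synonymous),
averaged over both sequences; pathway-averaged synonymous difference
counts (pathways through stop codons are excluded unless all are
blocked); Jukes-Cantor correction. `date_duplication()` converts Ks to
time as `T = Ks / (2 r)` with the rate always explicit. Saturated pairs
(`Sd/S >= 0.75`) propagate as undated with a reason, never as a number.

The simulator's counterpart, `simulate_synonymous_pair()`, evolves a
coding sequence under JC proposals and rejects any non-synonymous or
stop-creating proposal. Under that process synonymous substitutions
accrue at exactly the clock rate per Nei-Gojobori synonymous site, so
the expected Ks of the pair is `2 r t`. Two caveats are known and
accepted: two-fold degenerate sites saturate differently from the JC
assumption behind the correction, and the JC correction is convex in p;
together they bias recovered ages upward by roughly 5% at Ks near 0.56,
well inside the 15% recovery tolerance the tests use.

### Fusion scanning

`scan_sequence()` locates the best local hit per module role, projects
each hit to the full module extent, and classifies: `full_fusion` needs
both modules at >= 80% reference coverage, on one strand, P450 before
oxidoreductase, in one reading frame, with a translated linker of 9-13
aa (bounds configurable); `truncated_fusion` needs a full P450 plus a
conserved in-frame linker and then a short oxidoreductase remnant ending
at a premature stop, whose codon position is reported. A stop codon
*inside* the linker is reported as a diagnostic but does not change the
class - the structural requirements are strand, frame, order and linker
length. Coordinates are 0-based half-open throughout; minus-strand hits
are reported in forward coordinates, and scanning a reverse complement
returns the same call with the strand flipped. `scan_layout()` adds the
`unfused_pair` class for complementary single-module genes within 5 kb
(default) on one contig, with orientation-normalized order flags.

### Reconciliation and brackets

`lca_reconcile()` is the standard LCA mapping with the path-difference
loss count; `extract_subgroups()` returns the maximal duplication-free
clades, which is the package's operational definition of orthologous
subgroups. `dollo_losses()` performs single-origin (Dollo)
reconstruction: origin on the carrier MRCA's stem, losses on the stems
of the maximal carrier-free subtrees inside the carrier clade - a set
that is provably minimal, which the tests confirm by enumeration.

`bracket_fusion()` makes the bracket semantics explicit, since published
brackets for this system leave them implicit: the **lower** bound is the
crown age of the
carriers' MRCA (the fusion predates the carriers' radiation), the
**upper** bound is the age at which the nearest sampled non-carrier
lineage diverged (the parent node of that MRCA). On the study scenario
this reads [16.8, 24.1] MY. The single-origin reading is gated on the
monophyly of the fusion-derived gene subgroups (bootstrap support
threshold 0.7 by default); if monophyly fails, the bracket is refused
with the reason "possible multiple origins" rather than reported. All
inference is over the sampled species only; unsampled lineages could
only widen the true bracket.

The cluster-formation bracket works the same way one level up: the crown
age of the species sharing the complete five-gene cluster (the fusion
gene plus the four promorphinan genes) bounds the cluster's assembly
from below (9.7 MY in the scenario), and the fusion bracket's lower end
bounds it from above.

### Metabolite calls

`fit_lod()` is ordinary least squares of response on concentration with
`LOD = 3.3 Sy / S` (residual sd over slope). `call_presence()`
back-calculates concentrations through the fitted line (intercept
retained) and calls `detected` at or above 10x LOD - the boundary is
inclusive by choice, and configurable, since published presence calls do
not state which way exactly 10x falls. The bundled `papaver_presence()` table transcribes
the published 12-species presence matrix; its promorphinan class count
(4 species) is one of the package's exact worked examples.

## What the simulator does and does not emulate

The generator reproduces: clock-like coding-sequence evolution on a
dated tree, gene pairing at a configured genomic distance, segmental
duplication, a single in-frame fusion with a fresh 9-13 aa linker,
lineage-specific loss, pseudogenization (frameshift insertion or
premature stop), pair-order rearrangement, per-contig gene layouts, and
LOD-calibrated dilution/peak tables. Everything is byte-reproducible
from a mandatory seed.

It does **not** emulate: indels and alignment error, rate variation
across sites or lineages, GC/codon-usage bias, incomplete lineage
sorting, assembly artifacts, or chromatographic peak shapes. Passing
tests therefore demonstrate that the inference chain is correct and
well-calibrated under its stated model, not that real draft genomes are
free of the failure modes the model excludes.

## Problem sizes and numerical choices

The default pipeline configuration simulates eight species-tree genes of
2000 nt (16 kb concatenated), 900 + 600 nt modules, 100 bootstrap
replicates, and a 20-point dilution series per compound; a full run
takes a few seconds. These sizes were chosen as the package's standard
demonstration scale and match the recovery tolerances used in the tests
(bracket endpoints within 10%, Ks age within 15% over 50 replicates).
Other numerical defaults: local alignment scores +2/-3 with linear gap
-5 (the scanner uses -12 internally where codon-exact projections
matter), RBH normalized-score threshold 0.9, cluster span cap 1.2 Mb,
monophyly support 0.7, module coverage 0.8. Every one of these is a
`default_config()` entry, not a constant.

## Known limitations

* Strict clock only; lineage rate variation will bias node ages and is
  intentionally out of scope.
* The bootstrap-support threshold is not a posterior probability; the
  mapping between the two is undefined and the threshold is exposed as
  configuration rather than asserted as equivalent.
* JC saturation near the root calibration is the dominant noise source
  in single-calibration transfer; estimates remain unbiased but carry
  ~5% sd at the default data size.
* The Gblocks-like trimmer is parameterized by gap fraction and majority
  conservation; it is not parameter-equivalent to Gblocks.
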