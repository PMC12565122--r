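---
title: "Relative evolutionary rate scans: model, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative evolutionary rate scans: model, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rerscan)
library(dplyr)
```

## The model

A selection scan of this kind asks, gene by gene, whether the rate of
protein evolution shifted on the phylogenetic branches associated with a
phenotype — flight, homeothermy, large body mass, long lifespan — relative
to the gene's own genome-wide trend. The unit of analysis is the *relative
evolutionary rate* (RER): for gene $g$ and branch $b$,

$$ r_{gb} = \sqrt{\ell_{gb}} - \left( \hat a_g + \hat b_g \sqrt{c_b} \right), $$

the residual of an ordinary least-squares regression (with intercept,
fitted per gene) of the gene's square-root branch lengths $\ell_{gb}$ on
the square-root consensus lengths $c_b$, over the branches where the gene
has data. A gene that simply evolves twice as fast everywhere has slope
$\sqrt 2$ and residuals of zero; only branch-*specific* departures from the
gene's own trend register. Residuals are positive where the gene ran faster
than expected and negative where it ran slower.

Assumptions worth keeping in view:

* the master topology is correct and shared by all genes (gene trees are
  the master restricted to the gene's taxa, with re-estimated lengths);
* branch lengths are non-negative substitutions/site, with sampling noise
  whose variance grows with the mean — hence a variance-stabilizing
  square root before the regression (the standard choice for such data;
  any strictly monotone stabilizer gives the same downstream Kendall and
  Mann–Whitney results, which are rank-based);
* a linear relation on the transformed scale is adequate per gene.

### Branch identity

Branches are identified by their bipartition — the set of terminal taxa
descending from the branch — never by newick position, so rotated or
re-ordered trees match unambiguously. Trees are treated as rooted as
written and the root's two child branches stay distinct; the ancestral
foreground mode needs that direction. When a gene is missing taxa, each
master bipartition is restricted to the gene's taxon set; a branch
contributes an entry only if its restriction is non-trivial *and unique*.
Master branches that collapse onto one another under pruning are missing
for that gene — no path-sum reallocation — keeping the branch
correspondence one-to-one and testable.

### The consensus

Two consensus choices are supported:

* `consensus_lengths()` (the default inside `compute_rers()`): the
  arithmetic per-branch mean over the analyzed gene trees;
* `consensus_from_tree()`: the branch lengths of an independently
  estimated genome-wide reference tree, when one exists.

The difference matters when many genes share a convergent shift. With the
package's reference simulation (20% of genes shifted by a factor of 3 on a
common foreground), the averaged consensus is itself inflated on the
foreground (expected multiplier $0.8 + 0.1 \cdot 3 + 0.1/3 \approx 1.13$),
which pushes the residuals of unshifted genes systematically negative
there and produces hundreds of spurious "slow" calls. Against the
reference-tree consensus the same scan recovers the planted genes
completely with a ~5% false share. In genome-scale analyses with tens of
thousands of genes and few shifted ones the contamination is negligible,
but the validation studies in this package use
`consensus = consensus_from_tree(master)` throughout — the analogue of
taking the genome-wide species tree as the consensus — and we recommend
that configuration whenever a trusted reference tree is available.

## From traits to branch designs

Binary traits are mapped to branches with Fitch maximum parsimony
(`fitch_parsimony()`): bottom-up intersection/union (each union event is
one change; the count equals the global minimum, which the test suite
verifies by exhaustive enumeration), then a top-down pass that resolves
each node to its parent's state when possible. An ambiguous root resolves
to 0 — the background state — so arbitrary tie-breaking can never inflate
the foreground. A branch takes the state of its child node (the branch
"leads to" it). Three designs (`assign_foreground()`):

* **clade** — every branch whose child resolves to 1: terminals and
  internals of all trait clades, covering independent origins;
* **ancestral** — only stem branches where a 0 parent meets a 1 child: the
  parsimony origins of the trait;
* **terminal** — only the terminal branches of trait-bearing species.

Continuous traits attach to terminal branches only, since trait values are
observed on extant species; they are natural-log transformed first
(`log_normalize()`; the log base cannot affect a Pearson correlation).
Two derivation rules used by comparative studies are built in:
`binarize_mass_lifespan()` (strictly more than 40 kg *and* strictly more
than 10 years by default) and `select_top_k()`, which ranks species by the
product of their mass rank and lifespan rank and takes the top $k$
(default 4). The rank product is our choice where a joint ranking is
otherwise underdetermined; score ties break lexicographically by species
id, with a message, and an explicit species list always overrides.

## Per-gene tests and classification

The binary design creates one massive tie group per label, so the Kendall
correlation is computed as tie-corrected $\tau_b$. Its two-sided p-value is
exact for $n \le 10$ branches — every placement of the foreground labels is
enumerated, equivalent to the full permutation distribution — and otherwise
uses the normal approximation with the standard tie-corrected variance of
the concordance statistic. Continuous traits use the ordinary
product-moment correlation with its t-based p-value over species shared
between the gene and the trait (at least 4).

Benjamini–Hochberg correction is applied across all genes tested in one
trait-by-mode analysis — one family per analysis, since each trait is run
and interpreted separately. Classification at level $\alpha = 0.05$:
`fast` if $q < \alpha$ and $\rho > 0$, `slow` if $q < \alpha$ and
$\rho < 0$, else `ns`; a gene with $\rho$ exactly 0 is `ns` regardless of
$q$ (no direction, no call).

Class-level checks on a designated gene family (e.g. tumor suppressors)
are post hoc and reported without FDR correction:
`fisher_overrepresentation()` (one-sided hypergeometric),
`sign_bias_test()` — the positive/negative split inside the class against
the split outside it, two-sided Fisher; because that 2×2 needs a
comparison group while the quantity of interest is the in-class fraction
itself, a binomial test against 0.5 is reported alongside — and
`class_uniformity_test()`, a Freeman–Halton r×2 test, exact up to a table
total of 30 and Monte Carlo (10^5 draws, fixed seed) beyond.

## Pathway enrichment

Each gene's direction and significance are folded into one score,
$\mathrm{FAS} = \mathrm{sign}(\rho)\,(-\log_{10} p)$, using the raw p (the
formula references the per-gene evidence, not the BH-adjusted family
quantity). The log base is 10 for interpretable magnitudes; the choice is
immaterial downstream because set testing is rank-based. p-values are
floored at $10^{-300}$ before the log. Genes dropped earlier are excluded
from both member and background groups rather than imputed.

Each gene set with at least `min_set_size = 10` scored members is tested
against all remaining scored genes with a two-sided Mann–Whitney U test —
exact by complete enumeration of member placements when feasible
(correctly handling ties), the tie-corrected normal approximation
otherwise — followed by BH across eligible sets. Direction is the sign of
the mean member $\rho$: the average gene correlation is read as the
pathway's rate of acceleration or deceleration. The size floor reflects
how small annotation sets behave when intersected with the genes actually
scored in a branch-restricted analysis: below ~10 shared members the rank
test is unstable, and ancestral-branch analyses of distant clades rarely
share enough genes to clear it.

Significant pathways are clustered by strict Jaccard overlap: an edge
wherever $J > 0.5$ (a pair at exactly 0.5 stays apart), clusters = the
connected components, so chains of mutually overlapping annotation sets
merge into one higher-order process.

An optional `raw_p_filter` restricts scoring to genes with raw
$p < \alpha$, mirroring analyses that feed only nominally significant
genes into enrichment; the default scores every tested gene, which keeps
the background well-defined.

## The simulator

`simulate_rer_study()` emulates the input structure of a
genome-alignment-based study without any downloads. One root seed drives
four fixed streams (master tree = seed, gene trees = seed+1, traits =
seed+2, gene sets = seed+3), so stages can be regenerated independently
and identical configurations write byte-identical files.

* **Master tree**: Yule (pure-birth) topology, i.i.d. exponential branch
  lengths (mean 0.1 substitutions/site — the scale of vertebrate
  amino-acid trees), tips `sp01…`.
* **Gene trees**: $\ell_{gb} = r_g \, m_{gb} \, B_b \, \varepsilon_{gb}$
  with a lognormal gene scalar $r_g$ (sdlog 0.5, matching the order of
  rate variation across real genes), foreground multiplier $m$ for fast
  genes and $1/m$ for slow genes (symmetric on the log scale), and
  mean-one gamma noise with coefficient of variation `noise_cv`.
  Multiplicative gamma noise keeps lengths non-negative and mimics rate
  overdispersion with a single knob. Species drop out independently with
  `p_missing` (redrawn, with a counted retry, if a gene would fall below
  `min_taxa`).
* **Traits**: the binary trait is membership of a designated foreground
  clade; continuous traits are Brownian motion on the master tree
  (exponentiated for mass/lifespan so values are positive), with an
  optional terminal offset on foreground species to plant a true
  RER–trait correlation.
* **Gene sets**: enriched sets draw a configured fraction of members from
  the fast genes; null sets are uniform draws with sizes in
  `set_size_range`.

The reference configuration — the defaults of `sim_config()` — is 40 taxa,
500 genes, 10% fast + 10% slow at multiplier 3, a foreground clade of ~10
species, noise cv 0.2, 5% missingness, and 20 gene sets of which one is
enriched (30 members, 80% fast). A random Yule tree often has no clade of
exactly the requested size, so the bundle picks the nearest available size
(deterministically, with a message); `pick_clade(strategy = "exact")` and
the numeric-size form of `simulate_traits()` keep the strict behavior,
erroring with the list of available sizes.

What the simulator does *not* emulate: sequence-level evolution (no
alignments, no substitution models — trees are drawn at the
branch-length level the pipeline consumes), topological discordance
between gene trees and the species tree, correlated missingness (e.g.
whole clades absent from an alignment), and phylogenetic autocorrelation
between the trait and lineage-specific rate variation. Passing tests
therefore certify the pipeline's statistics under its own model, not the
biology of any particular alignment resource.

## Numerical choices and degenerate inputs

* Genes need ≥ 3 taxa (`min_taxa`) and ≥ 3 present branches
  (`min_branches`); below that the residuals are degenerate. Genes with a
  constant consensus predictor are dropped, with the reason logged and
  tallied in the run manifest, whose accounting always balances
  (`genes_in = genes_analyzed + drops`).
* Gap filtering of alignments removes a species when its gap fraction
  strictly exceeds 30% (exactly 30% is kept); only `-` counts as a gap —
  ambiguity codes such as `N`/`X` are data, not gaps. The filter is
  applied per gene alignment and is idempotent.
* Species matching is exact string equality everywhere; fuzzy matching
  could silently corrupt a foreground assignment.
* Missing branch lengths in newick input are an error, never a default;
  malformed newick reports the offending character offset.
* Exact-test switchovers: Kendall permutation p up to $n = 10$;
  Mann–Whitney enumeration while $\binom{N}{m} \le 20000$; Freeman–Halton
  exact to table total 30. All thresholds are arguments.

## Validation studies

The test suite validates every statistic against an independent oracle
(normal-equations OLS, exhaustive parsimony labelings, full permutation
and rank enumerations, hypergeometric summation) and runs three
simulation studies chosen to be informative yet quick: a five-seed null
study (40 taxa × 500 genes, no shifts) for type-I control, a planted-shift
study at the reference configuration for recovery, and a ten-seed
enrichment study for set ranking, plus one 1000-gene × 60-taxon end-to-end
run. `scripts/acceptance.R` re-runs the planted and null studies from a
single seed and writes the measured quantities as JSON.

## Known limitations

* Pearson correlations across species ignore phylogenetic
  non-independence, and the Kendall scan permutes branch labels rather
  than trait histories; neither is a phylogenetically exact null
  (no permulation-style correction is implemented).
* The gene-averaged consensus is biased when a large share of genes carry
  convergent shifts (see above); prefer a reference-tree consensus.
* No likelihood-based ancestral reconstruction, no codon-level or
  branch-site models; inputs are precomputed (amino-acid scale) trees.
* Weighted/heteroscedastic RER regression is a possible extension; the
  default is unweighted OLS on square-root lengths.
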