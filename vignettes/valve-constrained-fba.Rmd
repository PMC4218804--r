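---
title: "Valve-constrained flux balance analysis: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valve-constrained flux balance analysis: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxvalve)
```

## The problem

A genome-scale metabolic model (GSMM) predicts a phenotype — growth rate,
attainable flux through any reaction — from stoichiometry, flux bounds and an
objective.  Transcriptome data tell us that under some condition (here, the
motivating case is budding yeast carrying mutated histone tails) certain
metabolic genes are expressed less than in the wild type.  The question this
package answers quantitatively is: *if those genes are down-regulated by a
measured amount, how much metabolic capability does the cell lose, and
where?*

Two families of integration methods exist.  *Switch-based* methods set the
bounds of low-expression reactions to zero — biologically harsh, since low
expression is not gene silencing.  *Valve-based* methods, which this package
implements, throttle instead of cut: the bounds of an affected reaction are
scaled down in proportion to the expression change.

## The valve model

Let $S$ be the stoichiometric matrix, $v$ the flux vector
(mmol gDW$^{-1}$ h$^{-1}$), and $c$ the objective (biomass) coefficients.
Flux balance analysis (FBA) solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; l \le v \le u .$$

Given per-gene log2 fold changes (mutant minus wild type) and a
significance call, the valve construction proceeds in three steps:

1. **Reference state.**  FBA optima are degenerate, so the wild-type flux
   vector is made unique by a parsimonious refinement: the objective is
   fixed at its optimum $f_{WT}$ and total absolute flux over *all*
   reactions is minimized.  This is the reference $v^{ref}$.
2. **Gene-to-reaction mapping.**  A gene is *significantly down* when its
   two-sided $p < \alpha$ (default 0.01, raw, no multiplicity correction)
   and its fold change is negative.  Every reaction whose
   gene–protein–reaction (GPR) rule mentions a significantly down gene
   receives the *most negative* fold change among those genes — the most
   conservative throttle when several down genes hit one reaction.
   Up-regulated genes are ignored entirely: widening a bound cannot change
   an FBA maximum.
3. **Valve scaling.**  A reaction with assigned fold change $FC \le 0$ gets
   the factor $\varphi = 2^{FC}$ (so $FC = -2$ leaves one quarter of the
   wild-type flux; $FC = 0$ leaves it untouched).  In the default **cap**
   mode the new bounds are $[0, \varphi v^{ref}_r]$ when $v^{ref}_r > 0$,
   $[\varphi v^{ref}_r, 0]$ when $v^{ref}_r < 0$, and $\varphi$ times the
   original bounds when $v^{ref}_r = 0$ (so the valve still bites on
   reactions the reference solution happens not to use).

Cap mode guarantees the constrained feasible set is a subset of the base
set, hence mutant growth never exceeds wild-type growth, and the empty
constraint set changes nothing.  A **fixed** mode that pins both bounds at
$\varphi v^{ref}_r$ — the most literal reading of "restrict the upper and
lower bounds to a fraction of the wild-type flux" — is kept as an option,
but it is not the default: simultaneously fixing many fluxes at scaled
values of one particular optimal vector generically yields an infeasible
model, which contradicts the observation the method is meant to reproduce
(down-regulation of histone-related metabolic genes is not lethal).

```{r valve}
toy <- make_toy_model("linear")
ref <- compute_reference_fluxes(toy$model)
cm  <- apply_valve_constraints(toy$model, ref, c(R_AB = -1))
c(wild_type = fba(toy$model)$objective, valved = fba(cm)$objective)
```

## The analysis layer

All analyses run on one deterministic LP backend, a dense bounded-variable
two-phase simplex with Bland's smallest-index pivoting rule
(`solve_lp()`).  One backend with a fixed pivot rule means flux vectors are
bit-reproducible run to run, and the solver returns the full COBRA-style
quartet: optimum $f$, fluxes $x$, shadow prices $y$, reduced costs $w$
(the duals are exposed, not interpreted).  Bland's rule is slower than
steepest-edge pricing but cannot cycle; the models this package targets are
small enough that robustness wins.  In the test suite the solver is checked
against an independent second solver (HiGHS) on hundreds of randomized
models.

On top of it:

* **FBA / carrying flux** — `fba()`, plus counts of reactions with
  $|v| >$ tol, split by sign (`count_carrying_flux()`).
* **FVA / capacity comparison** — per-reaction min and max flux with the
  objective held at a fraction of its optimum (`fva()`, default fraction
  1.0, i.e. "same optimal objective value").  `compare_capacity()` takes
  mutant-minus-wild-type capacity differences and lists subsystems with at
  least one gaining (increased) or losing (decreased) reaction; a
  subsystem with divergent members appears in both lists.
* **pFBA and six-way classification** — `pfba()` fixes the objective within
  $10^{-6}$ relative and minimizes $\sum |v_i|$ over gene-associated
  reactions (positive/negative flux splitting).  `classify_genes_pfba()`
  assigns every gene-associated gene one label, in priority order:
  *essential* (deletion drops growth below the cutoff), *blocked* (no
  reaction of the gene can ever carry flux, objective requirement removed),
  *pFBA optima* (carries flux in the parsimonious solution), *ELE* (could
  carry flux at optimal growth but the parsimonious solution idles it),
  *MLE* (can carry flux only below optimal growth), *pFBA no-flux*
  (anything left).  Under these definitions the last category is actually
  empty: a gene that is not blocked has a reaction with nonzero
  unconstrained range, and if the ELE test failed that range vanishes at
  optimal growth, which is the MLE condition.  The category is kept for
  fidelity with the classification's usual presentation.
* **Single-gene deletion** — GPR rules are re-evaluated with the gene
  absent; reactions whose rule turns false are clamped to zero and FBA is
  re-run.  "Essential" uses a growth-ratio cutoff (default 0.01) rather
  than the literal "growth is reduced", which would label nearly every
  flux-carrying gene essential in a constrained model; a strict
  any-reduction count is reported alongside it in the pipeline tables
  because published summaries sometimes show both.
* **Objective swaps** — `maximize_reaction_objective()` re-points the
  objective at a single reaction (forcing its lower bound to zero so only
  forward production is scored) to measure maximal attainable turnover,
  e.g. of the acetyl-CoA synthetase and carboxylase reactions whose flux
  ceilings proxy the acetyl-CoA pool feeding histone acetylation.

## The enzyme-centric network

`build_enzyme_network()` projects the model onto its genes: nodes are GPR
leaves; two genes are adjacent when they share a reaction or their
reactions share a metabolite.  Currency metabolites (ATP, NAD(H), water,
protons, ... — `currency_metabolites()`) are excluded before adjacency is
computed, otherwise they connect nearly everything to everything.  Genes
are used as nodes (rather than enzyme complexes or reactions); this is a
modelling choice, made explicit because "enzyme-centric" is used loosely in
the literature.

`compute_centralities()` implements the twelve hub indices of the
CytoHubba family (MCC, DMNC, MNC, Degree, EPC, BottleNeck, Eccentricity,
Closeness, Radiality, Betweenness, Stress, Clustering Coefficient), with
all conventions written out in its help page.  Conventions worth knowing:
distance-based indices are computed within connected components; closeness
is the sum of reciprocal distances (unreachable pairs contribute zero);
the DMNC exponent defaults to 1.7; EPC is a seeded Monte-Carlo mean (1000
realizations, retention 0.5) whose seed is part of the configuration, and
at retention 1 it equals the component size exactly; BottleNeck trees
break parent ties toward the smallest node id, so the whole table is
deterministic.  Ranking (`rank_and_flag()`) is descending except for
eccentricity (smaller is more central) with lexicographic tie-breaks, and
flags which members of a supplied gene set (typically the down-regulated
enzymes) fall in the top $k$ (default 100).

## Synthetic data: what it emulates, what it does not

`make_toy_model()` provides analytic fixtures (`linear`, `parallel`,
`shortlong`, `classify`) whose optima are derived by hand and shipped with
the fixture, plus seeded random branched networks whose backbone guarantees
feasibility with growth at least the uptake cap (default 10
mmol gDW$^{-1}$ h$^{-1}$).  `simulate_expression()` draws log2 values with
Gaussian per-gene baselines (mean 8, sd 1 — typical log2 microarray
intensity scale) and Gaussian sample noise, planting a chosen set of
down-regulated genes at a chosen log2 fold change.  Defaults (4 vs 4
samples, fold change $-2$, noise sd 0.5, 20 planted of 200 genes) give a
two-sample pooled-$t$ detection power of 0.924 at $\alpha = 0.01$
(noncentral $t$, ncp $= 5.66$, df $= 6$) — the regime where recovery is
expected but not trivial.  `end_to_end_fixture()` writes a complete bundle
(SBML + expression TSV + sample sheet + truth JSON); bundles use paired
noise (mutant samples reuse wild-type noise draws) so the observed fold
change equals the planted one exactly and the expected post-valve growth
has a closed form.

The generator simulates at the level the pipeline consumes:
already-normalized, gene-level log2 values with Gaussian noise.  It does
*not* emulate probe-level microarray artefacts, RNA-Seq count dispersion,
normalization failures, probe-to-gene collapsing, or correlated gene
expression.  Passing tests therefore demonstrate that the pipeline's
arithmetic and inference behave as designed under its stated input
contract — not that any upstream preprocessing of real array or sequencing
data is correct, which is out of scope.

## Numerical choices

* Flux-zero tolerance $10^{-9}$ for carrying-flux counts; $10^{-6}$ for
  classification and capacity comparisons (LP-level noise is below both).
* pFBA objective slack $10^{-6}$ relative; the valve *reference* solve uses
  zero slack so the reference flux of an analytic fixture is exact.
* Infinite SBML bounds are capped at $\pm 1000$ (configurable) on read:
  variability analysis needs finite ranges, and $\pm 1000$ is the
  conventional "unbounded" sentinel in published GSMMs.
* Genes with zero pooled variance cannot be $t$-tested; they get $p = 0$
  when the group means differ, $p = 1$ otherwise, and carry a flag.
* Ties in centrality ranking break lexicographically by node id; the EPC
  seed is recorded so reports are reproducible byte for byte.
* The $t$ test is Student's pooled-variance by default (the classic
  microarray-era choice); Welch is available via `var_equal = FALSE`, and
  Benjamini–Hochberg adjustment via `adjust = "BH"` (off by default, since
  the thresholding convention this package mirrors uses raw p-values).

Fold-change orientation is mutant minus wild type on the log2 scale, so
"down in the mutant" is negative and $2^{FC}$ shrinks mutant bounds — the
orientation the valve arithmetic forces regardless of which group a study
nominally labels "case".

## Problem sizes in the shipped tests

The test suite runs entirely on generated data: random LP-oracle
comparisons use 200 seeded models of up to 10 reactions; centrality
brute-force comparisons use 100 seeded graphs of up to 8 nodes (the sizes
at which exhaustive clique/path/subset enumeration is itself trustworthy);
differential-expression recovery uses 50 seeds of the 200-gene planted
design.  These sizes were chosen so each oracle is exact and the whole
suite stays fast; the package functions themselves have no hard size
limits, though the dense simplex is intended for models up to a few
hundred reactions rather than full genome scale.

## Known limitations

* The dense simplex is $O(m^3)$ per iteration; genome-scale models (~2000
  reactions) are parsed and represented fine, but LP analyses at that scale
  are slow.  The module boundary (`solve_lp()`) is the place to swap in a
  sparse backend.
* Valve integration conditions on one reference flux vector; reactions
  with zero reference flux are handled by the documented bound-scaling
  rule, but the choice of parsimonious reference is itself a convention.
* No GIMME/iMAT/MADE/RELATCH/INIT/mCADRE variants, no MOMA/ROOM, no double
  deletions, no dynamic FBA, and shadow prices / reduced costs are exposed
  without biological interpretation.
* The enzyme network uses name-matched currency-metabolite exclusion;
  models with nonstandard metabolite naming need an explicit exclusion
  list.
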