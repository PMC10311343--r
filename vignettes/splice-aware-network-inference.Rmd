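---
title: "Splice-aware causal network inference: model and methods"
author: "splinter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-aware causal network inference: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splinter)
```

## The problem

Exon skipping can remove an entire Pfam domain from a translated protein,
and with it every protein–protein interaction (PPI) that this domain
mediates. Enrichment-style analyses can say *that* splicing touches a
pathway; they cannot say *which* interactions upstream of the observed
transcriptional response are lost. `splinter` addresses the mechanistic
question: given (i) a domain-resolved interaction prior (every PPI broken
down into its constituent domain–domain interactions, DDIs, with the exons
and transcripts that map into each domain), (ii) transcription-factor (TF)
activities estimated from differential expression, and (iii) differential
exon-skipping (dPSI) or transcript-abundance (logFC) statistics, infer the
smallest coherent subnetwork that connects an upstream perturbation to the
significantly regulated TFs — while treating interactions through skipped
domains as impossible (hard mode) or expensive (soft mode).

## TF activity and its permutation null

For each TF regulon with matched targets $g_1,\dots,g_k$ and regulation
modes $m_i \in \{+1,-1\}$ the activity score is the signed,
$\sqrt{k}$-normalized sum

$$ s = \frac{1}{\sqrt{k}} \sum_{i=1}^{k} m_i \, t_{g_i}, $$

where $t_g$ is the differential statistic of gene $g$. This is the
standard mean-based simplification of regulon enrichment; the package's
contribution is not the scorer but the selection model downstream, so the
scorer is kept transparent. Significance, however, is assigned exactly as
specified for the workflow this package implements: the bipartite
TF→target graph is randomized (default 1000 permutations), preserving each
TF's out-degree by resampling its targets without replacement, and the
two-sided empirical p-value is

$$ p = \frac{1 + \#\{\,|s_{perm}| \ge |s_{obs}|\,\}}{n_{perm} + 1}, $$

with add-one smoothing so that $p \ge 1/(n_{perm}+1) > 0$. TFs with
$p \le 0.05$ (default) are *significant*; their prize in the selection
objective is $w_T = |s|$ — the sign is deliberately unused, because the
interaction prior carries no activation/inhibition annotation.

**Null universe.** Targets are resampled from the assayed gene universe
(every gene carrying a statistic), not merely from the union of regulon
targets. With one or few small regulons the union-of-targets null is
degenerate — each permutation reshuffles the same handful of statistics and
an extreme regulon can never look extreme. Resampling from the scored gene
space keeps the null calibrated for any regulon collection; a global
label-shuffling alternative (`null_model = "global"`) is exposed.

## From splice evidence to skipped domains

Exon- and transcript-level evidence is matched onto (protein, Pfam)
domains through the prior's mapping tables. For a domain with matched
p-values $p_1,\dots,p_j$ and effects $e_1,\dots,e_j$ (dPSI for exons,
clipped to $[-1,1]$; log2 fold change for transcripts):

* aggregated significance: Fisher's method,
  $p_{dom} = \Pr\!\left[\chi^2_{2j} \ge -2\sum_i \ln p_i\right]$
  (identity for $j = 1$);
* effect: the arithmetic mean $\bar e$;
* skip call: $p_{dom} \le$ `p_skip` (default 0.05, ties skipped) **and**
  $\bar e < 0$.

The direction requirement is a deliberate reading of "the sign tells the
direction of change": a *negative* dPSI/logFC means exclusion or loss of
the carrying transcript, which is the only direction that can remove a
domain; included exons and up-regulated transcripts never trigger a skip,
however significant. Exon and transcript evidence for one domain is pooled
into a single aggregation. Domains with no matched evidence are treated as
splice-unaffected — absence of evidence is not evidence of skipping.
P-values of exactly 0 are floored at $10^{-300}$ before the log transform.
A stricter variant (`strict_all = TRUE`) additionally requires every
matched feature to pass the threshold individually, for users who read
"all mapped exons skipped" per-feature; the aggregated rule is the
default because it is the one stated for the multi-feature case.

## The selection ILP

All candidate elements carry binary variables: proteins $y_P$, domains
$z_{P,m}$, DDI orientations $u_{d,\rightarrow},u_{d,\leftarrow}$, PPI
orientations $v$, root links $r_P$, TF terminals $t_T$; integer depths
$d_P \in [0,N]$ encode acyclic reachability. The objective, maximized:

$$ \sum_{T\,\text{sig}} w_T t_T \;-\; \alpha \sum_{T\,\text{not sig}} t_T
   \;-\; \lambda\Big(\sum y + \sum z + \sum u + \sum v\Big)
   \;-\; \beta \sum_{(P,m)} s_{P,m}\, z_{P,m}\ \text{(soft mode)} $$

with $s_{P,m} = \min(-\log_{10} p_{dom}, 300)$ for domains whose evidence
points in the exclusion direction. The constraints mirror the prose rules
of the method: a domain needs its protein; a DDI needs both endpoint
domains; a PPI is functional iff at least one constituent DDI is, in the
same orientation; each edge takes at most one orientation; every selected
protein needs a selected incoming directed PPI or an active perturbation
root link; depth differences forbid directed cycles (big-M = protein
count), so nothing can justify itself through a loop; a TF terminal
requires the TF protein plus an incoming PPI. Hard mode adds
$z_{P,m} = 0$ for every skipped domain, making any DDI with a skipped
endpoint infeasible; soft mode drops that constraint and lets the
$\beta$-scaled penalties compete with the TF prizes. For
$\beta \ge \sum_T w_T / \min s$, the soft optimum provably coincides with
the hard optimum whenever the penalized and skipped domain sets coincide —
a convergence the test suite checks on 30 scenarios.

Orientation is decided *per solution*: the prior is undirected (the
resource records no direction of regulation), so each undirected edge
expands into two mutually exclusive directed candidates and the program
picks the orientation that lets a root-to-TF flow exist. Non-significant
TFs are penalized only as reached terminals ($t_T$), not as pass-through
nodes; the model stays agnostic about intermediate proteins that happen to
be TFs.

Defaults: $\lambda = 0.01$ (small enough that any single-TF prize of
order 1 supports a path several proteins long, large enough to prune
free-riding edges), $\alpha =$ half the median significant prize (0.1 when
none), $\beta = \lambda$ (penalties on the regularization scale),
`soft_p_cut = 1` (all exclusion-direction evidence penalized in proportion
to its significance, per the "proportional to $-\log p$" rule).

### Root designation

The perturbation is an auxiliary node, never a protein; its links are
directed, protein-level, and cost-free. Explicit roots take precedence.
Otherwise, if the table carries directed annotations, roots are the
proteins with zero incoming annotated edges ("no upstream regulator"); on
a fully undirected prior that rule is undefined, so every non-TF protein
becomes a candidate root and the size regularization selects among them.
Self-interacting DDIs (both domains on one protein) are retained in the
container, flagged, and excluded from path search — they cannot mediate
regulation between distinct proteins.

### Solving and determinism

The package ships an exact branch-and-bound (`backend = "bnb"`): a
depth-first search over per-DDI orientation states with incremental
directed-cycle prevention, per-PPI orientation consistency, and the
admissible bound *total remaining prize − accumulated cost*. Because every
non-prize term of the objective is a cost, the bound prunes aggressively
and the empty network (objective 0) is always feasible, so a genuine
infeasibility signals a model bug. The backend contract is pluggable: any
function taking an instance may serve as solver, and instances export to
LP and MPS for cross-solver debugging.

Ties between equal-objective optima (within $10^{-12}$) are broken
deterministically toward the lexicographically smallest selected
directed-edge set under canonical edge ordering. This is enforced
procedurally in the incumbent comparison — of both the solver and the
exhaustive reference — rather than through a tiny secondary cost in the
objective, because no fixed $\epsilon$ can be guaranteed smaller than the
(instance-dependent) smallest true objective gap.

Certification is two-route: `solve_exhaustive()` enumerates *all* base-3
orientation assignments with its own feasibility and objective code and is
deliberately unoptimized; the suite and the acceptance script compare the
two routes on hundreds of seeded random instances (≤ 6 proteins, ≤ 8
DDIs — sizes at which full enumeration stays exact and fast) and require
exact agreement of objective and selected edge set. Every returned
solution also passes `validate_solution()`, an independent structural
certificate (endpoints selected, constituent DDIs present, acyclicity,
root reachability, no skipped domain in hard mode).

## Solution pools, consensus, differencing

Alternative optima are biologically meaningful: several domain routes may
explain the same TF response. `enumerate_solutions()` re-solves with
no-good cuts on the selected directed-edge sets (solver-agnostic, unlike
solver-internal solution pools) until `k_max` solutions, an objective drop
beyond `objective_tolerance` (default 0: optima only), or exhaustion; a
minimum-Hamming-distance option enforces stronger diversity. The consensus
network weights every DDI by its appearance fraction across the pool —
exact rational counts, tested as such. `diff_networks()` partitions the
DDIs of a splice-aware and a splice-unaware consensus into shared /
aware-only / unaware-only and flags unaware-only edges with a skipped
endpoint as *splice-abrogated*: interactions a splice-blind analysis
reports that the splice evidence contradicts.

## Over-representation of inferred nodes

Inferred node sets are scored against GMT gene-set collections with the
one-sided hypergeometric upper tail
$P(X \ge k)$ ($N$ universe genes, $K$ in the set, $n$ in the network, $k$
overlapping), reported as $-\log_{10} p$ enrichment scores. The default
universe is the prior's protein set — the network can only ever contain
those — and scores are left uncorrected (distributions are compared raw),
with an optional Benjamini–Hochberg column.

## What the synthetic scenarios emulate — and what they do not

`generate_scenario()` builds a layered, root-identifiable prior: a
guaranteed perturbation→…→TF chain (length ≤ 4), dead-end decoy proteins
hanging off the chain, optional random decoy–decoy edges
(`edge_density`, default 0.25), two exons and one transcript per domain.
TF regulons (20 targets) receive strongly signed statistics
(|stat| ~ U(2.5, 3.5) against N(0,1) background over 200 genes), so the
TF is reliably significant at 1000 permutations. Planted skips walk the
chain backwards from the TF-side domain of the final edge, with exon
evidence dPSI ~ −U(0.35, 0.6) and p ~ U(10⁻⁴, 5·10⁻³) — safely past the
0.05 skip call; optional weak decoy evidence exercises the non-skip path.
The default single skip therefore severs the unique path in hard mode
while leaving it optimal in a splice-unaware run — the miniature version
of the rewiring phenomenon, recovered across 50 seeds with flag precision
1.0 in the acceptance checks.

These scenarios establish *correctness of the machinery*, not performance
on real data: they have a unique true path, noise-free prizes, and
unambiguous skip evidence. Real priors are larger by orders of magnitude,
have correlated evidence, isoform-shared exons and many near-optimal
routes; on such data the solution pool and consensus weights, not any
single network, are the interpretable output.

## Problem sizes, tolerances, degenerate inputs

The bundled certification uses 200 random instances (≤ 6 proteins, ≤ 8
DDIs), 50 rewiring scenarios and 30 convergence scenarios of 8 proteins
each — sizes chosen so exhaustive enumeration remains an exact oracle and
a full run stays in the minutes range on one CPU. Numerical comparisons
use $10^{-12}$ for objective equality (sums of order-1 doubles),
$10^{-9}$ against the Fisher closed form, and exact equality for
consensus-weight rationals. Degenerate inputs are defined, not errors: no
significant TF → empty network; all evidence blocked in hard mode → empty
network; flat statistics → empirical p = 1; a domain without evidence →
never skipped. The branch-and-bound is exponential in the worst case and
intended for priors up to tens of DDIs; larger instances should go to an
external MILP solver through the backend contract and the LP/MPS export.

## Interface shape

The package follows the classic modelling idiom: `splinter()` is the one
fitting entry point returning a classed object with `print`, `summary`,
`plot`, `coef` and `as.data.frame` methods; the module-level functions
(`tf_activity()`, `call_skipped_domains()`, `build_ilp()`, `solve_ilp()`,
`enumerate_solutions()`, `consensus_network()`, `diff_networks()`,
`ora_collection()`, `generate_scenario()`) remain exported for scripted
pipelines, and a thin command-line wrapper (`inst/exec/splinter`) maps
subcommands 1:1 onto them.

## Known limitations

* No direction-of-regulation (activation/inhibition) inference — the
  prior carries none.
* The TF scorer is a simplified regulon enrichment; shadow/pleiotropy
  analysis of full-featured activity inference is out of scope.
* The built-in solver is exact but not industrial; very large priors need
  an external backend.
* Consensus weights are frequencies over an enumerated pool, not
  posterior probabilities.
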