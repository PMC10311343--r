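# splinter

Splice-aware causal network inference from domain-resolved interaction
priors.

## The problem

Exon skipping can delete a Pfam domain from a translated protein and, with
it, every protein–protein interaction (PPI) that domain mediates. Methods
that reconstruct signalling networks upstream of regulated transcription
factors (TFs) from expression data alone are blind to this: they happily
report interactions through domains that the splicing data say are gone.
`splinter` is for analysts who have, for one perturbation-vs-control
comparison:

* a **domain-resolved interaction prior** — PPIs decomposed into
  domain–domain interactions (DDIs), with the Ensembl exons/transcripts
  mapping into each Pfam domain;
* **TF regulons** and per-gene **differential expression statistics**;
* differential **exon-skipping (dPSI)** and/or **transcript-abundance
  (logFC)** statistics.

It infers the smallest coherent subnetwork connecting an upstream
*Perturbation* node to the significantly regulated TFs, treating
interactions through skipped domains as infeasible (**hard mode**) or
penalized (**soft mode**), and then shows what a splice-blind analysis
would have claimed that the splice evidence contradicts.

## The model in brief

1. **TF activity.** For a regulon with $k$ matched targets,
   $s = \tfrac{1}{\sqrt{k}}\sum_i m_i t_{g_i}$ (modes $m_i = \pm 1$);
   significance from randomizing the bipartite TF→target graph (1000
   permutations, degree-preserving), $p = (1 + \#\{|s_{perm}| \ge
   |s_{obs}|\})/(n_{perm}+1)$; significant if $p \le 0.05$; prize
   $w_T = |s|$.
2. **Skipped domains.** Matched evidence per (protein, Pfam) domain is
   combined with Fisher's method, $p_{dom} = \Pr[\chi^2_{2j} \ge -2\sum
   \ln p_i]$, the effect is the mean dPSI/logFC; *skipped* iff
   $p_{dom} \le 0.05$ and the mean effect is negative (exclusion).
3. **Selection ILP** (maximized):
   $\sum_{sig} w_T t_T - \alpha\sum_{nonsig} t_T - \lambda(\sum y + \sum z
   + \sum u + \sum v) - \beta \sum s_{P,m} z_{P,m}\,[\text{soft}]$,
   subject to: domains imply proteins, DDIs imply both endpoint domains, a
   PPI is functional iff a constituent DDI is (same orientation), one
   orientation per edge, every selected protein has a selected incoming
   directed PPI or an active root link, integer depths forbid cycles, and
   (hard mode) skipped domains are fixed to zero. Solved exactly by a
   built-in branch-and-bound; certified against exhaustive enumeration.
4. **Pools and consensus.** Alternative optima are enumerated with
   no-good cuts; every DDI gets a weight = appearance fraction across the
   pool. Differencing the splice-aware vs splice-unaware consensus flags
   *splice-abrogated* interactions.
5. **ORA.** Inferred node sets are scored against GMT collections with the
   hypergeometric upper tail, reported as $-\log_{10} p$.

## Worked example

Everything below runs from a bundled synthetic scenario: an 8-protein
prior with a guaranteed perturbation→TF chain, a 20-target regulon with
strongly signed statistics, and one planted skipped domain on the TF side
of the final chain edge.

```r
library(splinter)

scn <- generate_scenario(seed = 7)
cmp <- compare_splice_modes(scn$records, scn$regulons, scn$gene_stats,
                            scn$evidence, roots = scn$roots,
                            n_perm = 1000, seed = 7)
cmp
#> Splice-aware vs splice-unaware comparison
#>   aware consensus: 0 DDIs   unaware consensus: 3 DDIs
#>   shared: 0  aware-only: 0  unaware-only: 3
#>   splice-abrogated DDIs: 1

cmp$unaware$tf_activity
#>    tf n_targets   score empirical_p significant  weight
#> 1 TF1        20 13.7224 0.000999001        TRUE 13.7224

cmp$aware$domain_skips
#>   protein  domain aggregated_p mean_effect n_features skipped
#> 1     D01 PF00051 0.6924661069 -0.08305986          1   FALSE
#> 2     D02 PF00061 0.9900159635 -0.09825908          1   FALSE
#> 3     TF1 PF00041 0.0000192961 -0.47553613          2    TRUE

subset(cmp$diff, splice_abrogated, select = c(key, weight_unaware, status))
#>                       key weight_unaware       status
#> 3 P03|PF00031|TF1|PF00041              1 unaware_only
```

Reading this: the TF scores far outside its permutation null
(p = 1/1001), so the splice-unaware fit connects the perturbation to it
through the three-edge chain, each edge in all (here: the single) optimal
solutions, weight 1. The domain `TF1:PF00041` is called skipped
(aggregated p ≈ 1.9e-5 from two exons, mean dPSI ≈ −0.48), so the
hard-constrained splice-aware fit cannot reach the TF at all and returns
the empty network; the differencing reports exactly the final chain edge
as splice-abrogated — the planted ground truth.

A command-line wrapper over the same functions is installed at
`exec/splinter` inside the package (subcommands `simulate`, `infer`,
`compare`, `ora`).

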