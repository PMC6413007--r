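# MolTopo

MolTopo is an R package for building combinatorial molecular libraries from
SMILES fragments and screening them with topological QSAR models. It is
aimed at molecular-topology practitioners who want the whole cascade —
R-group enumeration, descriptor calculation and model evaluation — in one
scriptable place, without a web front end or proprietary descriptor
software.

Three layers:

1. **Library builder.** A base scaffold carries indexed anchor points
   `[R1]`…`[Rk]`; each position has an ordered list of substituent
   fragments, each with a single `[R]` attachment marker (the
   marker-adjacent atom is the attachment atom; the marker itself
   contributes no atom). `enumerateLibrary()` assembles the full Cartesian
   product, renumbers ring closures so no digit is reused while open,
   validates every product and writes standard `.smi` files. Fragment
   faults (missing/duplicated markers, unparseable SMILES) are reported as
   data, not crashes.
2. **Descriptors** from the hydrogen-suppressed molecular graph:
   * Kier–Hall connectivity indices up to fourth order,
     `^mχ_t = Σ_s Π_{v∈s} (δ*_v)^{-1/2}` over path, cluster and
     path-cluster subgraphs, with simple (`δ`) and valence (`δ^v`) weights,
     where `δ^v = Z^v − h` for second-period atoms and
     `(Z^v − h)/(Z − Z^v − 1)` beyond;
   * quotient and difference combinations `C^mχ_t`, `D^mχ_t` of the simple
     and valence index (orientation is a documented, switchable
     convention);
   * Galvez topological charge indices `G_k`, `J_k` from `M = A·Q` with
     `q_ij = d_ij^{-2}`;
   * Wiener index `W = Σ_{i<j} d_ij` and constitutional counts (`V1..V4`
     vertex-degree counts, rings, element counts);
   * hyper-detour index `ww = ½ Σ (Δ_ij + Δ_ij²)` over longest-simple-path
     distances (computed exactly by biconnected-block decomposition);
   * electrotopological `MAXDN`, mass-weighted Burden-matrix eigenvalues
     (`BELm5`) and the adjacency principal-eigenvector sum `VEA1`.
3. **QSAR layer.** `LinearQsarModel` objects hold an intercept, named
   coefficients and an optional applicability window; `screenLibrary()`
   runs the two-model cascade (discriminant score → window classification →
   affinity prediction for actives → activity tiers). Generic machinery
   (`ldaFit`, `mlrFit`, `looQ2`, `yScramble`, `classMetrics`, `pdd`) covers
   discriminant/regression fitting with priors, leave-one-out validation,
   response scrambling and pharmacological distribution diagrams.

The package ships a worked screening study: a 6120-member dioxopiperazine
library (four anchor positions with 5, 8, 9 and 17 substituents, as
published for formylpeptide-receptor ligands) plus the two published linear
models — a discriminant function `DF = 245.5 − 296.2·C¹χ + 50.2·D⁴χ_pc −
0.0034·W + 4.4·V4` with applicability window (0, 8), and an affinity model
`Log k_i = 76.50 + 0.000033·ww − 9.50·MAXDN − 15.68·BELm5 − 3.18·GGI10 −
5.12·VEA1` (thresholds: active below 2.60 ≙ 400 nM, highly active below
1.0 ≙ 10 nM). The base scaffold is published only as a drawing, so the
packaged transcription is explicitly labelled synthetic
(`inst/extdata/fpr_scaffold_synthetic.yaml`); see the methods vignette for
what that implies.

## Worked example

```r
library(MolTopo)

spec <- librarySpec(
  "[R1]N1CCN(CC1)C(=O)[R2]",
  list(R1 = data.frame(code = c("A", "B"), name = c("benzyl", "propyl"),
                       smiles = c("[R]CC1=CC=CC=C1", "[R]CCC")),
       R2 = data.frame(code = c("A", "B", "C"),
                       name = c("phenyl", "methoxyphenyl", "butyl"),
                       smiles = c("[R]C1=CC=CC=C1", "[R]C1=CC=C(OC)C=C1",
                                  "[R]CCCC"))))
mols <- enumerateLibrary(spec)
out  <- screenLibrary(mols, fprDiscriminantModel(), fprAffinityModel())
out$records[, c("id", "DF", "probA", "class")]
#>   id      DF     probA        class
#> 1 AA -103.35 1.302e-45 unclassified
#> 2 AB  -94.75 7.089e-42 unclassified
#> 3 AC  -86.33 3.211e-38 unclassified
#> 4 BA  -87.42 1.078e-38 unclassified
#> 5 BB  -81.56 3.801e-36 unclassified
#> 6 BC  -64.19 1.327e-28 unclassified
out$summary
#>    nTotal   nActive nModerate     nHigh
#>         6         0         0         0
```

The six piperazine amides enumerate as `AA`…`BC` (first anchor most
significant, last varies fastest). Every DF score falls far below −8, i.e.
outside the discriminant's applicability domain, so all six are
`unclassified` and no affinity prediction is made — the cascade only
predicts `Log k_i` for molecules the discriminant places in the (0, 8)
active window. `probA` is the logistic model-posterior convention attached
to the score, and `nModerate`/`nHigh` count predicted actives below the
2.60 and 1.0 thresholds.

Per-molecule descriptors are a data.frame away:

```r
d <- computeDescriptors(mols[1:2])
round(unlist(d[1, c("chi1", "Cchi1", "Dchi4pc", "W", "ww", "MAXDN",
                    "BELm5", "G10", "VEA1")]), 4)
#>      chi1     Cchi1   Dchi4pc         W        ww     MAXDN     BELm5
#>   10.3265    1.3891    1.3187 1056.0000 9427.0000    1.5186    0.8435
#>       G10      VEA1
#>    0.0207    4.1107
```

A command-line interface wrapping the same functions is installed at
`inst/cli/moltopo` (subcommands `build`, `calc`, `screen`, `fixtures`; the
`--chi-quotient`, `--chi-difference` and `--burden-aromatic` flags expose
the descriptor-convention toggles, and every run logs the conventions in
effect).

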