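# phylodwell

Phylogenetic comparative analysis of dwelling size and post-marital
residence in pre-industrial societies.

## The problem

Where a couple lives after marriage — with the husband's kin
(patrilocality), the wife's kin (matrilocality), or neither — shapes much
of a society's social organization, but leaves almost no direct trace in
the archaeological record. Cross-cultural work has repeatedly found that
agricultural societies with large dwellings tend to be matrilocal while
small-dwelling societies tend to be patrilocal, suggesting average house
floor area (AHFA) as a material proxy for residence. Societies are not
independent data points, however: they inherit both houses and residence
rules from common ancestors (Galton's problem). `phylodwell` implements
the comparative toolkit needed to test the AHFA–residence association
while controlling for shared ancestry on a time-calibrated phylogeny, for
anthropologists and archaeologists working with Ethnographic-Atlas-style
data.

## What it computes

* **Trait recoding** — raw D-PLACE/Ethnographic Atlas codes to analysis
  variables: `ln(AHFA)` and a small/large split at 65 m²; the EA012
  residence code reduced to a five-state ordinal "tendency towards
  matrilocality" and a matrilocal/non-matrilocal binary; agriculture
  (EA028), settlement fixity (EA030) and wall-material durability
  (EA081, with the EA083 roofing fallback) dichotomized.
* **Phylogenetic signal** — Pagel's λ for continuous traits by profile
  maximum likelihood over the covariance
  `V(λ) = λ C + (1 − λ) diag(C)`, with a likelihood-ratio test against
  λ = 0; Fritz–Purvis D for binary traits,
  `D = (d_obs − mean d_B) / (mean d_R − mean d_B)`, scaled against
  tip-permutation (`d_R`) and Brownian-threshold (`d_B`) nulls so that 1
  means phylogenetically random and 0 Brownian-like.
* **PGLS** — generalized least squares
  `β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y` with residual λ estimated by ML, overall
  F-test, adjusted R², and AIC model comparison.
* **Ancestral states** — GLS/BLUP reconstruction of continuous traits
  under Brownian motion (the root is the phylogenetic mean
  `(1ᵀC⁻¹x)/(1ᵀC⁻¹1)`), with per-branch linear gradients exported
  numerically.
* **Correlated evolution** — Pagel's (1994) test: a 4-state Markov chain
  over the joint states of two binary traits, comparing the independent
  (4-rate) against the dependent (8-rate) model by a likelihood ratio on
  χ²(4), plus one-way-dependent (6-rate) models ranked by AIC to address
  the direction of dependence. The pruning likelihood is implemented in
  C++.
* **Synthetic studies** — a generator producing pure-birth trees and
  trait data with known regression effects, signal strength and
  transition rates, used as ground truth throughout the test suite.

## Worked example

```r
library(phylodwell)
study  <- simulate_study(study_config(seed = 42))   # 86 societies
bundle <- run_all(study$tree, study$records, seed = 42)
print(bundle)
```

```
Dwelling-size comparative analysis: 86 societies

Phylogenetic signal:
     variable statistic estimate p_value p_brownian
1    ahfa_log    lambda    0.344  0.0047         NA
2     pmr_ord    lambda    1.000  0.0000         NA
3 agriculture         D    0.079  0.0000      0.374
4  settlement         D    0.328  0.0000      0.092
5    material         D    0.492  0.0000      0.006

Model comparison (best by AIC flagged):
                                                      model  n    f_p_value  r2_adjusted      aic  best
1                                        ahfa_log ~ pmr_ord 86 2.514230e-01  0.003910517 251.2778 FALSE
5                                     ahfa_log ~ settlement 86 8.946044e-11  0.388288358 212.5793 FALSE
7                           ahfa_log ~ pmr_ord + settlement 86 5.516518e-12  0.451652771 208.7117  TRUE
...

Root house area: 3.68 log-m2 = 39.7 m2
Root residence ordinal: 1.31 (0 = patrilocal, 4 = matrilocal)

Correlated evolution: LR = 8.530, p = 0.07399, best model: dep_x
```

Reading the output: the signal table pairs each variable with its
statistic (λ near 0 = no phylogenetic structure; D near 0 = clumped as
under Brownian evolution, near 1 = random). The model table ranks the
candidate regressions of log house area; here the generating model's
residence + settlement structure is recovered as the lowest-AIC row. The
ancestral-state block reports the inferred root values (house area
back-transformed to m²), and the last line gives the
correlated-evolution likelihood-ratio test with the best-fitting
dependence structure by AIC.

On real data, supply a Newick tree whose tips are society identifiers
and a CSV with columns
`society_id, ahfa_m2, ea012, ea028, ea030, ea081, ea083`:

```r
bundle <- run_all("tree.nwk", "societies.csv", seed = 1, out_dir = "results/")
```

or from the shell:

```sh
Rscript inst/scripts/phylodwell-run.R --tree tree.nwk --data societies.csv --out results/
```

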