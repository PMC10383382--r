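# pfasqsar

QSAR and read-across modelling of PFAS binding to human serum albumin.

Per- and polyfluoroalkyl substances (PFAS) bind human serum albumin (HSA),
the main blood transport protein, and that binding drives their
bioaccumulation. This package re-implements, as tested R code, a complete
in-silico workflow for modelling HSA binding affinity (EC50, mM) of PFAS
from 2D structure: topological descriptor calculation from SMILES, a
classification QSAR (Fisher discriminant), a regression QSAR (MLR / PLS)
built with an exhaustive double cross-validation workflow for small
datasets, the full validation-metric battery, a standardization-based
applicability domain, and a generic similarity-weighted read-across scorer.
It is aimed at computational toxicologists and cheminformaticians who want
a scriptable, reproducible version of this modelling workflow — including
the 24-compound PFAS/HSA study dataset it was built around.

## The models

A compound is classed as high affinity (H) when its EC50 is at or below
1.45 mM, low (L) otherwise; the two fluorotelomer alcohols that do not bind
are always L. The frozen discriminant model scores

    ΔP = −14.668 + 33.651·Eig12_AEA(bo) + 0.378·DECC + 30.405·X4A

with scores above the potency threshold classed L and at/below classed H,
and the frozen regression model predicts

    EC50 (mM) = 24.427 − 23.551·PDI − 0.862·GATS8v − 0.607·MATS8m − 4.388·QED

Here `X4A` is the average Kier–Hall path connectivity of order 4, `DECC`
the dispersion of vertex eccentricities, `Eig12_AEA(bo)` the 12th-largest
eigenvalue of the bond-order-augmented edge adjacency matrix, `MATS8m` /
`GATS8v` the Moran (mass) and Geary (van der Waals volume) lag-8
autocorrelations, `PDI = Vx/SAtot` the packing density index, and `QED`
the quantitative estimate of drug-likeness. All seven are computed by this
package from SMILES (`descriptor_table()`), with brute-force oracle tests
backing each implementation.

The frozen equations are serialized contracts of the published models: the
descriptor values behind their coefficients came from a commercial
descriptor engine whose scaling conventions are not public, so published
per-compound predictions are reproduced from the published table, not by
pushing this package's descriptors through the frozen coefficients. To
model new data, fit fresh models on this package's descriptors with
`qsar_lda()`, `qsar_mlr()`, `qsar_pls()` or the full
`small_dataset_qsar()` workflow (pretreatment → genetic-algorithm subset
selection → exhaustive double cross-validation).

## Worked example

```r
library(pfasqsar)

## the bundled 24-compound study table
ds <- pfas_hsa_data()
#> qsar_dataset: 24 compounds ( 16 train / 8 test )

## descriptors for PFOA (compound C5), from its SMILES
descriptor_table(c(C5 = ds$records$smiles[ds$records$id == "C5"]))
#>   id    X4A   DECC Eig12_AEA_bo    PDI MATS8m GATS8v    QED
#> 1 C5 0.0943 1.0688            0 0.0128 0.0183 0.6768 0.7057

## recompute every published summary number from the bundled inputs
reproduce_study()
#> class split at threshold: H=11 / L=13  [ PASS ]
#> train set metrics [ PASS ]
#>          sensitivity specificity precision accuracy f_measure  mcc kappa g_means
#> computed        87.5         100       100    93.75     93.33 0.88  0.88   93.54
#> expected        87.5         100       100    93.75     93.33 0.88  0.88   93.50
#> test set metrics [ PASS ]  (all 100 / 1)
#> regression (published PLS predictions) [ PASS ]
#>              r2    mae  n
#> computed 0.8031 0.2045 22
#> expected 0.8020 0.2050 22
```

The class split (11 H / 13 L), the whole training/test metric table and the
regression quality (R² 0.803, MAE 0.205 mM over the 22 binders) all match
the published values.

The selection workflow itself is validated on synthetic data shaped like
the study (22 compounds, 30-descriptor pool, 4 true descriptors, 10%
noise):

```r
d <- make_descriptor_dataset(synthetic_spec(n = 22, pool = 30,
       true_idx = c(3, 9, 17, 25), beta = c(1.5, -2, 1, -1), seed = 7001))
res <- small_dataset_qsar(d$x, d$y, n_desc = 4)
res$selected
#> [1] "D3"  "D9"  "D17" "D25"     # the planted descriptors
```

A thin command-line front end over these functions lives in
`inst/cli/pfasqsar.R` (subcommands `descriptors`, `classify`, `regress`,
`validate`, `reproduce`, `correlate-docking`, `simulate`, `readacross`).

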