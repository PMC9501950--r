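# antiradical

Conceptual-DFT antiradical profiling and donor–acceptor maps in R.

## The problem

Whether a compound scavenges free radicals by *donating* or by *accepting*
an electron is decided, in the electron-transfer picture, by a handful of
energy differences. From the total electronic energies of a molecule's
neutral, cation and anion species (at the neutral geometry) one obtains the
vertical ionization potential and electron affinity,

    I = E(cation) − E(neutral)        A = E(neutral) − E(anion)

and from them the global conceptual-DFT reactivity descriptors

    η = (I − A)/2    χ = (I + A)/2    μ = −χ    S = 1/(2η)    ω = μ²/(2η)

together with the asymmetric charge-transfer propensities of Gázquez,
Cedillo and Vela,

    ω⁻ = (3I + A)² / 16(I − A)        ω⁺ = (I + 3A)² / 16(I − A)

Normalizing ω⁻ by sodium (an excellent donor) and ω⁺ by fluorine (an
excellent acceptor) gives the dimensionless indices **Rd = ω⁻/ω⁻(Na)** and
**Ra = ω⁺/ω⁺(F)**, whose scatter — the **donor–acceptor map (DAM)** —
classifies compounds as antioxidant-like electron donors or
anti-reductant-like electron acceptors. This package computes all of the
above from energy triplets or pre-computed I/A tables, compares gas-phase
and implicit-solvent values, ranks compounds by frontier-orbital (HOMO)
energies with a consistency check against the I order, and handles the
in vitro side of such studies: DPPH percent inhibition, IC50 estimation
(log-linear interpolation or a logistic fit) and descriptor–activity
Pearson correlation with residuals. A seeded synthetic-data generator
provides ground-truth inputs for every stage, so the whole pipeline is
testable without any quantum-chemistry run.

It is written for computational natural-product and medicinal chemists who
have DFT single-point energies (or published I/A tables) in hand and want
the descriptor/DAM/assay arithmetic done reproducibly, with conventions
made explicit.

## Worked example

The bundled reference panel holds published B3LYP/6-31+G(2d,2p) vertical
I/A values for three prenylated flavanones from *Erythrina crista-galli*
(lupinifolin, citflavanone, lonchocarpol A) and two standard antioxidants
(quercetin, ascorbic acid):

```r
library(antiradical)
panel <- flavanone_panel()
gas <- panel$ia[panel$ia$phase == "gas", ]
desc <- global_descriptors(gas$I_eV, gas$A_eV, convention = "replication",
                           compound_id = gas$compound_id)
desc[, c("compound_id", "I_eV", "A_eV", "eta_eV", "S", "chi_eV", "omega_eV")]
#>     compound_id I_eV  A_eV eta_eV     S chi_eV omega_eV
#>     lupinifolin 7.15  0.07  3.540 104.6  3.610   0.2395
#>    citflavanone 7.24 -0.01  3.625 102.1  3.615   0.2401
#>  lonchocarpol_A 7.24 -0.10  3.670 100.9  3.570   0.2342
#>       quercetin 8.03  2.99  2.520 146.9  5.510   0.5579
#>   ascorbic_acid 9.74  3.06  3.340 110.8  6.400   0.7526

dam <- build_dam_table(dam_points(desc))
dam[, c("compound_id", "omega_minus_eV", "omega_plus_eV", "Rd", "Ra",
        "sector_relative")]
#>             compound_id omega_minus_eV omega_plus_eV   Rd    Ra  sector_relative
#>           ascorbic_acid           9.75         3.349 2.81 0.985 acceptor-leaning
#>            citflavanone           4.06         0.448 1.17 0.132    donor-leaning
#>          lonchocarpol_A           3.98         0.410 1.15 0.121    donor-leaning
#>             lupinifolin           4.09         0.478 1.18 0.141    donor-leaning
#>               quercetin           9.09         3.584 2.62 1.054 acceptor-leaning
#>    Na (donor reference)           3.47         0.626 1.00 0.184             <NA>
#>  F (acceptor reference)          13.81         3.402 3.98 1.000             <NA>
```

Read: the flavanones have low electronegativity (χ ≈ 3.6 eV), low ω⁻
relative to the standards and Ra far below 1 — they sit on the donor
(antioxidant) side of the map, while quercetin and ascorbic acid (Ra ≈ 1)
are the better electron acceptors (anti-reductants). The hardness/softness
column ranks charge-transfer willingness: quercetin > ascorbic acid >
lupinifolin > citflavanone > lonchocarpol A.

The full pipeline (descriptors → DAM → phase shifts → FMO → assay →
correlation) runs from tabular inputs in one call, or from the command
line:

```r
dir <- system.file("extdata", "flavanone_panel", package = "antiradical")
bundle <- run_pipeline(ar_config(seed = 1),
                       ia_file = file.path(dir, "ia_values.csv"),
                       assay_file = file.path(dir, "assay.csv"))
bundle$phase_shift[, c("compound_id", "delta_I_eV", "delta_A_eV")]
#>      compound_id delta_I_eV delta_A_eV
#>     citflavanone      -1.48       1.75
#>   lonchocarpol_A      -1.26       1.75
#>      lupinifolin      -1.38       1.64
write_report_bundle(bundle, "out", format = "csv")
```

(Implicit methanol lowers every I and raises every A: the flavanones
become weaker donors and better acceptors in solution.) The CLI wraps the
same stages: `antiradical profile --ia-file ... --out-dir out`, plus
`phases`, `fmo`, `assay`, `correlate`, `synth` and `all`.

## Conventions worth knowing

Published descriptor tables in this area are often computed with ω = μ²/2
and S = 1/(2η) evaluated in *atomic units* and the bare number relabelled
"eV". `convention = "replication"` reproduces exactly that; `"standard"`
gives the literature definitions on the eV scale (ω = μ²/2η in eV,
S = 1/(2η) in eV⁻¹). Outputs carry the convention tag and the writers
refuse to mix them. See the methods vignette
(`vignettes/antiradical-methods.Rmd`) for the full account.
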