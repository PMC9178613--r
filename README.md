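# hydromelt

Analysis of wide-line ¹H NMR **melting diagrams** of frozen protein
solutions: the fraction *n* of mobile (motionally narrowed) water protons
as a function of temperature, measured while a rapidly frozen solution is
thawed slowly through equilibrium states. Melting diagrams discriminate
intrinsically disordered proteins (IDPs), whose mobile hydration grows
steadily with temperature, from globular proteins, which show a wide
plateau — and they quantify how much water is bound at which potential
barrier.

The package is aimed at structural biophysicists working with hydration
NMR data on disordered proteins (the shipped reference parameter sets are
the Parkinson's-disease-linked α-synuclein mutants A30P and E46K), and at
anyone who needs a well-tested segmented-curve fitter with exact amplitude
profiling.

## The model

Temperature is used on the normalized fundamental scale
`T_fn = T / 273.15` (ice melts at `T_fn = 1`), equivalently as a potential
barrier `E_a = 6.01 kJ/mol × T_fn` via the molar heat of fusion of ice.
The melting curve is piecewise:

```
n(T_fn) = 0                                        T_fn < T_fn0
        = A                                        T_fn0 <= T_fn < T_fn1
        = A + B (T_fn - T_fn1)                     T_fn1 <= T_fn < T_fn2
        = A + B (T_fn - T_fn1) + C (T_fn - T_fn2)² T_fn >= T_fn2
```

An *extended* variant adds a gradual onset ramp, a jump `delta` at the
plateau end and a second linear slope — features needed for E46K-type
diagrams. Fitting profiles the amplitudes out exactly (for fixed
breakpoints the problem is linear), locates breakpoints by grid search
plus local refinement, and is fully deterministic.

From a fitted curve the package derives hydration measures
(`h` g water/g protein, `naa` waters per residue, `W` waters per protein),
the differential melting diagram, an IDP/globular classification, and the
heterogeneity statistics `HeR = (1 − T_fn1)/(1 − T_fn0)`,
`HeR_n = n_he/(n_ho + n_he)` and `HeM = (B + 2C)/(1 − T_fn1)` of the
water-binding barrier distribution. A separate module aggregates
secondary-structure predictor tracks (DSSP 8→3 mapping, plurality vote,
minimum-run filter) and calls disorder regions from per-residue score
tracks. Seeded generators simulate every input with known ground truth.

## Worked example

Simulate an A30P-like melting diagram (40 points, noise σ = 5·10⁻⁴) and
run the full analysis:

```r
library(hydromelt)

wt   <- read_fasta(system.file("extdata", "alpha_synuclein_wt.fasta",
                               package = "hydromelt"))
a30p <- sample_info(apply_mutation(wt, "A30P"), concentration = 50)

truth <- md_params(A = 0.0156, B = 0.24, C = 50,
                   T_fn0 = 0.824, T_fn1 = 0.879, T_fn2 = 0.959)
md  <- gen_md(truth, grid = seq(0.80, 1.00, length.out = 40),
              sigma = 5e-4, seed = 1, sample = a30p)
fit <- md_fit(md)
fit
#> Piecewise melting-curve parameters (standard variant)
#>  parameter    value        se
#>          A  0.01564 0.0001123
#>          B  0.23690 0.0024370
#>          C 51.15869 0.2654137
#>      T_fn0  0.82308        NA
#>      T_fn1  0.87825        NA
#>      T_fn2  0.95930        NA
#> RSS = 6.67e-06 on 40 points
```

The fit recovers the generating parameters (plateau within 0.3%, all
breakpoints within 0.001). The diagram is classified and summarised:

```r
md_classify(fit)
#> [1] "IDP-like"

het_report(fit, sample = a30p)
#> Water-binding heterogeneity report (standard variant)
#>   n_ho       0.01564
#>   n_he       0.1136
#>   naa_ho     0.8982
#>   naa_he     6.524
#>   h_ho       0.3127
#>   h_he       2.272
#>   HeR        0.6882
#>   HeR_n      0.879
#>   HeM        842.3
#>   homogeneous 31%
```

Read: the homogeneously bound water (`h_ho ≈ 0.31` g/g, `naa ≈ 0.9` waters
per residue, ~126 waters per protein) is about one monolayer — enough for
function — while ~88% of the mobile water at 0 °C is bound across a
heterogeneous spread of potential barriers (`HeR_n = 0.879`), the
signature of a disordered, solvent-exposed chain. Only 31% of the barrier
distribution is homogeneous:

```r
hydration_from_n(fit$A, a30p, tfn = fit$T_fn0)
#>        T_fn      E_a         t          n         h       naa        W
#> 1 0.8230769 4.946692 -48.32654 0.01563733 0.3127467 0.8981621 125.7427
```

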