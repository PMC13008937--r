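# mrmediate

Two-sample Mendelian randomization (MR) with two-step mediation, built for
proteome-wide screens against a rare binary outcome.

## The problem

Plasma proteins are attractive causal candidates for cancer risk, but
observational protein–disease associations are confounded and can run in
reverse (the tumour changes the proteome). `mrmediate` implements the causal
chain used to screen thousands of protein exposures against a disease
endpoint with genetic instruments, and to ask how much of a protein's effect
is transmitted through an intermediate immune phenotype:

1. **Instrument selection** — variants associated with the exposure at
   `p < 1e-5`, greedily LD-clumped (r² 0.001, 10,000 kb window).
2. **Harmonization** — outcome effects aligned to the exposure's effect
   allele, with palindromic (A/T, C/G) variants resolved by allele frequency
   or dropped.
3. **Five estimators** — inverse-variance weighted (IVW, the primary
   analysis), MR-Egger (slope + pleiotropy intercept), weighted median, and
   simple/weighted mode, each reported as `OR(95%CI)` with
   `OR = exp(beta)`, `CI = exp(beta ∓ 1.96·se)`.
4. **Sensitivity** — Cochran's Q, leave-one-out IVW, reverse MR (outcome as
   instrument source; exposures are retained only when the reverse p-value
   exceeds 0.05), and a direction-consistency filter requiring all five
   estimators to agree in sign.
5. **Two-step mediation** — with IVW estimates of the total effect
   `α_total` (exposure→outcome), `α₁` (exposure→mediator) and `α₂`
   (mediator→outcome):

   ```
   α_mediated = α₁ · α₂                     (product of coefficients)
   α_direct   = α_total − α_mediated
   proportion = α_mediated / α_total × 100%
   se(α_mediated) = sqrt(α₁²·se₂² + α₂²·se₁²)   (first-order delta method)
   ```

A seeded synthetic GWAS generator (`sim_config()`, `simulate_triple()`,
`null_registry()`, `simulate_screen_registry()`) draws summary statistics
under a known causal diagram — including the study-shaped configuration of a
large proteomic exposure GWAS (n = 35,559), a small immune-phenotype mediator
GWAS (n = 3,757) and a rare outcome (126 cases / 412,055 controls) — so every
stage can be tested against ground truth. An individual-level simulator
(`simulate_individual_oracle()`) serves as an independent cross-check of the
summary-level sampler.

GWAS summary statistics are read from tab-delimited text (plain or gzip) in a
generic dialect or the FinnGen column dialect (`#chrom, pos, ref, alt, rsids,
af_alt, beta, sebeta, pval`, with `alt` as effect allele).

## Worked example

```r
library(mrmediate)

cfg <- sim_config(m_snps = 20, h2_x = 0.1,
                  theta_xm = 0.4, theta_md = 0.5, theta_xd = 0.8,  # 20% mediated
                  n_cases = 50000, n_controls = 50000, seed = 42)
tri <- simulate_triple(cfg)

iv  <- clump(tri$exposure, select_instruments(tri$exposure))
h   <- harmonize(tri$exposure, tri$outcome, iv)
fit <- mr_fit(h, n_boot = 200, seed = 3)
print(fit)
#> Two-sample MR fit: X -> D (16 instruments)
#>           method n_snp   beta     se      pval          OR(95%CI)
#>              ivw    16 0.9864 0.0206  0.00e+00 2.682(2.575-2.792)
#>            egger    16 1.0020 0.0433 2.92e-118 2.724(2.502-2.965)
#>  weighted_median    16 0.9749 0.0257  0.00e+00 2.651(2.520-2.788)
#>      simple_mode    16 1.0153 0.0516  2.74e-86 2.760(2.495-3.054)
#>    weighted_mode    16 0.9840 0.0260  0.00e+00 2.675(2.542-2.815)

med <- mediation_pipeline(tri$exposure, tri$mediator, tri$outcome)
print(med)
#> Two-step MR mediation
#>   total effect      alpha_total    =   0.9864 (se 0.0206)
#>   exposure->mediator alpha_1       =   0.4710 (se 0.0533)
#>   mediator->outcome  alpha_2       =   0.5049 (se 0.0694)
#>   mediated effect   alpha_mediated =   0.2378 (95% CI 0.1548 to 0.3208)
#>   direct effect     alpha_direct   =   0.7486
#>   proportion mediated: 24.11% of the total effect
#>   instruments per leg: exposure->outcome=16, exposure->mediator=16, mediator->outcome=6
```

The fitted total effect (0.99 ± 0.02, true value 1.0) and mediated proportion
(24% against a true 20%, within simulation error at one replicate) illustrate
the scale of estimate and uncertainty the pipeline produces. All five
estimators agree in direction (`direction_consistency(fit)` is `TRUE`), and
`leave_one_out(h)` flags no single influential instrument.

The screening surface (`screen_exposures()`, `screen_mediators()`,
`screen_pipeline()`) runs this chain over registries of many exposures and
candidate mediators with the forward (`p < 0.01`), reverse (`p > 0.05`) and
direction-consistency filters. `h_score()` computes the immunostaining
H-score (`1·%weak + 2·%moderate + 3·%strong`, range 0–300) used for tissue
validation readouts.

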