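# crmkit

Tools for decoding the cis-regulatory logic of enhancers and silencers
from DNA sequence and dual-luciferase reporter assays, built around the
workflow used to dissect the regulatory modules of a lineage-determining
myeloid gene: annotate transcription-factor binding sites, predict
construct activity with a sequence-based thermodynamic model, design
site-killing mutations in silico, infer activator/repressor roles by
ensemble fitting, and turn raw Firefly/Renilla luminescence into
fold-changes with robust statistics.

It is aimed at groups running transient reporter assays on candidate
cis-regulatory modules (CRMs) who want model-guided mutagenesis and
statistically sound normalization in one place.

## The models at the core

**Thermodynamic activity model.** Binding configurations σ over annotated
sites carry Boltzmann weights W(σ) = Π K·q·ν (binding scale × relative
affinity × TF concentration, with optional cooperativity factors ω), with
overlapping sites mutually exclusive. Site occupancies O_i are
partition-function fractions computed by dynamic programming. Repressors
quench activator occupancy within ~150 bp, O_eff = O·Π(1 − γO_rep), and
repress dominantly at any distance by scaling the interaction strength
E = Σ α·O_eff to E′ = E·Π(1 − β_R·O_rep). Initiation is enzymatic:
r = R_max·exp(−max(0, θ − E′)). Fold-changes are always relative to the
promoter-only construct.

**Robust errors-in-variables normalization.** Firefly (y) is regressed on
Renilla (x) through the origin; the residual is the orthogonal distance
d_i = (1+β²)^(−1/2)(y_i − βx_i); Tukey's biweight (c = 4.7) bounds
outlier influence, and the residual scale S solves the M-scale equation
mean χ(d_i/S) = κ with χ the biweight at c = 1.56 and κ = 0.05 (an
S-estimate of the slope followed by a fixed-scale M-step). Confidence
intervals come from the basic bootstrap over 999 pair resamples.

## Worked example

Plant an activator (CEBP) and a repressor (GATA) site in a synthetic CRM,
scan it, kill the activator site, and compare predicted activity:

```r
library(crmkit)
counts <- rbind(c(91,3,3,3), c(3,91,3,3), c(3,3,91,3),
                c(3,3,3,91), c(91,3,3,3), c(3,91,3,3))
cebp <- alignment_matrix(counts, "CEBP")                 # consensus ACGTAC
gata <- alignment_matrix(counts[c(3,3,1,4,1,2), ], "GATA")  # consensus GGATAC
enh <- simulate_crm(250, list(list(matrix = cebp, position = 40, strand = "+"),
                              list(matrix = gata, position = 160, strand = "+")),
                    seed = 101, id = "crm7")$crm
prom <- crm_record("prom", strrep("A", 80), "promoter")
sites <- scan_sites(enh, list(cebp, gata), q_min = 0.05)
sites
#>     tf start end strand site_seq q      llr
#> 1 CEBP    40  46      +   ACGTAC 1 7.665963
#> 2 GATA   160 166      +   GGATAC 1 7.665963
#> 3 CEBP   195 201      -   ACGTAC 1 7.665963
```

Both planted sites are recovered at relative affinity q = 1 (plus a
chance CEBP match the random background happened to contain — exactly the
kind of site a re-scan must keep an eye on). Now the model and the
mutant:

```r
conc <- rbind(CEBP = c(1.0, 0.4), GATA = c(0.2, 1.5))
colnames(conc) <- c("uninduced", "induced")
spec <- thermo_spec(list(tf_spec("CEBP", "activator", alpha = 2),
                         tf_spec("GATA", "repressor", gamma = 0.7, beta_lr = 0.5)),
                    theta = 2, concentrations = conc)
tgt <- sites[sites$tf == "CEBP" & sites$q == 1, ][1, ]
plan <- design_site_mutation(enh, tgt, list(cebp, gata), q_min = 0.05)
plan
#> <mutation_plan> CEBP [40, 46) +: 6 edits, 0 fallback position(s)
mut <- apply_mutation_plan(enh, plan)
predict_mutant_series(prom, list(crm7 = enh, crm7m1 = mut), spec,
                      list(cebp, gata), spacer_bp = 1000)
#>   construct condition     fold
#> 1      crm7 uninduced 6.201981
#> 2      crm7   induced 1.580020
#> 3    crm7m1 uninduced 2.788637
#> 4    crm7m1   induced 1.279151
```

The wildtype CRM is a ~6-fold enhancer in the uninduced condition, driven
by the CEBP sites; killing one cuts the fold to ~2.8, and the
GATA-repressed induced condition barely moves — the signature of an
activator-site mutant. On the measurement side, normalize synthetic
luminescence (true slope ratio 11/2 = 5.5):

```r
lum <- rbind(simulate_luminescence(2, seed = 1, construct = "0")$table,
             simulate_luminescence(11, seed = 2, construct = "7")$table)
fold_change(lum, "7", "uninduced", "vs_same_condition_promoter",
            robust_config(), seed = 42)
#>   construct condition                       mode   value   ci_low  ci_high  n n_ref
#> 1         7 uninduced vs_same_condition_promoter 5.87654 5.166791 6.487827 10    10
```

The estimate 5.88 (95% CI 5.17–6.49) covers the true ratio 5.5 from ten
noisy replicates per group.

A YAML-driven entry point wires the stages for shell use:
`Rscript -e 'crmkit::run_pipeline("config.yml")'` (stages: scan, mutate,
predict, normalize, foldchange, qpcr, simulate; each run writes a
manifest with parameters, input digests, and seeds).

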