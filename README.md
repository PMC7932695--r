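# faidr — Function Analysis of Intrinsically Disordered Regions

Intrinsically disordered regions (IDRs) of proteins carry
sequence-distributed molecular features — isoelectric point, hydropathy,
compositions, repeats, short linear motifs — rather than alignable
conserved positions. Functional annotations, however, attach to whole
proteins, and a protein often contains several IDRs. `faidr` is for
computational biologists who want to predict biological function for
*individual* IDRs from per-IDR feature vectors (such as 164-dimensional
evolutionary-signature Z-scores) and protein-level binary annotations,
to infer *which* IDR of a multi-IDR protein carries each function, and
to identify the molecular features associated with it.

## The model

Protein labels are modelled as generated by exactly one responsible IDR,
indicated by a hidden one-hot variable X. The per-IDR probability is
logistic, *h*(Z) = 1 / (1 + e^(−(Zb + b₀))), and the marginal likelihood
over n proteins with rᵢ IDRs each is

    P(Y | Z, b) = ∏ᵢ Σⱼ P(Xᵢⱼ = 1) h(Zᵢⱼ)^Yᵢ (1 − h(Zᵢⱼ))^(1−Yᵢ),

with uniform prior P(Xᵢⱼ = 1) = 1/rᵢ. It is fitted by
expectation–maximization: the E-step computes posterior responsibilities
⟨Xᵢⱼ⟩ by Bayes' rule, and the M-step runs five truncated iterations of
IRLS for an elastic-net-penalized logistic regression (λ = 0.2,
α = 0.99 by default) in which each IDR row is weighted by its
responsibility — the modified IRLS weight is
wᵢⱼ = ⟨Xᵢⱼ⟩ h(Zᵢⱼ)(1 − h(Zᵢⱼ)). Selected features are then refit
unpenalized to obtain Wald t-statistics, which are filtered and
clustered (average linkage, uncentered correlation) into a
function × feature association map. See `vignettes/faidr-methods.Rmd`
for the full treatment.

## Worked example

Synthetic data with the exact generative structure the model assumes
(here 800 proteins, 20 features, 3 true effects of ±3):

```r
library(faidr)
sim <- generateSynthetic(nProteins = 800, mFeatures = 20,
                         supportSize = 3, effectSize = 3, seed = 1)
fit <- fitFaidr(sim@featureTable, sim@annotations, "synthetic",
                faidrControl(lambda = 0.05))
fit
#> FaidrFit for function 'synthetic'
#>   lambda = 0.05  alpha = 0.99
#>   3 of 20 features selected; intercept = -0.4189
#>   EM rounds: 11 (converged)
#>   penalized marginal log-likelihood: -0.693147 -> -0.613266
round(coef(fit)[coef(fit) != 0], 3)
#>  f003  f008  f012
#> 0.700 0.621 0.545
recoveryReport(sim, fit)[c("supportRecall", "signAgreement", "heldoutAuc")]
#> support recall 1.00, sign agreement 1.00, held-out protein AUC 0.830
```

The three selected features are exactly the generator's true support,
with correct signs; the penalized marginal log-likelihood rises
monotonically from the ln 2 of an empty model; 0.83 is the AUC of the
uniform-mixture protein score on a fresh draw from the same truth.

The sequence-feature calculators reproduce the Cox15 N-terminal
targeting-signal arithmetic from the DNA sequences shipped in
`inst/extdata/`:

```r
dna <- Biostrings::readDNAStringSet(
  system.file("extdata", "cox15_idr_variants_dna.fa", package = "faidr"))
wt <- translateDna(dna[[1]])
as.character(wt)
#> "MLFRNIEVGRQAAKLLTRTSSRLAWQSIGASRNISTIRQQIRKTQ"
c(pI = isoelectricPoint(wt), kd = meanHydropathy(wt))
#>    pI 12.40, kd -0.49
lowpi <- substituteResidues(wt, c(R = "E"))   # arginine -> glutamate
c(pI = isoelectricPoint(lowpi), kd = meanHydropathy(lowpi))
#>    pI 4.04, kd -0.33
```

Mutating every arginine to glutamate collapses the isoelectric point
from 12.40 to 4.04 — an 8.4-unit shift — while moving mean
Kyte–Doolittle hydropathy by only 0.16: the two features are
independently tunable, which is what makes them separately testable
determinants of mitochondrial targeting.

## Command line

A thin wrapper over the package functions is installed at
`system.file("scripts", "faidr", package = "faidr")`:

```sh
faidr simulate --n 2000 --m 164 --support 10 --effect 2 --seed 1 --out-prefix sim
faidr fit --features sim_features.tsv --annotations sim_annotations.tsv \
      --function synthetic --lambda 0.2 --out fit.json
faidr predict --fit fit.json --features sim_features.tsv --level protein --out p.tsv
faidr cv --features sim_features.tsv --annotations sim_annotations.tsv \
      --function synthetic --folds 5 --seed 1
faidr seqfeat --fasta seqs.fa --features pI,kd_hydropathy,frac_R --out feat.tsv
```

All tabular I/O is TSV (comma auto-detected on input); fits serialize to
versioned JSON; identical commands with identical seeds produce
byte-identical output.

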