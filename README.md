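# pgxdip

Star-allele diplotype inference and pharmacogenomic annotation from a
single-sample germline VCF (GRCh38).

## The problem

Pharmacogenes occur as named *star alleles* (haplotypes): curated sets of
variants on one chromosome copy. A person's drug-relevant genotype is a
*diplotype* — an unordered pair of star alleles such as `UGT1A1 *28/*28`.
Short-read sequencing yields an unphased VCF, so several diplotypes can be
consistent with — or even indistinguishable from — the observed genotypes,
and real data add missing positions and artifact calls. pgxdip is for
bioinformaticians who need to turn such a VCF plus a population label into
per-gene diplotype calls, prescribing categories and predicted drug-response
phenotypes.

## The method

For each gene with haplotypes *h₁…h_H*, all H(H+1)/2 unordered pairs are
candidates. Each candidate's *combined definition* gives the expected
unordered allele pair at every position declared by any haplotype of the
gene. Candidates are scored against the observed genotypes:

| locus type | observed = expected | observed ≠ expected |
|---|---|---|
| declared (≥1 haplotype declares a variant) | 0 | **disqualified** |
| undeclared (expected hom-reference) | 0 | **−1** |
| missing genotype | skipped | skipped |

Disqualified candidates are excluded; the remainder are ranked first by
total consistency score (closest to 0) and then by Hardy-Weinberg population
frequency — *p²* for a homozygote, *2pq* for a heterozygote — in the
sample's biogeographic group (one of AAC, AME, SAS, EAS, EUR, LAT, NEA, OCE,
SSA). Null haplotype frequencies (no data) are filled with ε = 10⁻⁵; exact
zeros are preserved. Residual ties are all reported.

Calls then trigger consortium dosing-guideline records (CPIC, DPWG, CPNDS,
RNPGx), classifying each drug as **avoid / caution / routine**, and matched
clinical annotations (evidence levels 1A-2B) are integrated per drug and
category (toxicity, dosage, efficacy, metabolism) as the mean of direction
codes 0.5 (decreased) / 1 (normal) / 2 (increased), mapped back to a
direction by the <1 / =1 / >1 thresholds. Avoid-use drugs receive no
phenotype prediction. Results are rendered as a five-section HTML report
with a machine-readable JSON twin.

The bundled knowledgebase (`inst/extdata/synthetic_kb/`) is **synthetic** —
invented definitions and frequencies for the thirteen multi-variant
pharmacogenes — for demonstration and testing only.

## Worked example

```r
library(pgxdip)

spec <- fixture_spec(seed = 42)
kb_dir <- file.path(tempdir(), "toy_kb")
kb <- generate_toy_knowledgebase(spec, kb_dir)

vcf <- file.path(tempdir(), "toy.vcf")
synthesize_vcf(kb, list(TOYG01 = "*1/*2", TOYG02 = "*2/*2"), spec, vcf)

res <- pgx_annotate(vcf, "EAS", kb = kb_dir, timestamp = "2026-01-01T00:00:00Z")
summary(res)
#> pgxdip annotation — SAMPLE01 · EAS 
#>   positions typed: 14 / 14
#>   genes called: 3 / 3
#>   drugs: 0 avoid, 0 caution, 1 routine
#> 
#> Diplotype calls:
#> TOYG01: *1/*2  (penalty 0, freq 0.0834, exact match)
#> TOYG02: *2/*2  (penalty 0, freq 1e-10, exact match)
#> TOYG03: *1/*1  (penalty 0, freq 0.000269, exact match)
#> 
#> Single-variant alleles:
#>   TOYSV1 (rs9000001): C/C
#>   TOYSV2 (rs9000002): G/G
#> 
#> Drugs:
#>   drug01 [routine] — dosage: increased

write_annotation_report(res, file.path(tempdir(), "toy"))  # .pgx.html + .pgx.json
```

Reading the output: each gene's call shows the winning diplotype, its
consistency penalty (0 = every observed genotype matches the definition),
its Hardy-Weinberg frequency in the chosen population (the `*2/*2` call's
`1e-10` is `(10⁻⁵)²` — both constituent frequencies were ε-filled), and
whether the match was exact (no defining position missing). `drug01` was
triggered by the `TOYG01 *1/*2` guideline record as routine use, with its
matched annotations averaging above 1, i.e. an increased-dosage phenotype.

A thin CLI wraps the same functions:

```sh
Rscript exec/pgxdip fixtures --out demo --seed 4
Rscript exec/pgxdip annotate -i demo/sample.vcf -p EAS -k demo -o demo/report
```

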