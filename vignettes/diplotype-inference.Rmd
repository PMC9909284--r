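---
title: "Star-allele diplotype inference and pharmacogenomic annotation with pgxdip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-allele diplotype inference and pharmacogenomic annotation with pgxdip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxdip)
```

## The problem

Pharmacogenes such as CYP2D6, CYP2C19 or UGT1A1 occur in the population as
named *star alleles* (haplotypes): curated sets of variants that travel
together on one chromosome copy and change the activity of the gene product.
A person's drug-relevant genotype is a *diplotype* — an unordered pair of
star alleles, e.g. `UGT1A1 *28/*28`, the classic poor-metabolizer genotype
for irinotecan. Clinical sequencing, however, delivers an unphased germline
VCF: per position we see an unordered pair of alleles, with no information
about which variants share a chromosome. Several distinct diplotypes can
therefore produce exactly the same set of unphased genotypes
(*indistinguishable diplotypes*), and real VCFs additionally miss positions
and carry artifact calls.

pgxdip infers the most plausible diplotype per gene from such a VCF, then
translates the calls into prescribing categories and integrated
drug-response phenotypes, rendered as an HTML report with a JSON twin.

## The inference model

### Candidate space

For a gene with haplotypes $h_1, \dots, h_H$ (one of which is the
wild-type/reference and declares no variants), every unordered pair —
homozygous pairs included — is a candidate diplotype: $H(H+1)/2$ candidates.
The gene's *position set* is the union of all positions declared by any of
its haplotypes; positions outside it are never consulted, because the model
can only reason about loci that appear in some allele definition.

The *combined definition* of a candidate $a/b$ assigns to every position of
the position set the unordered pair of alleles contributed by $a$ and $b$,
where a haplotype contributes its declared alternate allele at positions it
declares and the reference allele elsewhere. A position is *declared* for
the pair if at least one of the two haplotypes declares a variant there.
Two candidates with identical combined definitions are indistinguishable
from unphased genotypes; `indistinguishable_groups()` computes these
equivalence classes.

### Consistency scoring

Each candidate is compared position by position against the observed
genotype (an unordered allele pair; `|` and `/` separators are treated
identically, since phase is not trusted):

* **declared** position, observed pair equals the expected pair: score 0;
  observed differs: the candidate is **disqualified** — its defining
  variants are contradicted by the data;
* **undeclared** position (expected homozygous reference), observed equals
  reference: 0; observed differs: **−1** — an unexplained variant, tolerated
  but penalised;
* **missing** position (no VCF record, or `./.`): skipped and counted, never
  penalised. Absence of a record is treated as *untyped*, not as homozygous
  reference: assuming reference would silently disqualify true calls when a
  defining variant simply was not covered.

The candidate's penalty sum is the total over non-missing positions (always
$\le 0$).

### Two-step ranking

1. Disqualified candidates are removed; among the rest only those with the
   maximal penalty sum (closest to zero) are kept.
2. Ties are resolved by population frequency: under Hardy-Weinberg
   equilibrium a homozygote $a/a$ has expected frequency $p_a^2$ and a
   heterozygote $a/b$ frequency $2 p_a p_b$, using the haplotype frequencies
   of the sample's biogeographic group. Only candidates at the maximal
   frequency survive.

Residual ties — typically members of one indistinguishable class whose
haplotype frequencies coincide (e.g. both epsilon-filled) — are *all*
reported in canonical order rather than broken arbitrarily; inventing a
unique answer would hide genuine ambiguity. An `exact_match` flag marks
calls with penalty 0 and no skipped declared position, distinguishing
confident matches from tolerant best-effort calls.

If every candidate is disqualified the gene is flagged `undeterminable`
(empty top set, not an error); if every position is missing it is
`not tested`. With a schema-valid knowledgebase the reference homozygote
declares nothing and thus can never be disqualified, so `undeterminable`
can only arise from corrupted definitions — the code still handles it.

### Population stratification and frequencies

Frequencies are stratified over nine standardized biogeographic groups
(AAC, AME, SAS, EAS, EUR, LAT, NEA, OCE, SSA). Two rules govern the
frequency table:

* **Minimum rule**: when a haplotype's frequency must be derived from the
  frequencies of its defining variants, the per-group haplotype frequency is
  the *minimum* over those variants — a haplotype cannot be more common than
  its rarest defining variant. If any defining variant lacks data for a
  group the result is null for that group: a minimum over partially known
  values would overstate confidence.
* **Epsilon fill**: a null frequency means *no data*, whereas an observed
  zero means the haplotype is essentially absent from that population. Nulls
  are therefore replaced by a small constant $\varepsilon = 10^{-5}$
  (configurable), while exact zeros are preserved. All diplotype frequencies
  are derived on demand from the filled haplotype table; they are never
  stored, so Hardy-Weinberg consistency is automatic
  ($\sum_{a\le b} f_{ab} = (\sum_a p_a)^2$).

Frequencies are recorded as supplied and not renormalized per gene and
group; the cross-population dispersion summary `frequency_cv()` uses the
population standard deviation (denominator $n = 9$, since the nine groups
are an exhaustive partition, not a sample) divided by the mean, computed on
epsilon-filled values.

## Annotation model

Dosing-guideline records from the four consortia (CPIC, DPWG, CPNDS, RNPGx)
carry a curated category and two flags. A record is *triggered* when its
(gene, genotype key) matches a call — a multi-variant gene's top diplotype
label, a single-variant gene's observed genotype, or a present HLA allele.
Per drug the most conservative triggered category wins:

* **avoid** — avoidance is clearly stated for the genotype;
* **caution** — a prescribing change is recommended, or the triggered
  recommendation is population-dependent or requires consideration of
  multiple genes (both flags force at least caution);
* **routine** — triggered records recommend no change.

Drugs with no triggered record are omitted. Clinical-annotation records
(only evidence levels 1A, 1B, 2A, 2B are retained on load) carry a
direction per phenotype category — toxicity, dosage, efficacy, metabolism —
coded $0.5$ (decreased), $1$ (normal), $2$ (increased). Per drug and
category the unweighted mean of matched records' codes is mapped to
decreased ($<1$), normal ($=1$) or increased ($>1$); categories without
matches are `not_predicted`. Avoid-use drugs are excluded from phenotype
interpretation entirely. Records for one drug are pooled across genes: the
prediction is drug-centric, reflecting the many-to-one relation between
genotypes and a drug.

Two open choices were resolved as follows: the mean is *unweighted* by
evidence level (the simplest reading of "mean of the annotation scores"),
and the $=1$ comparison uses a $10^{-9}$ tolerance because the codes are
dyadic rationals but the mean is computed in floating point.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | `1e-5` | fill value for null haplotype frequencies (dimensionless frequency) |
| `population` | — | one of the nine biogeographic group codes; selects the frequency column used in ranking |
| `respect_filter` | `FALSE` | when `TRUE`, drop VCF records whose FILTER is neither `PASS` nor `.`; the default ignores FILTER to stay concordant with upstream pipelines |
| `dropout_rate`, `spurious_rate` | 0, 0 | fixture generator noise: probability of omitting a target position / of injecting a spurious heterozygote at an expected-reference position |
| `null_rate` | 0.1 | fixture generator: fraction of frequency cells left null, emulating populations without curated data |

## Numerical and determinism choices

* All orderings (haplotype names, diplotype labels, report tables) use
  byte-wise (C-locale radix) sorting, so output is identical across locales.
* Diplotype labels are canonical: `"A/B"` with `A <= B`, unique per
  unordered pair.
* Frequency comparisons in the ranking use exact equality — frequencies are
  derived deterministically from the same table, so equality is meaningful
  and no tolerance is applied.
* Variant records are normalized to a parsimonious left-aligned form
  (shared suffix trimmed, then shared prefix with position advanced) before
  matching, so indels written with different anchors still meet their
  knowledgebase positions; the operation is idempotent.
* Report timestamps are injected by the caller, never read from the clock
  inside the renderer, making report bytes reproducible.
* Fixture generation uses a single seeded pseudo-random stream per generator
  call, with draws in documented order, so knowledgebases and VCFs are
  byte-identical across runs of the same seed.

## What the synthetic data emulates — and what it does not

`generate_toy_knowledgebase()` produces schema-complete knowledgebases:
per-gene star-allele tables with exactly one reference haplotype and
distinct declared sets, Dirichlet-style per-group frequencies summing to at
most 1 with optional nulls, and guideline/annotation records that reference
only generated content. With `ambiguity = TRUE` the first gene contains the
minimal indistinguishable construction (haplotypes declaring $\{v\}$,
$\{w\}$ and $\{v, w\}$, so ref/$\{v,w\}$ collides with $\{v\}$/$\{w\}$).
`synthesize_vcf()` writes a VCF whose records realise a chosen true
diplotype per gene, with independent per-position dropout and spurious
heterozygotes injected only inside gene position sets (elsewhere they could
never perturb scoring).

The bundled knowledgebase under `inst/extdata/synthetic_kb/` is generated
this way for the thirteen multi-variant pharmacogenes of
`pgx_gene_registry()` plus a few single-variant and HLA entries. It is
entirely synthetic: allele definitions, frequencies, guidelines and
annotations are invented for demonstration and testing and must never be
used to interpret real samples.

Passing tests on this material demonstrate the *algorithmic* contracts —
enumeration combinatorics, scoring semantics, Hardy-Weinberg consistency,
oracle-equivalent ranking, recovery from noiseless data, deterministic
reporting. They do not demonstrate clinical accuracy on real genomes: the
generator has no linkage disequilibrium, no structural variants, no
multi-nucleotide or repeat alleles beyond simple normalization, and its
frequencies are not the curated ones.

## The recovery experiment

The recovery test synthesizes noiseless VCFs from known truths and requires
the truth in the top set in 100% of replicates. One subtlety is inherent to
the model: if the truth is a *rarer* member of an indistinguishable class,
the frequency step reports the more frequent member — that prioritization
is exactly what the second ranking step is for, and no unphased method can
do otherwise. The experiment therefore draws the truth among recoverable
diplotypes (the frequency-maximal member of its class; every unambiguous
diplotype qualifies) and separately asserts that the call never leaves the
truth's combined-definition class. Problem sizes: one gene of 4-6
haplotypes over 3-5 positions per replicate, 200 replicates; the oracle
comparison uses 500 random instances with up to 12 haplotypes; both finish
in seconds.

## Known limitations

* Alleles defined on copy-number or structural variants cannot be called
  from a typical VCF and are out of scope; HLA typing is consumed (symbolic
  ALT entries or a sidecar file), never performed.
* Phase information in the VCF is deliberately ignored; the model is defined
  for unphased input.
* No linkage-disequilibrium reasoning: a haplotype that is rare *given* the
  observed variants elsewhere is not down-weighted beyond its marginal
  frequency.
* Disease context, dose calculation and free-text recommendation generation
  are out of scope; the report reproduces curated recommendation text.

## A worked toy run

```{r example, eval = FALSE}
spec <- fixture_spec(seed = 42)
kb_dir <- file.path(tempdir(), "toy_kb")
kb <- generate_toy_knowledgebase(spec, kb_dir)

vcf <- file.path(tempdir(), "toy.vcf")
synthesize_vcf(kb, list(TOYG01 = "*1/*2", TOYG02 = "*2/*2"), spec, vcf)

res <- pgx_annotate(vcf, "EAS", kb = kb_dir,
                    timestamp = "2026-01-01T00:00:00Z")
summary(res)
write_annotation_report(res, file.path(tempdir(), "toy"))
```
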