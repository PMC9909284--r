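Package: pgxdip
Title: Star-Allele Diplotype Inference and Pharmacogenomic Annotation from Germline VCFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers pharmacogene star-allele diplotypes from a single-sample
    unphased germline VCF (GRCh38) by a two-step ranking model: candidate
    diplotypes are scored for consistency with the observed genotypes
    (declared-locus mismatches disqualify a candidate; unexplained variants at
    undeclared loci accrue -1 penalties), and ties are resolved by
    Hardy-Weinberg diplotype frequencies in one of nine biogeographic groups.
    Inferred diplotypes are translated into prescribing categories (avoid /
    caution / routine) from consortium dosing guidelines and into integrated
    drug-response phenotypes (toxicity, dosage, efficacy, metabolism) from
    evidence-graded clinical annotations, rendered as a self-contained HTML
    report with a machine-readable JSON twin. A synthetic knowledgebase and
    VCF generator makes the whole pipeline testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
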