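Package: dirichscan
Title: Dirichlet Regression Association Scans for Longitudinal Blood-Pressure States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genetic association analysis for a compositional phenotype derived
    from longitudinal blood-pressure records. Exam-level systolic/diastolic
    pressures and medication use are classified into three hypertension states;
    per-previous-state generalized-logit (multinomial) transition models yield
    a subject-specific transition probability matrix, whose row conditioned on
    the last observed state is a 3-simplex response. That response is related
    to SNP genotypes by Dirichlet regression with a log link, with joint Wald
    tests per marker (with or without fixed pedigree adjustment), and by a
    penalized Dirichlet regression mixing squared group-L2 (ridge) and L1
    (lasso) penalties for gene-level SNP selection. Includes native genotype
    QC (call rate, exact Hardy-Weinberg test, minor allele frequency), readers
    for VCF / PLINK text / dosage CSV, and a family-blocked synthetic-cohort
    simulator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    vcfR,
    yaml
Config/testthat/edition: 3
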