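Package: mssrates
Title: Multiclass Synonymous Substitution Codon Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and maximum-likelihood fitting of Muse-Gaut (MG94xREV)
    codon substitution models in which synonymous substitution rates vary across
    codon pairs (multiclass synonymous substitution, MSS, models including the
    SynREV and SynREVCodon parameterizations with CF3x4 equilibrium frequencies).
    Includes per-gene and joint multi-gene fitting, nested-model comparison, a
    CHC genetic-algorithm search over synonymous rate partitions scored by BIC
    with Akaike-weight model averaging, a parametric Markov alignment simulator,
    a forward Wright-Fisher simulator with selection on synonymous codon classes,
    and per-codon-pair covariates (synonymous SNP density, pooled tRNA decoder
    abundance ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
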