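Package: fragretro
Title: Fragment-Based Sequence-to-Sequence Retrosynthesis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-step retrosynthetic prediction recast as neural machine
    translation between molecular fragment "sentences". Molecules are encoded
    as rank-ordered words over a curated MACCS-key vocabulary, a bidirectional
    LSTM encoder-decoder with Luong attention translates product sentences
    into reactant sentences, predictions are scored with fragment-set Tanimoto
    similarity under a combinatorial reactant pair-matching rule, and
    predicted key-sets are mapped back to real molecules through a lookup
    table with discrepant-key tolerance and circular-fingerprint re-ranking.
    Includes the full reaction-corpus curation cascade (single-product
    filtering, duplicate and internal-twin removal, reactant-count and
    pair-length limits, injective collapse) and a synthetic rule-based
    reaction generator so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineOB,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
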