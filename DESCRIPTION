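Package: phenomine
Title: Mining Phenotype Annotation Models for Diseases from Tagged Abstract Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives disease-to-phenotype annotation models from a corpus of
    disease-tagged abstracts. Provides OBO ontology parsing with DAG
    operations and corpus-driven information content, dictionary-based
    concept recognition over term labels and synonyms, assembly of
    disease-tagged corpora with MeSH descriptor filtering, a
    TFIDF/TFIDFIC-weighted density-clustering filter that distils raw term
    mentions into per-disease phenotype models, subsumption-aware Jaccard
    and MICA-based semantic similarity between annotation sets, and a
    phenotypic disease network with gray-edge-fraction randomization tests.
    Includes a synthetic-corpus generator with planted disease models for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
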