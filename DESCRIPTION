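Package: netproxrx
Title: Network-Proximity Drug Repurposing with Signature-Reversal Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Network-medicine drug repurposing on a protein-protein
    interactome. Scores drug-disease pairs by the closest-distance network
    proximity between drug targets and disease-associated genes, assesses
    significance with a degree-preserving permutation null, rescales
    proximity to a 0-1 similarity, and complements it with a
    signature-reversal score that counts, over several disease expression
    datasets, how many disease signatures a drug's expression signature
    reverses (a weighted Kolmogorov-Smirnov connectivity statistic).
    Candidates are ranked by similarity, reversal score, and name. Includes
    readers for edge lists, GMT gene sets, drug-target tables, and
    differential-expression tables, plus a synthetic-data generator that
    plants disease modules, drugs at controlled proximity, and signature
    libraries with controlled reversal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
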