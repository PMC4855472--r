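Package: rankmap
Title: Signed-Rank Gene Expression Connectivity Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectivity mapping of transcriptomic query signatures against
    reference databases of drug-perturbation expression profiles encoded as
    signed ranks. Builds reference databases from plate-structured expression
    matrices (differential expression against same-plate controls, signed-rank
    transform), scores up/down query signatures against treatment sets with
    median aggregation, estimates connection p-values by a normal-approximation
    null model fitted to random-signature scores, and attributes connections to
    individual signature probes via the Contribution Fraction statistic. Ships
    a synthetic-data generator emulating LINCS-like plates with planted
    perturbagen effects so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
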