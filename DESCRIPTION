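Package: o2balance
Title: Oxygen Contamination and Component Balances for Closed
    Gas-Recirculation Fermenters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing anaerobic fermentations run with a closed,
    recirculating gas reservoir: a helium-tracer estimate of total system gas
    volume, an indirect estimate of the oxygen contamination rate from the
    nitrogen fraction of the recirculating gas (using the 3.73 N2:O2 ratio of
    air), dilution-corrected volumetric production and consumption rates for a
    continuously stirred tank reactor, degree-of-reduction electron-equivalent
    ledgers with percent closure error, test-versus-control contrast tables,
    and rarefaction plus significance-masked Spearman correlation of genus
    counts against process rates. A stoichiometric simulator of the reactor
    and its gas loop generates synthetic time series with known ground truth
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
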