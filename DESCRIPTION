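Package: isophys
Title: Biophysical Differentiation of Protein Isoforms from Instrument-Level Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis chain for differentiating two protein
    isoforms from tabular instrument data: two-state thermal unfolding fits of
    fluorescence melt curves (Tm, van't Hoff dH), single-site isothermal
    titration calorimetry with proton-linkage and heat-capacity decomposition,
    first-order turnover (cycloheximide chase) and FRAP recovery kinetics,
    densitometry normalization with the exact two-tailed Mann-Whitney test,
    and a peptide-evidence co-immunoprecipitation interactor filter. Includes
    seeded synthetic-data generators emulating each instrument output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
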