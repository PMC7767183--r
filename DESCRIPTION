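Package: sebumetry
Title: Quantifying Alcoholamine Penetration into Model Skin Sebum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two complementary methods for quantifying the penetration of an
    alcoholamine (such as 2-amino-2-methyl-1,3-propanediol, AMPD) into a model
    skin sebum layer: an optical method converting pixel-calibrated layer
    heights to cylinder volumes, and a pH-equilibrium method converting the
    drop in solution pH to a reacted sebum volume through weak-base
    equilibrium and neutralization stoichiometry. Includes salt-hydrolysis
    equilibrium theory, pycnometer density determination, a self-consistent
    synthetic experiment generator with known ground truth, and an
    end-to-end pipeline that reconciles the two methods over a
    concentration sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
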