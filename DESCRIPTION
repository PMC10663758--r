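Package: sacchsim
Title: Stochastic Simulation and Fitting of Enzymatic Lignocellulose
    Saccharification
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monomer-resolved, three-dimensional stochastic (Gillespie)
    simulation of the enzymatic saccharification of a single lignocellulose
    microfibril by a cocktail of endoglucanase (EG), cellobiohydrolase
    (CBH), beta-glucosidase (BGL) and xylanase (XYL).  The substrate is a
    bundle of cellulose chains sheathed by hemicellulose and lignin on a
    square lattice, with crystalline and amorphous regions, defect
    patches, end-product inhibition, non-productive adsorption onto
    lignin, steric hindrance and structural occlusion.  A hybrid
    random/directed generational search fits shared kinetic parameters
    and per-sample substrate parameters to experimental glucan/xylan
    conversion time courses, and fitted models predict saccharification
    of new samples from their composition and crystallinity alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
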