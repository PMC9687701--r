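Package: nanobone
Title: Nanoscale Mechanics of Collagen-Hydroxyapatite Bone Composites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds atomistic models of mineralized collagen at the nanometre
    scale (type I collagen triple helices, hydroxyapatite crystal slabs and
    their oriented, optionally hydrated composites, including osteogenesis
    imperfecta glycine substitutions and crack defects), evaluates a
    CHARMM-style potential with analytic forces, runs steered uniaxial
    tensile molecular dynamics with virial-stress extraction, and reduces
    stress-strain curves to ultimate tensile strength, toughness, elastic
    moduli, polynomial constitutive models, orientation laws and one-way
    ANOVA summaries with connecting-letter reports. A synthetic-data module
    generates curve families and modulus grids with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    pracma,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
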