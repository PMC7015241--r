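Package: fibractin
Title: Contractile Mechanics, Actin Filament Kinetics and Muscle Morphometry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for striated-muscle physiology and actin
    biochemistry. Fits the classical relations of muscle mechanics: the Hill
    hyperbolic force-velocity curve with power output, the sigmoid force-pCa
    calcium-sensitivity relation, the length-step (T1) stiffness line with
    half-sarcomere strain, and the passive stress tangent (Young's) modulus.
    Quantifies actin filament biochemistry from co-sedimentation binding
    isotherms (dissociation constants), low/high-speed bundling partitions,
    and pyrene-fluorescence polymerization and Latrunculin-A
    depolymerization kinetics. Summarises image-derived morphometry (Z-line
    width at base from averaged density profiles, fibre cross-sectional
    areas, fusion index, EdU fraction) and routine assay quantities
    (delta-delta-Ct expression, dual-luciferase ratios, densitometry).
    Includes seeded synthetic-data generators emulating each assay so every
    analysis stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    minpack.lm,
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
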