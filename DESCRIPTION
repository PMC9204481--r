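Package: plaqrupt
Title: Morphometry and Idealized Physiology of Ruptured Coronary Plaques from OCT Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ruptured coronary plaques from frame-level optical
    coherence tomography (OCT) annotations: culprit-lesion delimitation,
    minimum lumen area and radius gradients, fibrous cap thickness and
    thin-cap fibroatheroma phenotyping, lipid/calcific/macrophage tissue
    indices, rupture and thrombus metrics, and group-comparison tables for
    native-vessel versus neoatherosclerotic cohorts. Also builds
    representative idealized pre-rupture lesion geometries (native and
    stented) and evaluates desk-scale physiology surrogates: quasi-1D and
    axisymmetric laminar wall shear stress, pressure drop, and closed-form
    (Lame, Laplace, Mooney-Rivlin) plaque structural stress estimators.
    Includes a seeded synthetic-cohort generator so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
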