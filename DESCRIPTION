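Package: hadronarc
Title: Ion-Beam Arc Therapy Planning and Radiobiological Evaluation in Water Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical pencil-beam physics for proton, helium and carbon ion
    beams in water (Bethe stopping power, range straggling, nuclear attenuation,
    fragment tails), modified microdosimetric kinetic model (mMKM) RBE-weighted
    dose for mixed radiation fields, a hypoxia reduction factor (HRF/OER) model
    parameterized in oxygen tension and (Zeff/beta)^2, spot-weight optimization
    for monoenergetic arc (SHArc) and static multi-field plans on cylindrical
    phantoms, and evaluation of DVH, dose-averaged LET, tumor control
    probability and hypoxia-induced effective dose reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
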