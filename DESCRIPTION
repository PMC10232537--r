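Package: empot
Title: Charge and Hydrogen Analysis of Cryo-EM Coulomb Potential Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing charges and hydrogen bonding in Coulomb
    potential maps from high-resolution single-particle cryo-EM. Implements
    electron scattering factors for neutral, ionized and partially charged
    atoms (published 5-Gaussian parameterizations and the Mott-Bethe
    relation), structure-factor calculation from atomic models,
    band-limited map synthesis, hydrogen-omit Fourier difference maps,
    sub-voxel density peak detection with riding-hydrogen assignment and
    per-bond-type distance statistics, negative-charge density metrics
    across resolution and dose series, half-map model-precision estimation
    (RMSD between models refit to each half map), Fourier shell
    correlation, and a synthetic-data generator producing polypeptide toy
    models, band-limited maps and half-map pairs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
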