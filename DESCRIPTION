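Package: RelaxAniso
Title: Orientation-Resolved Quantitative MRI Relaxometry and Relaxation
    Anisotropy Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise relaxation-time mapping for multi-sequence
    quantitative MRI (inversion-recovery T1, multi-echo spin-echo T2,
    continuous-wave and adiabatic rotating-frame relaxation, and RAFF),
    in-plane rigid co-registration of a specimen imaged at several
    physical orientations in the magnet, and Michelson-contrast
    relaxation-anisotropy maps with region-of-interest summaries.
    Includes a synthetic rotating-phantom generator implementing the
    dipolar magic-angle relaxation model with spin-lock dispersion and
    Rician magnitude noise, so the whole pipeline can be exercised and
    validated at desk scale without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RelaxAniso-package.R'
    'anisotropy.R'
    'protocols.R'
    'signal-models.R'
    'fitting.R'
    'io.R'
    'phantom.R'
    'registration.R'
    'pipeline.R'
    'show-methods.R'
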