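Package: enamelQuant
Title: Quantitative Microanalysis of Tooth Thin Sections
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the quantitative study of dental enamel and dentin in
    crown thin sections: crown formation chronology from incremental growth
    markings (cross-striation spacings, striae of Retzius counts and
    periodicity), registration of trace-element banding events onto
    developmental time along prism paths, calibration of synchrotron X-ray
    fluorescence element maps to mass fractions via foil-standard
    sensitivities and hydroxyapatite matrix attenuation correction, Raman
    band metrics (phosphate 960 and carbonate 1070 band areas, FWHM maps),
    and EDX atomic-ratio summaries. Includes a synthetic tooth-section
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    pracma,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chronology.R'
    'edx.R'
    'enamelQuant-package.R'
    'events.R'
    'xrf-data.R'
    'sxrf.R'
    'io.R'
    'raman.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
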