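Package: acetorient
Title: Acetabular Inclination and Anteversion from CT Bone Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes acetabular cup orientation from labelled bony landmarks
    exported from a 3-D pelvic CT reconstruction. Fits the acetabular face
    plane to rim landmarks by total least squares, builds patient-specific
    coronal (anterior pelvic plane), sagittal and transverse reference planes
    from the anterior superior iliac spines, pubic tubercles and sacral crest,
    and reports anatomical, operative and radiographic inclination and
    anteversion under Murray's definitions, together with reference-plane
    perpendicularity audits, conversion-formula residuals, and cohort-level
    statistics (normality testing, Blom normal scores, group comparisons,
    one-way ANOVA with Fisher LSD contrasts). A seeded synthetic-pelvis
    generator with known ground-truth orientation supports validation without
    imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
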