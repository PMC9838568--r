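Package: biopsyGuide
Title: Multimodal Optical Imaging Pipeline for Oral Biopsy Guidance
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Desk-scale software pipeline for active biopsy guidance in the
        oral cavity. Computes normalized red-to-green autofluorescence cancer
        risk maps inside a clinician-drawn mucosa outline, tracks a colored
        marker at the tip of a fiber-bundle microendoscope through widefield
        video, quality-controls and scores microendoscopy frames with a
        pluggable diagnostic scorer (nuclear-morphometry baseline included),
        fuses per-frame scores onto anatomy as a per-pixel average score
        field, derives dual-threshold biopsy guidance maps with fast
        interactive threshold updates, registers high-frame-rate
        microendoscopy frames into mosaics with score-versus-distance
        profiles, and maps guidance masks into projector coordinates through
        a planar homography. A fully seeded synthetic phantom generator
        emulates complete imaging sessions with ground truth so every stage
        is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, grDevices, utils, tools, EBImage, png, tiff,
        jsonlite, yaml, pROC
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, Visualization
RoxygenNote: 7.3.3
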