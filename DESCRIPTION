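Package: aoslomorph
Title: Vessel Wall Morphometry from Multi-Offset AO-SLO Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for adaptive-optics scanning laser ophthalmoscope
    (AO-SLO) image stacks acquired with a four-fiber offset aperture bundle plus
    a confocal channel. Computes split-detector images, the magnitude of the
    phase gradient (MPG), multi-offset standard-deviation and ring-sum images,
    and motion-contrast (temporal STD) angiography from registered frame
    stacks; segments the vessel wall (outer boundary from MPG gradient maxima,
    inner boundary from the motion-contrast flow edge) and measures
    arclength-resolved vessel diameter, lumen diameter, wall thickness and
    wall-to-lumen ratio. Includes a ground-truthed synthetic scene simulator
    (vessel as a phase object, flowing blood cells, eye-motion jitter) so every
    stage is verifiable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    png,
    yaml,
    jsonlite,
    EBImage,
    pracma,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
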