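Package: panodont
Title: Panoramic Dental Image Reconstruction from CT/CBCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automatic synthesis of a two-dimensional panoramic dental
    image from an axial CT or cone-beam CT volume. The dental arch is
    segmented by Hounsfield-unit thresholding and morphological connection,
    its medial-axis skeleton is extracted and ordered, a Bezier curve is
    fitted to the skeleton by minimising a discrete mean point-to-skeleton
    distance with a quasi-Newton optimiser, parallel offset curves are built
    from the rotated curve derivative, and the panoramic image is the average
    intensity projection across the offset family for every axial slice.
    Includes a synthetic dental-arch phantom generator with known ground
    truth, a minimal DICOM series reader, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
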