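Package: thrombseg
Title: Bidirectional Convolutional LSTM Segmentation of Aortic Thrombus in
    Postoperative CTA Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segmentation of abdominal aortic aneurysm thrombus regions in
    postoperative computed-tomography-angiography (CTA) volumes using a
    bidirectional convolutional LSTM (Bi-CLSTM) over sequences of adjacent
    axial slices. Each slice is paired with a spatial attention map from a
    detection-style backbone; pairs are encoded by residual convolutional
    blocks, passed through forward and backward ConvLSTM cells, fused, and
    decoded into a per-pixel thrombus probability map trained with focal
    loss. Includes volume readers and writers (NIfTI and PNG stacks), 8-bit
    intensity rescaling, bounding-box ground-truth derivation, elastic and
    rotational augmentation applied consistently to images and masks, the
    five overlap metrics (total overlap, Dice, Jaccard, false-negative and
    false-positive rates), patient-wise k-fold cross-validation, a synthetic
    postoperative-CTA phantom generator for desk-scale experiments, and a
    command-line pipeline covering generation, attention-map precomputation,
    training, prediction and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
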