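Package: rvit
Title: Rotation-Invariant Vision Transformers for Binary Tumor Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a rotation-invariant vision transformer (RViT) for binary
    tumor/non-tumor classification of 2-D medical images. Quarter-rotated copies of
    the input are patch-embedded with a shared linear projection and averaged before
    the transformer encoder, making the classifier exactly invariant to 90-degree
    rotations. Includes the baseline vision transformer and two ablation variants
    (no rotation averaging; no depth-wise convolution stem), a seeded training and
    evaluation pipeline with stratified splitting, binary classification metrics
    (sensitivity, specificity, F1, Matthews correlation coefficient), Grad-CAM
    saliency maps over the patch grid, an MRI-like phantom generator for
    download-free testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
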