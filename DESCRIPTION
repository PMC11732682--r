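Package: CascadeReg
Title: Cascaded Deformable Registration and Multi-Atlas Segmentation of 3-D Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised deformable registration of 3-D volumes by a stack of
    cascaded convolutional networks that predict incremental displacement
    fields which are accumulated (rather than composed) so the moving image is
    interpolated only once per stage. Training minimises a multi-scale local
    normalized cross-correlation similarity plus a gradient-norm smoothness
    penalty, evaluated on the final warped image and final field only. On top
    of the registration model the package provides a weakly-supervised
    multi-atlas segmentation pipeline (atlas registration, similarity-based
    selection, label propagation, majority and local weighted voting fusion),
    Jacobian-determinant folding analysis, overlap/Hausdorff evaluation
    metrics, and a synthetic multi-tissue phantom generator with ground-truth
    deformations for end-to-end testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, RNifti, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'CascadeReg-package.R'
    'RcppExports.R'
    'volume_io.R'
    'phantom.R'
    'metrics.R'
    'transform.R'
    'losses.R'
    'nn.R'
    'network.R'
    'mas.R'
    'training.R'
    'cli.R'
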