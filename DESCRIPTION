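Package: grqsar
Title: QSAR Classification of Glucocorticoid Receptor Antagonists with
    Multi-View Fingerprint Fusion, Hybrid Resampling and a BiGRU-Attention
    Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative structure-activity relationship (QSAR) pipeline for
    identifying glucocorticoid receptor (GR) antagonists from molecular
    fingerprints. Curates IC50 bioactivity tables into active/inactive
    compound sets, fuses five fingerprint views (AP2D, CDKExt, KR, Morgan,
    RDKIT) into a 10,757-dimensional representation, balances the severely
    imbalanced classes with proportional SMOTE oversampling combined with
    random undersampling, learns a 4000-dimensional feature embedding with a
    bidirectional GRU and scaled dot-product self-attention network trained
    end-to-end on binary cross-entropy, reduces it by PCA at an explained
    variance threshold, and classifies with extremely randomized trees or one
    of eleven baseline classifiers under stratified grid-search
    cross-validation. Includes threshold and ranking metrics (sensitivity,
    specificity, balanced accuracy, MCC, F1, AUC, AUPR), confusion-matrix
    recovery from printed rates, leakage-safe fold-wise balancing, ablation
    experiments, t-SNE visualization, and seeded synthetic data generators so
    the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    class,
    e1071,
    jsonlite,
    MASS,
    nnet,
    ranger,
    rpart,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
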