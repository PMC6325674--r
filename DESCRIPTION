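Package: satox
Title: Synthetic Accessibility and Toxicity Prediction from Molecular Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the synthetic accessibility score (SAscore, a value
    between 1 and 10) and a toxicity score (Tox-score, a probability-like
    value between 0 and 1) of small organic compounds directly from 1024-bit
    hashed path fingerprints. Synthetic accessibility is regressed with a
    deep belief network (stacked restricted Boltzmann machines pre-trained
    by contrastive divergence, then fine-tuned with a linear regression
    head), and toxicity is classified with an ensemble of extremely
    randomized trees. Includes dataset curation (molecular-weight and
    Tanimoto-redundancy filters), bin-wise over/under-sampling of skewed
    SAscore distributions, evaluation metrics (accuracy, TPR, FPR, MCC,
    MSE, PCC, ROC/AUC), k-fold cross-validation, MCC-maximizing decision
    threshold selection, grid search, chemical-fragment composition
    comparison, and synthetic data generators for fully reproducible
    testing without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
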