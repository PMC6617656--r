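Package: vacoder
Title: Cause-of-Death Coding from Verbal Autopsy Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns cause-of-death (CoD) categories to verbal autopsy (VA)
    free-text narratives. Provides the full narrative-only pipeline: spelling
    correction against an English plus medical lexicon, stopword removal and
    Porter stemming; word-frequency features with an age-group indicator;
    one-way ANOVA F-value feature ranking and top-k selection; four classifier
    families (multinomial naive Bayes, random forest, one-vs-rest linear SVM,
    and a single-hidden-layer ReLU feed-forward network) with per-category
    confidence scores; 10-fold cross-validated evaluation with the VA-specific
    population metrics (CSMF accuracy, PCCC, and Monte-Carlo chance-corrected
    CSMF accuracy); and a seeded synthetic VA corpus generator for testing and
    benchmarking when real physician-coded data cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    ranger,
    e1071,
    methods,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
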