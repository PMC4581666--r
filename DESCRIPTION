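Package: boneage
Title: Automated Bone Age Assessment by Image Retrieval and Extreme
    Learning Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated skeletal-maturity (bone age) assessment from
    hand radiographs. Implements content-based image retrieval over
    weighted-PCA eigenimage features with a mean-of-top-k age estimator,
    together with three regression engines for benchmarking: extreme
    learning machines (random hidden layer, Moore-Penrose pseudoinverse
    output weights), a backpropagation multilayer perceptron, and
    gene-expression-programming symbolic regression. Because real
    radiograph collections are third-party data, the package ships a
    seeded synthetic phantom generator producing age-, gender- and
    ethnicity-conditioned 256 x 260 grayscale hand images, so the whole
    pipeline is reproducible offline. Models are compared by RMSE,
    Pearson r and the coefficient of determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
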