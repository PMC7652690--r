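Package: mealrank
Title: Image-Based Ranking and Screening of Meal Healthiness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for learning a meal-healthiness score from ranked meal
    photographs. Ranked training data are produced by pivot-based comparison
    sessions in which an annotator orders small sets of images at a time;
    multiple annotators' rankings can be merged with TrueSkill skill updates.
    A compact Siamese convolutional network with food-region input masking is
    trained on ordered image pairs with a logistic pairwise ranking loss,
    optionally after per-pixel segmentation pretraining of its feature
    extractor. Raw network outputs are standardized into a 0-100 deviation
    score used to screen unhealthy meals by threshold. A seeded synthetic
    meal-scene generator with pixel-accurate food masks, a known latent
    healthiness function, and a noisy simulated annotator supports end-to-end
    evaluation: pairwise and order error rates, rank correlations,
    Bland-Altman agreement, ROC screening analysis, a Rank-SVM baseline, and
    an ablation grid over masking and pretraining.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
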