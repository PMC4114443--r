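#!/usr/bin/env Rscript
# Step 4 -- linear-SVM staging with 10-fold cross-validation.
#
# Concatenates the six per-stage feature tables into the 120-sample
# dataset (9 features each), evaluates a one-vs-one linear-kernel SVM
# (C = 1) by plain 10-fold cross-validation with per-fold feature
# standardization, tests the mean accuracy against the 1/6 chance level by
# exact binomial test, and repeats the whole procedure with permuted
# labels as a negative control.
#
# Outputs under results/svm/: cv_report.json, confusion.csv.

suppressPackageStartupMessages(library(phasetex))

SEED <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
feat <- "results/features"
out <- "results/svm"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tabs <- list()
for (g in stage_levels()) {
  tabs[[g]] <- utils::read.csv(file.path(feat, sprintf("features_%s.csv", g)))
}
ds <- build_dataset(tabs)
message(sprintf(
  "dataset: %d samples (%d stages x %d ROIs), %d features each",
  nrow(ds), nlevels(ds$stage), nrow(ds) / nlevels(ds$stage), 9
))

cv <- tenfold_cv(ds, seed = SEED + 101, k = 10, C = 1)
p <- stats::binom.test(cv$n_correct, cv$n, 1 / 6, "greater")$p.value
message(sprintf(
  "10-fold CV: folds test 12 / train 108; mean accuracy %.1f%% (%d/%d); chance 16.7%%, exact binomial p = %.2e",
  100 * cv$mean_accuracy, cv$n_correct, cv$n, p
))

ds_perm <- ds
set.seed(SEED + 500)
ds_perm$stage <- sample(ds$stage)
cv_perm <- tenfold_cv(ds_perm, seed = SEED + 101, k = 10, C = 1)
message(sprintf(
  "label-permutation control: %.1f%% (chance band 16.7%% +/- %.1f%%)",
  100 * cv_perm$mean_accuracy, 300 * sqrt(1 / 6 * 5 / 6 / cv$n)
))

jsonlite::write_json(
  list(
    fold_accuracies = cv$fold_accuracies, mean_accuracy = cv$mean_accuracy,
    n_correct = cv$n_correct, n = cv$n, k = cv$k, C = cv$C,
    seed = cv$seed, chance_binomial_p = p,
    permuted_mean_accuracy = cv_perm$mean_accuracy,
    fold_assignment = cv$fold_assignment
  ),
  file.path(out, "cv_report.json"),
  auto_unbox = TRUE, digits = NA
)
utils::write.csv(as.data.frame.matrix(cv$confusion), file.path(out, "confusion.csv"))
message("confusion matrix (rows = truth, cols = prediction):")
print(cv$confusion)
message("done: ", out)
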