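#!/usr/bin/env Rscript
# Step 2 — train the plain backpropagation network.
#
# Reads the simulated cohort from step 1, min-max normalizes the five RCM
# scores on the training split, trains the 5-10-1 sigmoid perceptron
# (learning rate 0.2, up to 1000 epochs, error goal 0.001) from a random
# initialization, and writes the per-epoch error curve and the per-sample
# test validation table.

library(melasmaGABP)

train <- read_cohort("results/cohort_train.csv")
test <- read_cohort("results/cohort_test.csv")
tr <- cohort_xy(train); te <- cohort_xy(test)

nz <- fit_normalizer(tr$X)
net <- network_config(seed = 2)

fit <- bp_train(net, apply_normalizer(nz, tr$X), tr$b)
print(fit)

report <- evaluate_network(fit$weights, nz, te$X, te$b, ids = test$id)
print(report)

write.csv(data.frame(epoch = seq_along(fit$error_history),
                     error = fit$error_history),
          "results/bp_error_history.csv", row.names = FALSE)
write.csv(report$rows, "results/bp_report.csv", row.names = FALSE)
writeLines(
  jsonlite::toJSON(list(V = fit$weights$V, W = fit$weights$W,
                        normalizer = list(min = nz$min, max = nz$max)),
                   digits = NA),
  "results/bp_model.json")

cat("\nconfusion over outcome grades (test):\n")
print(grade_report(report))
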