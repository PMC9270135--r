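#!/usr/bin/env Rscript
# Step 3 — train the GA-initialized network (GA-BP).
#
# Same data and training settings as step 2, but the starting weights come
# from a real-coded genetic algorithm (population 20, 40 generations,
# crossover 0.3, mutation 0.01, elitism 1) searching the 71-dimensional
# weight space for the lowest training error before gradient descent
# refines it.

library(melasmaGABP)

train <- read_cohort("results/cohort_train.csv")
test <- read_cohort("results/cohort_test.csv")
tr <- cohort_xy(train); te <- cohort_xy(test)

nz <- fit_normalizer(tr$X)
net <- network_config(seed = 2)
ga <- ga_config(seed = 3)

fit <- ga_bp_train(ga, net, apply_normalizer(nz, tr$X), tr$b)
print(fit)

report <- evaluate_network(fit$weights, nz, te$X, te$b, ids = test$id)
print(report)

write.csv(fit$evolution_trace, "results/ga_trace.csv", row.names = FALSE)
write.csv(report$rows, "results/gabp_report.csv", row.names = FALSE)

tr0 <- fit$evolution_trace
cat(sprintf("\nGA best training error: %.4f (gen 0) -> %.4f (gen %d)\n",
            tr0$best_error[1], tr0$best_error[nrow(tr0)],
            tr0$generation[nrow(tr0)]))
cat("confusion over outcome grades (test):\n")
print(grade_report(report))
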