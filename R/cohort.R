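# Synthetic patient cohorts with the structure the analysis assumes: five
# ordinal RCM severity scores per patient driving a continuous
# treatment-effect target in [0, 1]. No clinical records ship with the
# package; every cohort is generated in code.

cohort_feature_cols <- c("pigment", "dendritic", "melanophage",
                         "elastosis", "vascularity")

#' Specification of a synthetic patient cohort
#'
#' Defaults mirror the study design the evaluation pipeline assumes: 240
#' patients split 200 train / 40 test, five RCM scores each on the 1-4
#' ordinal scale, and a continuous treatment-effect target.
#'
#' @param n_patients Cohort size (default 240).
#' @param n_train,n_test Split sizes (defaults 200 / 40);
#'   `n_train + n_test <= n_patients`.
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   ground-truth target (default 0.05).
#' @param feature_weights Length-5 ground-truth effect of each RCM parameter
#'   on the target (default equal weights 0.2).
#' @param copula_rho Gaussian-copula correlation between the pigmentation and
#'   melanophage scores (default 0.4) — pigment-laden macrophages tend to
#'   accompany heavier epidermal pigmentation.
#' @param nonlinear When `TRUE`, adds an interaction between the dendritic
#'   and melanophage scores to the ground truth, to stress the hidden layer.
#' @param seed Integer seed; generation is fully reproducible from the spec.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 240L, n_train = 200L, n_test = 40L,
                        noise_sd = 0.05, feature_weights = rep(0.2, 5),
                        copula_rho = 0.4, nonlinear = FALSE, seed = 1L) {
  stopifnot(n_patients >= 1, n_train >= 1, n_test >= 1, noise_sd >= 0,
            length(feature_weights) == 5, abs(copula_rho) < 1)
  if (n_train + n_test > n_patients) {
    stop("n_train + n_test exceeds n_patients")
  }
  structure(
    list(n_patients = as.integer(n_patients), n_train = as.integer(n_train),
         n_test = as.integer(n_test), noise_sd = noise_sd,
         feature_weights = feature_weights, copula_rho = copula_rho,
         nonlinear = isTRUE(nonlinear), seed = as.integer(seed)),
    class = "cohort_spec")
}

# Ground-truth treatment effect: higher pathology scores mean a worse
# response. Linear in the (score - 1)/3 severity fractions, clipped to [0,1];
# optional dendritic x melanophage interaction.
cohort_truth <- function(scores, spec) {
  sev <- (scores - 1) / 3
  g <- 1 - as.vector(sev %*% spec$feature_weights)
  if (spec$nonlinear) g <- g - 0.15 * sev[, 2] * sev[, 3]
  pmin(pmax(g, 0), 1)
}

#' Generate a synthetic cohort
#'
#' The five scores are marginally uniform on \{1, 2, 3, 4\}, with a mild
#' Gaussian-copula correlation (`copula_rho`) between the pigmentation and
#' melanophage scores. The target is the ground truth
#' `clip(1 - sum(w_k (score_k - 1) / 3), 0, 1)` plus Gaussian noise, clipped
#' back to \[0, 1\]; the outcome grade is derived from the target via
#' [grade_outcome()].
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with columns `id`, the five score columns `pigment`,
#'   `dendritic`, `melanophage`, `elastosis`, `vascularity`, `target`, and
#'   `grade`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  R <- diag(5)
  R[1, 3] <- R[3, 1] <- spec$copula_rho
  Z <- matrix(stats::rnorm(n * 5), n, 5) %*% chol(R)
  U <- stats::pnorm(Z)
  scores <- matrix(findInterval(U, c(0.25, 0.50, 0.75)) + 1L, n, 5,
                   dimnames = list(NULL, cohort_feature_cols))
  g <- cohort_truth(scores, spec)
  target <- g
  if (spec$noise_sd > 0) {
    target <- pmin(pmax(g + stats::rnorm(n, 0, spec$noise_sd), 0), 1)
  }
  out <- data.frame(id = seq_len(n), scores, target = target)
  out$grade <- grade_outcome(out$target)
  out
}

#' Split a cohort into training and test sets
#'
#' Seeded random partition without replacement: `n_train` patients for
#' training and `n_test` disjoint patients for testing.
#'
#' @param cohort data.frame from [generate_cohort()] or [read_cohort()].
#' @param spec The [cohort_spec()] giving `n_train`, `n_test` and the seed.
#' @return List with data.frames `train` and `test`.
#' @export
split_cohort <- function(cohort, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(cohort)
  if (n < spec$n_train + spec$n_test) {
    stop("cohort has ", n, " records; need at least ",
         spec$n_train + spec$n_test)
  }
  set.seed(spec$seed + 1L)  # offset so the split reshuffles independently
  idx <- sample.int(n, spec$n_train + spec$n_test)
  list(train = cohort[idx[seq_len(spec$n_train)], , drop = FALSE],
       test = cohort[idx[spec$n_train + seq_len(spec$n_test)], , drop = FALSE])
}

#' Extract the feature matrix and target vector from a cohort
#'
#' @param cohort Cohort data.frame.
#' @return List with `X` (n x 5 numeric matrix of RCM scores) and `b`
#'   (target vector).
#' @export
cohort_xy <- function(cohort) {
  list(X = as.matrix(cohort[, cohort_feature_cols]), b = cohort$target)
}

#' Write a cohort to CSV
#'
#' Targets are written at full precision so [read_cohort()] round-trips
#' losslessly.
#'
#' @param cohort Cohort data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$target <- sprintf("%.17g", out$target)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates the schema (id, five score columns, target) and the score and
#' target ranges; a missing column or out-of-range row is reported by name
#' and line. An empty file yields an empty cohort.
#'
#' @param path CSV path written by [write_cohort()] or following the same
#'   schema.
#' @return Cohort data.frame (with `grade` recomputed from `target` if
#'   absent).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.frame(id = integer(),
                      matrix(integer(), 0, 5,
                             dimnames = list(NULL, cohort_feature_cols)),
                      target = numeric(),
                      grade = factor(character(), levels = outcome_grades,
                                     ordered = TRUE))
  if (file.size(path) == 0) return(empty)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty)
  required <- c("id", cohort_feature_cols, "target")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in cohort_feature_cols) {
    bad <- which(!df[[col]] %in% 1:4)
    if (length(bad) > 0) {
      stop("column '", col, "' out of range 1-4 at line ", bad[1] + 1L)
    }
  }
  bad <- which(!is.finite(df$target) | df$target < 0 | df$target > 1)
  if (length(bad) > 0) {
    stop("column 'target' outside [0, 1] at line ", bad[1] + 1L)
  }
  if (is.null(df$grade)) df$grade <- grade_outcome(df$target)
  else df$grade <- factor(df$grade, levels = outcome_grades, ordered = TRUE)
  df[, c(required, "grade")]
}
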