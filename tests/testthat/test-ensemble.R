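test_that("role assignments enumerate the full lexicographic hypercube", {
  expect_equal(nrow(enumerate_role_assignments(0)), 1L)
  a3 <- enumerate_role_assignments(3)
  expect_equal(nrow(a3), 8L)
  expect_equal(a3[1, ], c(tf1 = 0L, tf2 = 0L, tf3 = 0L))
  expect_equal(a3[8, ], c(tf1 = 1L, tf2 = 1L, tf3 = 1L))
  expect_equal(a3[2, ], c(tf1 = 0L, tf2 = 0L, tf3 = 1L))
  expect_false(anyDuplicated(apply(a3, 1, paste, collapse = "")) > 0)
  expect_error(enumerate_role_assignments(21), "combinatorial guard")
})

test_that("the score is a key-joined weighted log-fold SSR", {
  obs <- data.frame(construct = c("a", "a", "b"),
                    condition = c("c1", "c2", "c1"),
                    fold = c(2, 3, 0.5))
  expect_equal(score_model(obs, obs), 0)
  pred <- obs
  pred$fold[1] <- 4   # one residual of log 2
  expect_equal(score_model(pred, obs), log(2)^2, tolerance = 1e-12)
  # permuting rows leaves the score unchanged (key-based join)
  expect_equal(score_model(pred[c(3, 1, 2), ], obs), log(2)^2,
               tolerance = 1e-12)
  expect_equal(score_model(pred, obs[c(2, 3, 1), ]), log(2)^2,
               tolerance = 1e-12)
  w <- data.frame(construct = obs$construct, condition = obs$condition,
                  weight = c(3, 1, 1))
  expect_equal(score_model(pred, obs, w), 3 * log(2)^2, tolerance = 1e-12)
  bad <- obs
  bad$construct[1] <- "zz"
  expect_error(score_model(pred, bad), "mismatched keys")
})

test_that("noiseless two-TF data is recovered with near-zero score at rank one", {
  mats <- fixture_matrices()[1:2]
  prom <- fixture_promoter()
  conc <- fixture_concentrations()[1:2, ]
  spec <- thermo_spec(list(
    tf_spec("TFA", "activator", K = 1, alpha = 2),
    tf_spec("TFB", "repressor", K = 1, gamma = 0.8, beta_lr = 0.6)),
    theta = 2, concentrations = conc)
  constructs <- list(
    cA = plant_crm("cA", mats[c(1, 1)], c(20, 120), 1),
    cB = plant_crm("cB", mats[c(2, 2)], c(20, 120), 2),
    cAB = plant_crm("cAB", mats[c(1, 2)], c(20, 120), 4))
  sim <- simulate_reporter_dataset(prom, constructs, spec, mats,
                                   noise_cv = 0, seed = 1,
                                   spacer_bp = 300)
  fit <- fit_ensemble(prom, constructs, mats, sim$folds, conc,
                      n_restarts = 3, seed = 11, spacer_bp = 300)
  expect_equal(fit$assignment[1], "01")
  expect_lt(fit$score[1], 1e-6)
})

test_that("an activator-generated single-TF dataset rejects the repressor model", {
  mats <- fixture_matrices()[1]
  prom <- fixture_promoter()
  conc <- fixture_concentrations()[1, , drop = FALSE]
  spec <- thermo_spec(list(tf_spec("TFA", "activator", K = 1, alpha = 2)),
                      theta = 2, concentrations = conc)
  constructs <- list(cA = plant_crm("cA", mats[c(1, 1)], c(20, 120), 1))
  sim <- simulate_reporter_dataset(prom, constructs, spec, mats,
                                   noise_cv = 0, seed = 2, spacer_bp = 300)
  fit <- fit_ensemble(prom, constructs, mats, sim$folds, conc,
                      n_restarts = 3, seed = 5, spacer_bp = 300)
  expect_equal(fit$assignment, c("0", "1"))
  expect_lt(fit$score[1], fit$score[2])
})

test_that("fits are reproducible given the seed", {
  mats <- fixture_matrices()[1:2]
  prom <- fixture_promoter()
  conc <- fixture_concentrations()[1:2, ]
  spec <- thermo_spec(list(
    tf_spec("TFA", "activator", alpha = 2),
    tf_spec("TFB", "repressor", gamma = 0.5, beta_lr = 0.5)),
    theta = 2, concentrations = conc)
  constructs <- list(cAB = plant_crm("cAB", mats, c(20, 120), 4),
                     cA = plant_crm("cA", mats[c(1, 1)], c(20, 120), 1))
  sim <- simulate_reporter_dataset(prom, constructs, spec, mats,
                                   noise_cv = 0.05, seed = 3,
                                   spacer_bp = 300)
  f1 <- fit_ensemble(prom, constructs, mats, sim$folds, conc,
                     n_restarts = 2, seed = 21, spacer_bp = 300)
  f2 <- fit_ensemble(prom, constructs, mats, sim$folds, conc,
                     n_restarts = 2, seed = 21, spacer_bp = 300)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("a TF without sites anywhere is flagged as unidentifiable", {
  mats <- fixture_matrices()
  prom <- fixture_promoter()
  conc <- fixture_concentrations()
  constructs <- list(cA = plant_crm("cA", mats[c(1, 1)], c(20, 100), 1,
                                    length = 160))
  # TFB/TFC may or may not have chance sites; force a site-free construct
  clean <- crm_record("cA", paste0(strrep("A", 20), "ACGTAC",
                                   strrep("A", 40)), "distal_crm")
  obs <- data.frame(construct = "cA",
                    condition = c("uninduced", "IL3+OHT"),
                    fold = c(2, 1.2))
  fit <- fit_ensemble(prom, list(cA = clean), mats, obs, conc,
                      n_restarts = 1, seed = 1, spacer_bp = 100)
  expect_true(any(grepl("TFB", attr(fit, "warnings"))))
})

test_that("the score falls monotonically as a parameter approaches its true value", {
  mats <- fixture_matrices()[1:2]
  prom <- fixture_promoter()
  conc <- fixture_concentrations()[1:2, ]
  spec <- thermo_spec(list(
    tf_spec("TFA", "activator", K = 1, alpha = 2),
    tf_spec("TFB", "repressor", K = 1, gamma = 0.8, beta_lr = 0.6)),
    theta = 2, concentrations = conc)
  constructs <- list(cA = plant_crm("cA", mats[c(1, 1)], c(20, 120), 1),
                     cAB = plant_crm("cAB", mats, c(20, 120), 4))
  sim <- simulate_reporter_dataset(prom, constructs, spec, mats,
                                   noise_cv = 0, seed = 1, spacer_bp = 300)
  score_at <- function(alpha) {
    spec_a <- thermo_spec(list(
      tf_spec("TFA", "activator", K = 1, alpha = alpha),
      tf_spec("TFB", "repressor", K = 1, gamma = 0.8, beta_lr = 0.6)),
      theta = 2, concentrations = conc)
    pred <- predict_mutant_series(prom, constructs, spec_a, mats,
                                  spacer_bp = 300)
    score_model(pred, sim$folds)
  }
  line <- vapply(c(3.0, 2.75, 2.5, 2.25, 2.0), score_at, numeric(1))
  expect_true(all(diff(line) < 0))
  expect_lt(line[5], 1e-20)
})
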