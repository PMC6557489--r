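sites_row <- function(tf, start, end, q = 1) {
  data.frame(tf = tf, start = start, end = end, strand = "+",
             site_seq = NA_character_, q = q, llr = 0,
             stringsAsFactors = FALSE)
}

test_that("configuration enumeration respects exclusion and the power set", {
  spec <- fixture_spec()
  none <- enumerate_configurations(crmkit:::empty_sites(), spec, "uninduced")
  expect_length(none, 1L)
  expect_equal(none[[1]]$weight, 1)

  overlapping <- rbind(sites_row("TFA", 10, 16), sites_row("TFC", 12, 18))
  expect_length(enumerate_configurations(overlapping, spec, "uninduced"), 3L)

  free <- rbind(sites_row("TFA", 0, 6), sites_row("TFB", 10, 16),
                sites_row("TFC", 20, 26))
  expect_length(enumerate_configurations(free, spec, "uninduced"), 8L)

  big <- do.call(rbind, lapply(0:22, function(i) sites_row("TFA", i * 10,
                                                           i * 10 + 6)))
  expect_error(enumerate_configurations(big, spec, "uninduced"),
               "site_occupancies")
})

test_that("occupancies match the two-state and mutual-exclusion closed forms", {
  conc <- matrix(1, 1, 1, dimnames = list("TFA", "c1"))
  spec <- thermo_spec(list(tf_spec("TFA", "activator", K = 1, alpha = 1)),
                      theta = 1, concentrations = conc)
  one <- sites_row("TFA", 0, 6, q = 1)     # K q nu = 1
  expect_equal(as.numeric(site_occupancies(one, spec, "c1")), 0.5)

  two <- rbind(sites_row("TFA", 0, 6), sites_row("TFA", 3, 9))
  expect_equal(as.numeric(site_occupancies(two, spec, "c1")),
               c(1, 1) / 3)

  zero <- thermo_spec(list(tf_spec("TFA", "activator")), theta = 1,
                      concentrations = matrix(0, 1, 1,
                                              dimnames = list("TFA", "c1")))
  expect_equal(as.numeric(site_occupancies(two, zero, "c1")), c(0, 0))
})

test_that("DP occupancies equal brute-force enumeration on random instances", {
  for (seed in 1:50) {
    n <- sample(1:12, 1)
    sites <- random_sites(n, seed)
    spec <- random_spec(seed)
    occ <- site_occupancies(sites, spec, "c1")
    expect_lt(max(abs(as.numeric(occ) -
                        brute_occupancies(sites, spec, "c1"))), 1e-10)
  }
})

test_that("configuration probabilities sum to one", {
  for (seed in c(3, 17)) {
    sites <- random_sites(8, seed)
    spec <- random_spec(seed)
    cfgs <- enumerate_configurations(sites, spec, "c1")
    Z <- attr(site_occupancies(sites, spec, "c1"), "partition")
    expect_equal(sum(vapply(cfgs, `[[`, numeric(1), "weight")) / Z, 1,
                 tolerance = 1e-12)
  }
})

test_that("cooperativity multiplies adjacent-pair weights in both routes", {
  conc <- matrix(c(1, 1), 2, 1, dimnames = list(c("TFA", "TFB"), "c1"))
  spec <- thermo_spec(list(
    tf_spec("TFA", "activator", K = 1, alpha = 1,
            cooperativity = list(partner = "TFB", omega = 4, max_gap = 50)),
    tf_spec("TFB", "activator", K = 1, alpha = 1)),
    theta = 1, concentrations = conc)
  sites <- rbind(sites_row("TFA", 0, 6), sites_row("TFB", 10, 16))
  # Z = 1 + 1 + 1 + 4; each site bound in the single and the paired config
  occ <- site_occupancies(sites, spec, "c1")
  expect_equal(as.numeric(occ), c(5, 5) / 7)
  expect_equal(brute_occupancies(sites, spec, "c1"), c(5, 5) / 7)
  # beyond the gap the pair factor does not apply
  far <- rbind(sites_row("TFA", 0, 6), sites_row("TFB", 100, 106))
  expect_equal(as.numeric(site_occupancies(far, spec, "c1")), c(0.5, 0.5))
})

test_that("interaction strength applies quenching and long-range repression", {
  spec <- fixture_spec()
  # no repressors: weighted sum of occupancies
  acts <- rbind(sites_row("TFA", 0, 6), sites_row("TFA", 20, 26))
  st <- interaction_strength(c(0.5, 0.5), acts, spec)
  expect_equal(st$E, 2 * (0.5 * 2))   # alpha_TFA = 2
  expect_equal(st$E_prime, st$E)

  # activator with a repressor 50 bp away: O_eff = O (1 - gamma O_rep)
  spec2 <- thermo_spec(list(
    tf_spec("TFA", "activator", alpha = 1),
    tf_spec("TFB", "repressor", gamma = 1, beta_lr = 0)),
    theta = 1, concentrations = fixture_concentrations()[1:2, ])
  pair <- rbind(sites_row("TFA", 0, 6), sites_row("TFB", 56, 62))
  st2 <- interaction_strength(c(0.8, 0.5), pair, spec2)
  expect_equal(st2$activity$effective_occupancy[1], 0.4)
  expect_equal(st2$E, 0.4)

  # full dominant repression: beta_lr = 1, O = 1 annihilates E'
  spec3 <- thermo_spec(list(
    tf_spec("TFA", "activator", alpha = 3),
    tf_spec("TFB", "repressor", gamma = 0, beta_lr = 1)),
    theta = 1, concentrations = fixture_concentrations()[1:2, ])
  st3 <- interaction_strength(c(0.9, 1), pair, spec3)
  expect_equal(st3$E_prime, 0)
})

test_that("a repressor beyond the quenching range only acts long-range", {
  spec <- thermo_spec(list(
    tf_spec("TFA", "activator", alpha = 1),
    tf_spec("TFB", "repressor", gamma = 1, quench_range = 150,
            beta_lr = 0.5)),
    theta = 1, concentrations = fixture_concentrations()[1:2, ])
  # edge-to-edge distance 151 > 150: no quenching
  far <- rbind(sites_row("TFA", 0, 6), sites_row("TFB", 157, 163))
  st <- interaction_strength(c(0.8, 0.6), far, spec)
  expect_equal(st$activity$effective_occupancy[1], 0.8)
  expect_equal(st$E_prime, 0.8 * (1 - 0.5 * 0.6))
  # at exactly 150 the quenching factor applies
  at <- rbind(sites_row("TFA", 0, 6), sites_row("TFB", 156, 162))
  st2 <- interaction_strength(c(0.8, 0.6), at, spec)
  expect_equal(st2$activity$effective_occupancy[1], 0.8 * (1 - 0.6))
})

test_that("the rate law is exponential in the unfilled barrier and saturates", {
  spec <- fixture_spec(theta = 2)
  expect_equal(transcription_rate(0, spec), exp(-2))
  expect_equal(transcription_rate(2, spec), 1)
  expect_equal(transcription_rate(5, spec), 1)
  grid <- seq(0, 2, length.out = 50)
  rates <- transcription_rate(grid, spec)
  expect_true(all(diff(rates) > 0))
  expect_error(transcription_rate(-0.1, spec), "nonnegative")
})

test_that("construct predictions respect activation/repression monotonicity", {
  mats <- fixture_matrices()
  prom <- fixture_promoter()
  spec <- fixture_spec()
  expect_error(predict_construct(prom, NULL, spec, mats, "nope"),
               "no concentration vector")
  only_prom <- predict_construct(prom, NULL, spec, mats, "uninduced")
  expect_equal(only_prom$fold_vs_promoter_only, 1)

  act <- plant_crm("act", list(fixture_matrices()[[1]]), 20, seed = 2,
                   length = 100)
  p_act <- predict_construct(prom, act, spec, mats, "uninduced",
                             spacer_bp = 500)
  expect_gte(p_act$fold_vs_promoter_only, 1)

  # repressor-only distal: clean background so no chance activator sites
  repc <- crm_record("rep", paste0(strrep("A", 20), "GGATCC",
                                   strrep("A", 20)), "distal_crm")
  p_rep <- predict_construct(prom, repc, spec, mats, "IL3+OHT",
                             spacer_bp = 500)
  expect_lte(p_rep$fold_vs_promoter_only, 1)
})

test_that("raising activator concentration never lowers the rate (and dually)", {
  mats <- fixture_matrices()
  prom <- fixture_promoter()
  crm <- fixture_constructs(mats)$cAB
  for (seed in 1:10) {
    spec <- random_spec(seed, conditions = c("c1"))
    conc2 <- spec$concentrations
    conc2 <- cbind(conc2, c2 = conc2[, "c1"])
    conc2["TFA", "c2"] <- conc2["TFA", "c1"] * 3   # activator up
    spec2 <- thermo_spec(spec$tfs, spec$theta, spec$r_max, conc2)
    r1 <- predict_construct(prom, crm, spec2, mats, "c1",
                            spacer_bp = 200)$rate
    r2 <- predict_construct(prom, crm, spec2, mats, "c2",
                            spacer_bp = 200)$rate
    expect_gte(r2, r1 - 1e-12)
    conc3 <- spec$concentrations
    conc3 <- cbind(conc3, c2 = conc3[, "c1"])
    conc3["TFB", "c2"] <- conc3["TFB", "c1"] * 3   # repressor up
    spec3 <- thermo_spec(spec$tfs, spec$theta, spec$r_max, conc3)
    r3 <- predict_construct(prom, crm, spec3, mats, "c2",
                            spacer_bp = 200)$rate
    expect_lte(r3, r1 + 1e-12)
  }
})

test_that("mutating a site is equivalent to deleting it from the site list", {
  mats <- fixture_matrices()
  prom <- fixture_promoter()
  spec <- fixture_spec()
  for (seed in 1:10) {
    crm <- plant_crm("x", mats[c(1, 2)], c(30, 110), seed = seed,
                     length = 200)
    pred_wt <- predict_construct(prom, crm, spec, mats, "uninduced",
                                 spacer_bp = 300)
    sites <- pred_wt$sites
    tgt <- sites[sites$tf == "TFA" & sites$q == 1, ][1, ]
    # construct-frame target maps back into the distal CRM
    offset <- nchar(prom$sequence) + 300
    tgt_local <- tgt
    tgt_local$start <- tgt$start - offset
    tgt_local$end <- tgt$end - offset
    plan <- design_site_mutation(crm, tgt_local, mats, q_min = 0.01)
    mut <- apply_mutation_plan(crm, plan)
    pred_mut <- predict_construct(prom, mut, spec, mats, "uninduced",
                                  spacer_bp = 300)
    # the equivalence holds when the mutation touched nothing but the
    # target: site tables must agree exactly once the target is dropped
    # (collateral loss of weak sites overlapping the target is allowed by
    # the design checks and excluded here)
    wt_minus <- sites[!(sites$tf == tgt$tf & sites$start == tgt$start &
                          sites$strand == tgt$strand),
                      c("tf", "start", "strand", "q")]
    mut_tab <- pred_mut$sites[, c("tf", "start", "strand", "q")]
    if (!isTRUE(all.equal(mut_tab[order(mut_tab$tf, mut_tab$start), ],
                          wt_minus[order(wt_minus$tf, wt_minus$start), ],
                          check.attributes = FALSE))) next
    # reference: drop the target row from the wildtype construct site list
    keep <- !(sites$tf == tgt$tf & sites$start == tgt$start &
                sites$strand == tgt$strand)
    occ <- site_occupancies(sites[keep, ], spec, "uninduced")
    st <- interaction_strength(occ, sites[keep, ], spec)
    r_del <- transcription_rate(st$E_prime, spec)
    r_prom <- predict_construct(prom, NULL, spec, mats, "uninduced")$rate
    expect_equal(pred_mut$fold_vs_promoter_only, r_del / r_prom,
                 tolerance = 1e-9)
  }
})

test_that("mutant series folds move with the role of the killed site", {
  mats <- fixture_matrices()
  prom <- fixture_promoter()
  spec <- fixture_spec()
  wt <- plant_crm("wt", mats[c(1, 2)], c(30, 110), seed = 4, length = 200)
  wt_sites <- scan_sites(wt, mats, 0.01)
  kill <- function(tf) {
    tgt <- wt_sites[wt_sites$tf == tf & wt_sites$q == 1, ][1, ]
    apply_mutation_plan(wt, design_site_mutation(wt, tgt, mats, 0.01))
  }
  series <- predict_mutant_series(
    prom, list(wt = wt, no_act = kill("TFA"), no_rep = kill("TFB")),
    spec, mats, conditions = "uninduced", spacer_bp = 300)
  fold <- setNames(series$fold, series$construct)
  expect_lte(fold[["no_act"]], fold[["wt"]] + 1e-12)
  expect_gte(fold[["no_rep"]], fold[["wt"]] - 1e-12)
})
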