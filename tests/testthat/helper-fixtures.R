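# Shared fixture builders: strong count matrices with a given consensus,
# planted-site constructs, and a small 3-TF model used across the thermo,
# ensemble, and recovery tests.

make_matrix <- function(name, consensus, strong = 91, weak = 3) {
  codes <- match(strsplit(consensus, "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T"))
  counts <- matrix(weak, length(codes), 4)
  counts[cbind(seq_along(codes), codes)] <- strong
  alignment_matrix(counts, name)
}

# non-palindromic consensus strings with distinct base composition
fixture_matrices <- function() {
  list(make_matrix("TFA", "ACGTAC"),
       make_matrix("TFB", "GGATCC"),
       make_matrix("TFC", "TTGACA"))
}

plant_crm <- function(id, matrices, positions, seed, length = 300,
                      strand = "+") {
  planted <- lapply(seq_along(matrices), function(i)
    list(matrix = matrices[[i]], position = positions[i], strand = strand))
  simulate_crm(length, planted, seed = seed, id = id)$crm
}

# promoter with no binding sites for the fixture matrices
fixture_promoter <- function() {
  crm_record("prom", strrep("A", 60), "promoter")
}

fixture_concentrations <- function() {
  conc <- rbind(TFA = c(1, 0.2, 2), TFB = c(0.3, 1.5, 0.5),
                TFC = c(0.5, 1.5, 0.1))
  colnames(conc) <- c("uninduced", "IL3+OHT", "GCSF+OHT")
  conc
}

fixture_spec <- function(theta = 2) {
  thermo_spec(list(
    tf_spec("TFA", "activator", K = 1, alpha = 2),
    tf_spec("TFB", "repressor", K = 1, gamma = 0.8, beta_lr = 0.6),
    tf_spec("TFC", "activator", K = 1, alpha = 1.5)),
    theta = theta, concentrations = fixture_concentrations())
}

# six constructs with distinct site compositions for role recovery
fixture_constructs <- function(mats = fixture_matrices()) {
  list(cA  = plant_crm("cA",  mats[c(1, 1)], c(20, 120), 1),
       cB  = plant_crm("cB",  mats[c(2, 2)], c(20, 120), 2),
       cC  = plant_crm("cC",  mats[c(3, 3)], c(20, 120), 3),
       cAB = plant_crm("cAB", mats[c(1, 2)], c(20, 120), 4),
       cAC = plant_crm("cAC", mats[c(1, 3)], c(20, 120), 5),
       cBC = plant_crm("cBC", mats[c(2, 3)], c(20, 120), 6))
}

# brute-force occupancy from the explicit configuration list
brute_occupancies <- function(sites, spec, condition) {
  cfgs <- enumerate_configurations(sites, spec, condition)
  Z <- sum(vapply(cfgs, `[[`, numeric(1), "weight"))
  vapply(seq_len(nrow(sites)), function(i) {
    sum(vapply(cfgs, function(cf)
      if (i %in% cf$members) cf$weight else 0, numeric(1))) / Z
  }, numeric(1))
}

# random site table (possibly overlapping) over the fixture TFs
random_sites <- function(n, seed, span = 400, L_range = c(5, 12)) {
  set.seed(seed)
  tfs <- sample(c("TFA", "TFB", "TFC"), n, replace = TRUE)
  start <- sort(sample.int(span, n, replace = TRUE)) - 1L
  len <- sample(L_range[1]:L_range[2], n, replace = TRUE)
  data.frame(tf = tfs, start = start, end = start + len,
             strand = sample(c("+", "-"), n, TRUE),
             site_seq = NA_character_,
             q = runif(n, 0.05, 1), llr = 0, stringsAsFactors = FALSE)
}

random_spec <- function(seed, conditions = c("c1", "c2")) {
  set.seed(seed + 1)
  conc <- matrix(runif(3 * length(conditions), 0.1, 3), 3,
                 dimnames = list(c("TFA", "TFB", "TFC"), conditions))
  thermo_spec(list(
    tf_spec("TFA", "activator", K = runif(1, 0.3, 3),
            alpha = runif(1, 0.5, 3)),
    tf_spec("TFB", "repressor", K = runif(1, 0.3, 3),
            gamma = runif(1, 0, 1), beta_lr = runif(1, 0, 1)),
    tf_spec("TFC", "activator", K = runif(1, 0.3, 3),
            alpha = runif(1, 0.5, 3))),
    theta = runif(1, 0.5, 4), concentrations = conc)
}
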