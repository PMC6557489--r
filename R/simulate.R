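#' Simulate dual-luciferase luminescence with transfection variation
#'
#' Emulates the statistical structure of transient reporter assays: a
#' shared multiplicative transfection efficiency `T_i` (log-normal,
#' spanning roughly 2-4 fold across wells at the default
#' `transfection_sdlog = 0.35`), independent multiplicative measurement
#' noise on each luminescence channel, and an optional fraction of gross
#' Firefly outliers:
#' `Renilla_i = T_i (1 + eps_i)`, `Firefly_i = beta T_i (1 + delta_i)`.
#'
#' @param true_beta true Firefly/Renilla slope of the group.
#' @param n replicates (default 10).
#' @param transfection_sdlog sdlog of the log-normal transfection
#'   efficiency.
#' @param measurement_cv coefficient of variation of the mean-zero
#'   measurement noise on each channel.
#' @param outlier_frac fraction of rows whose Firefly value is multiplied
#'   by `outlier_scale`.
#' @param outlier_scale multiplier applied to outlier rows.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param construct,condition,note labels written into the table.
#' @return `list(table, truth)`: a luminescence data.frame (`firefly`,
#'   `renilla`, `construct`, `condition`, `note`) and a truth record
#'   (`true_slope`, `outlier_rows`, `seed`, `params`).
#' @export
simulate_luminescence <- function(true_beta, n = 10,
                                  transfection_sdlog = 0.35,
                                  measurement_cv = 0.1, outlier_frac = 0,
                                  outlier_scale = 10, seed = 1,
                                  construct = "synthetic",
                                  condition = "uninduced",
                                  note = "wildtype") {
  stopifnot(n >= 3, outlier_frac >= 0, outlier_frac <= 1,
            measurement_cv >= 0, transfection_sdlog >= 0)
  set.seed(seed)
  transfection <- rlnorm(n, 0, transfection_sdlog)
  eps <- rnorm(n, 0, measurement_cv)
  delta <- rnorm(n, 0, measurement_cv)
  renilla <- transfection * (1 + eps)
  firefly <- true_beta * transfection * (1 + delta)
  n_out <- round(outlier_frac * n)
  outlier_rows <- integer(0)
  if (n_out > 0) {
    outlier_rows <- sort(sample.int(n, n_out))
    firefly[outlier_rows] <- firefly[outlier_rows] * outlier_scale
  }
  table <- data.frame(firefly = firefly, renilla = renilla,
                      construct = construct, condition = condition,
                      note = note, stringsAsFactors = FALSE)
  truth <- list(true_slope = true_beta, outlier_rows = outlier_rows,
                seed = seed,
                params = list(n = n,
                              transfection_sdlog = transfection_sdlog,
                              measurement_cv = measurement_cv,
                              outlier_frac = outlier_frac,
                              outlier_scale = outlier_scale))
  list(table = table, truth = truth)
}

#' Simulate a CRM sequence with planted binding sites
#'
#' Background bases are drawn i.i.d. from the background frequencies;
#' planted positions carry the matrix consensus (reverse-complemented for
#' minus-strand plants), so [scan_sites()] recovers every planted site
#' with `q = 1`.
#'
#' @param length sequence length in bp.
#' @param planted list of `list(matrix =, position =, strand =)` plants
#'   (0-based start positions; non-overlapping and in bounds).
#' @param background base probabilities (A, C, G, T).
#' @param seed integer seed.
#' @param id record id.
#' @return `list(crm, truth)` where `truth$planted_sites` is a data.frame
#'   of `tf`, `start`, `end`, `strand`.
#' @export
simulate_crm <- function(length, planted = list(),
                         background = rep(0.25, 4), seed = 1,
                         id = "synthetic_crm") {
  stopifnot(length >= 1)
  set.seed(seed)
  chars <- sample(DNA_BASES, length, replace = TRUE, prob = background)
  plants <- lapply(planted, function(p) {
    strand <- p$strand %||% "+"
    L <- nrow(p$matrix$freq)
    if (p$position < 0 || p$position + L > length)
      stop("planted site out of bounds")
    data.frame(tf = p$matrix$tf_name, start = p$position,
               end = p$position + L, strand = strand,
               stringsAsFactors = FALSE)
  })
  truth_sites <- if (length(plants)) do.call(rbind, plants) else
    data.frame(tf = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  if (nrow(truth_sites) > 1L) {
    o <- order(truth_sites$start)
    s <- truth_sites[o, ]
    if (any(s$start[-1L] < s$end[-nrow(s)]))
      stop("planted sites overlap")
  }
  for (i in seq_along(planted)) {
    p <- planted[[i]]
    cons <- consensus_seq(p$matrix)
    if ((p$strand %||% "+") == "-") cons <- revcomp(cons)
    idx <- p$position + seq_len(nchar(cons))
    chars[idx] <- strsplit(cons, "", fixed = TRUE)[[1L]]
  }
  crm <- crm_record(id, paste(chars, collapse = ""), "distal_crm")
  list(crm = crm,
       truth = list(planted_sites = truth_sites, seed = seed))
}

#' Simulate a reporter fold-change dataset from a known model
#'
#' Ground-truth folds are the thermodynamic model's predictions for the
#' given constructs and conditions; observed folds multiply them by
#' mean-one log-normal noise with the requested coefficient of variation.
#' Optionally the folds are expanded into raw luminescence tables via
#' [simulate_luminescence()], with group slope `fold x promoter_slope`.
#'
#' @param promoter,constructs,spec,matrices as in
#'   [predict_mutant_series()].
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates luminescence replicates per group (when expanded).
#' @param seed integer seed.
#' @param conditions condition names (default: all in the spec).
#' @param as_luminescence also generate raw luminescence tables.
#' @param promoter_slope true Firefly/Renilla slope of the promoter-only
#'   group.
#' @param ... passed to [simulate_luminescence()] (noise structure).
#' @inheritParams predict_construct
#' @return `list(folds, luminescence, truth)`; `truth` carries the
#'   noiseless predictions and all seeds.
#' @export
simulate_reporter_dataset <- function(promoter, constructs, spec, matrices,
                                      noise_cv = 0.05, n_replicates = 10,
                                      seed = 1,
                                      conditions =
                                        colnames(spec$concentrations),
                                      as_luminescence = FALSE,
                                      promoter_slope = 1, spacer_bp = 2000,
                                      q_min = 0.01, ...) {
  truth_folds <- predict_mutant_series(promoter, constructs, spec,
                                       matrices, conditions, spacer_bp,
                                       q_min)
  set.seed(seed)
  sigma <- sqrt(log(1 + noise_cv^2))
  noise <- if (sigma > 0)
    rlnorm(nrow(truth_folds), -sigma^2 / 2, sigma) else
    rep(1, nrow(truth_folds))
  folds <- truth_folds
  folds$fold <- truth_folds$fold * noise
  lum <- NULL
  if (as_luminescence) {
    groups <- rbind(
      data.frame(construct = "0", condition = conditions, fold = 1,
                 stringsAsFactors = FALSE),
      folds)
    tabs <- lapply(seq_len(nrow(groups)), function(i) {
      simulate_luminescence(groups$fold[i] * promoter_slope,
                            n = n_replicates, seed = seed + i,
                            construct = groups$construct[i],
                            condition = groups$condition[i], ...)$table
    })
    lum <- do.call(rbind, tabs)
  }
  list(folds = folds, luminescence = lum,
       truth = list(true_folds = truth_folds,
                    promoter_slope = promoter_slope, noise_cv = noise_cv,
                    seed = seed))
}
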