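#' Enumerate activator/repressor role assignments
#'
#' All `2^n_tfs` combinations of per-TF roles (0 = activator,
#' 1 = repressor) in lexicographic order, first TF most significant.
#'
#' @param n_tfs number of TFs (0 to 20; larger ensembles are refused).
#' @return integer matrix `2^n_tfs x n_tfs` of role bits with an `index`
#'   attribute (0-based row encodings).
#' @export
enumerate_role_assignments <- function(n_tfs) {
  if (!is.numeric(n_tfs) || n_tfs != round(n_tfs) || n_tfs < 0)
    stop("`n_tfs` must be a nonnegative integer")
  if (n_tfs > 20)
    stop("refusing to enumerate 2^", n_tfs,
         " role assignments (combinatorial guard at n_tfs = 20)")
  n <- as.integer(n_tfs)
  idx <- seq_len(2^n) - 1L
  bits <- matrix(0L, length(idx), n)
  if (n > 0) {
    for (j in seq_len(n)) {
      bits[, j] <- idx %/% 2L^(n - j) %% 2L
    }
  }
  colnames(bits) <- if (n > 0) paste0("tf", seq_len(n)) else NULL
  attr(bits, "index") <- idx
  bits
}

#' Score predicted against observed fold-changes
#'
#' Weighted sum of squared residuals on the log-fold scale, joined by
#' (construct, condition) keys; invariant to row order, zero iff the
#' predictions equal the observations.
#'
#' @param predicted,observed data.frames with columns `construct`,
#'   `condition`, `fold`.
#' @param weights optional data.frame with columns `construct`,
#'   `condition`, `weight`; default weight 1.
#' @return nonnegative score.
#' @export
score_model <- function(predicted, observed, weights = NULL) {
  for (tb in list(predicted, observed))
    if (!all(c("construct", "condition", "fold") %in% names(tb)))
      stop("tables need columns construct, condition, fold")
  key <- function(tb) paste(tb$construct, tb$condition, sep = "\r")
  kp <- key(predicted)
  ko <- key(observed)
  if (anyDuplicated(kp) || anyDuplicated(ko))
    stop("duplicate (construct, condition) keys")
  if (!setequal(kp, ko))
    stop("predicted and observed tables have mismatched keys")
  m <- match(ko, kp)
  w <- rep(1, length(ko))
  if (!is.null(weights)) {
    kw <- key(weights)
    mw <- match(ko, kw)
    if (anyNA(mw)) stop("weights table is missing some keys")
    w <- weights$weight[mw]
  }
  res <- log(predicted$fold[m]) - log(observed$fold)
  sum(w * res^2)
}

default_fit_bounds <- function() {
  list(logK = c(-2, 2), alpha = c(0, 10), gamma = c(0, 1),
       beta_lr = c(0, 1), theta = c(0.05, 10))
}

#' Fit an ensemble of role assignments to reporter activity
#'
#' For every combination of activator/repressor roles of the TFs, fits the
#' thermodynamic model's free parameters (per-TF binding scale and
#' activation/repression efficiencies, plus the barrier `theta`) to an
#' observed fold-change table by bounded multi-start local optimization
#' (L-BFGS-B over Latin-hypercube starts), and ranks the assignments by
#' score.  `r_max` cancels in promoter-normalized folds and is fixed at 1.
#'
#' @param promoter a promoter [crm_record()].
#' @param constructs named list of distal CRM records (`NULL` for
#'   promoter-only entries); names must match `observed$construct`.
#' @param matrices list of [alignment_matrix()] objects, one per TF; their
#'   `tf_name`s define the TF set and its order.
#' @param observed data.frame with columns `construct`, `condition`,
#'   `fold` covering at least two conditions.
#' @param concentrations TF x condition concentration matrix (rows named
#'   by TF).
#' @param bounds named list overriding [default bounds][fit_ensemble]
#'   `logK`, `alpha`, `gamma`, `beta_lr`, `theta` (each `c(lo, hi)`).
#' @param n_restarts Latin-hypercube multi-starts per assignment.
#' @param seed integer seed; the whole run is reproducible given it.
#' @param quench_range quenching distance in bp.
#' @param spacer_bp,q_min construct assembly and scanning settings.
#' @param control passed to [stats::optim()] (defaults
#'   `maxit = 100`, `factr = 1e7`).
#' @return data.frame of fit results sorted by ascending score: role bits
#'   (one column per TF), `index`, `score`, `converged`, and fitted
#'   parameters; full per-assignment detail in `attr(, "fits")`, any
#'   identifiability warnings in `attr(, "warnings")`.
#' @export
fit_ensemble <- function(promoter, constructs, matrices, observed,
                         concentrations, bounds = NULL, n_restarts = 3,
                         seed = 1, quench_range = 150, spacer_bp = 2000,
                         q_min = 0.01, control = list()) {
  tf_names <- vapply(matrices, `[[`, character(1), "tf_name")
  n_tf <- length(tf_names)
  conc <- as.matrix(concentrations)[tf_names, , drop = FALSE]
  conditions <- colnames(conc)
  if (length(unique(observed$condition)) < 2L)
    stop("`observed` must cover at least two conditions")
  if (!all(observed$condition %in% conditions))
    stop("observed conditions missing from `concentrations`")
  if (!all(observed$construct %in% names(constructs)))
    stop("observed constructs missing from `constructs`")
  bounds <- modifyList(default_fit_bounds(), bounds %||% list())
  control <- modifyList(list(maxit = 100, factr = 1e7), control)

  # sites are parameter-independent: scan each construct once
  tf_index <- setNames(seq_len(n_tf), tf_names)
  site_table <- function(rec) {
    s <- scan_sites(rec, matrices, q_min)
    cbind(start = s$start, end = s$end, tf = tf_index[s$tf], q = s$q)
  }
  prom_sites <- site_table(promoter)
  tables <- lapply(constructs, function(d) {
    if (is.null(d)) return(prom_sites)
    site_table(crm_record("c", paste0(promoter$sequence,
                                      strrep("N", spacer_bp), d$sequence)))
  })
  warnings <- character(0)
  seen <- unique(unlist(lapply(c(tables, list(prom_sites)),
                               function(tb) tb[, "tf"])))
  absent <- setdiff(seq_len(n_tf), seen)
  if (length(absent)) {
    warnings <- paste0("TF '", tf_names[absent],
                       "' has no sites in any construct; ",
                       "its parameters are unidentifiable")
  }
  # align observed folds into a construct x condition matrix
  cons_names <- names(constructs)
  obs <- matrix(NA_real_, length(cons_names), length(conditions),
                dimnames = list(cons_names, conditions))
  obs[cbind(match(observed$construct, cons_names),
            match(observed$condition, conditions))] <- observed$fold
  obs_log <- log(obs)
  wt <- !is.na(obs_log)

  assignments <- enumerate_role_assignments(n_tf)
  # parameter layout per assignment: logK (all), alpha (activators),
  # gamma + beta_lr (repressors), theta
  layout_for <- function(role) {
    lower <- rep(bounds$logK[1], n_tf)
    upper <- rep(bounds$logK[2], n_tf)
    nm <- paste0("logK_", tf_names)
    for (i in seq_len(n_tf)) {
      if (role[i] == 0L) {
        lower <- c(lower, bounds$alpha[1]); upper <- c(upper, bounds$alpha[2])
        nm <- c(nm, paste0("alpha_", tf_names[i]))
      } else {
        lower <- c(lower, bounds$gamma[1], bounds$beta_lr[1])
        upper <- c(upper, bounds$gamma[2], bounds$beta_lr[2])
        nm <- c(nm, paste0("gamma_", tf_names[i]),
                paste0("beta_lr_", tf_names[i]))
      }
    }
    lower <- c(lower, bounds$theta[1])
    upper <- c(upper, bounds$theta[2])
    nm <- c(nm, "theta")
    list(lower = lower, upper = upper, names = nm)
  }
  unpack <- function(par, role) {
    K <- 10^par[seq_len(n_tf)]
    alpha <- numeric(n_tf); gamma <- numeric(n_tf); beta_lr <- numeric(n_tf)
    p <- n_tf
    for (i in seq_len(n_tf)) {
      if (role[i] == 0L) {
        alpha[i] <- par[p <- p + 1L]
      } else {
        gamma[i] <- par[p <- p + 1L]
        beta_lr[i] <- par[p <- p + 1L]
      }
    }
    list(K = K, alpha = alpha, gamma = gamma, beta_lr = beta_lr,
         theta = par[p + 1L])
  }

  set.seed(seed)
  fits <- vector("list", nrow(assignments))
  for (a in seq_len(nrow(assignments))) {
    role <- as.integer(assignments[a, ])
    lay <- layout_for(role)
    npar <- length(lay$lower)
    objective <- function(par) {
      pp <- unpack(par, role)
      pred <- .predict_folds_cpp(tables, prom_sites, conc, role, pp$K,
                                 pp$alpha, pp$gamma, pp$beta_lr,
                                 quench_range, pp$theta, 1)
      sum((log(pred)[wt] - obs_log[wt])^2)
    }
    starts <- lhs::randomLHS(n_restarts, npar)
    best <- NULL
    conv <- FALSE
    for (s in seq_len(n_restarts)) {
      p0 <- lay$lower + starts[s, ] * (lay$upper - lay$lower)
      opt <- try(optim(p0, objective, method = "L-BFGS-B",
                       lower = lay$lower, upper = lay$upper,
                       control = control), silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (is.null(best) || opt$value < best$value) {
        best <- opt
        conv <- opt$convergence == 0
      }
    }
    if (is.null(best))
      stop("all optimizer starts failed for assignment ", a)
    pp <- unpack(best$par, role)
    fits[[a]] <- list(index = attr(assignments, "index")[a], role = role,
                      score = best$value, par = setNames(best$par,
                                                         lay$names),
                      params = pp, converged = conv)
  }
  scores <- vapply(fits, `[[`, numeric(1), "score")
  ord <- order(scores)
  out <- data.frame(
    index = vapply(fits, `[[`, numeric(1), "index")[ord],
    assignment = vapply(fits, function(f)
      paste(f$role, collapse = ""), character(1))[ord],
    score = scores[ord],
    converged = vapply(fits, `[[`, logical(1), "converged")[ord],
    stringsAsFactors = FALSE)
  roles_mat <- do.call(rbind, lapply(fits, `[[`, "role"))[ord, ,
                                                          drop = FALSE]
  colnames(roles_mat) <- paste0("role_", tf_names)
  out <- cbind(out, as.data.frame(roles_mat))
  attr(out, "fits") <- fits[ord]
  attr(out, "warnings") <- warnings
  attr(out, "seed") <- seed
  attr(out, "n_restarts") <- n_restarts
  class(out) <- c("ensemble_fit", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
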