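#' Enumerate all binding configurations (brute-force oracle)
#'
#' Explicitly lists every subset of pairwise non-overlapping sites together
#' with its statistical weight (product of site weights `K * q * nu` and of
#' cooperativity factors between consecutive bound sites).  Intended as the
#' small-instance oracle for [site_occupancies()]; refuses more than 22
#' sites.
#'
#' @param sites a [scan_sites()] table.
#' @param spec a [thermo_spec()].
#' @param condition condition name selecting the concentration vector.
#' @return list of configurations, each `list(members =, weight =)`;
#'   `members` are row indices into `sites` (empty configuration first,
#'   weight 1).
#' @export
enumerate_configurations <- function(sites, spec, condition) {
  n <- nrow(sites)
  if (n > 22L)
    stop("too many sites (", n, ") for explicit enumeration; ",
         "use site_occupancies()")
  if (n == 0L) return(list(list(members = integer(0), weight = 1)))
  prep <- site_weights(sites, spec, condition)
  ord <- order(sites$start, sites$end)
  w <- prep$w[ord]
  st <- sites$start[ord]
  en <- sites$end[ord]
  omega <- prep$omega[ord, ord, drop = FALSE]
  configs <- list(list(members = integer(0), weight = 1))
  # depth-first over sites in coordinate order; prune overlapping branches
  recurse <- function(i, members, max_end, last, weight) {
    if (i > n) return(invisible())
    recurse(i + 1L, members, max_end, last, weight)
    if (st[i] >= max_end) {
      wt <- weight * w[i]
      if (last > 0L) wt <- wt * omega[last, i]
      configs[[length(configs) + 1L]] <<-
        list(members = ord[c(members, i)], weight = wt)
      recurse(i + 1L, c(members, i), en[i], i, wt)
    }
  }
  recurse(1L, integer(0), -Inf, 0L, 1)
  configs
}

#' Thermodynamic fractional occupancy of each site
#'
#' Computes, for every annotated site, the Boltzmann-weighted fraction of
#' binding configurations that contain it, using a partition-function
#' dynamic programme over the sites sorted by start.  Overlapping sites are
#' never co-bound; declared cooperative pairs multiply configuration
#' weights by `omega`.
#'
#' @inheritParams enumerate_configurations
#' @return numeric vector of occupancies in `[0, 1]`, one per row of
#'   `sites` (in input order), with attributes `partition` (the partition
#'   function) and `condition`.
#' @export
site_occupancies <- function(sites, spec, condition) {
  n <- nrow(sites)
  if (n == 0L)
    return(structure(numeric(0), partition = 1, condition = condition))
  prep <- site_weights(sites, spec, condition)
  ord <- order(sites$start, sites$end)
  res <- .occ_dp_cpp(as.integer(sites$start[ord]),
                     as.integer(sites$end[ord]),
                     prep$w[ord], prep$omega[ord, ord, drop = FALSE])
  occ <- numeric(n)
  occ[ord] <- res$occupancy
  structure(occ, partition = res$partition, condition = condition)
}

# weights w_i = K * q * nu and the cooperativity factor matrix
site_weights <- function(sites, spec, condition) {
  check_sites_in_spec(sites, spec)
  nu <- conc_for(spec, condition)
  n <- nrow(sites)
  K <- vapply(spec$tfs[sites$tf], `[[`, numeric(1), "K")
  w <- K * sites$q * nu[sites$tf]
  omega <- matrix(1, n, n)
  for (i in seq_len(n)) {
    coop <- spec$tfs[[sites$tf[i]]]$cooperativity
    if (is.null(coop)) next
    for (j in seq_len(n)) {
      if (i == j) next
      if (sites$tf[j] != coop$partner) next
      gap <- max(sites$start[j] - sites$end[i],
                 sites$start[i] - sites$end[j])
      if (gap >= 0 && gap <= coop$max_gap) {
        omega[i, j] <- coop$omega
        omega[j, i] <- coop$omega
      }
    }
  }
  list(w = w, omega = omega)
}

#' Interaction strength with quenching and long-range repression
#'
#' Effective activator occupancies are reduced by every repressor site
#' within the repressor's quenching range (edge-to-edge):
#' `O_eff = O * prod_j (1 - gamma_j * O_j)`.  The interaction strength is
#' the efficiency-weighted sum `E = sum_i alpha_i * O_eff_i` over activator
#' sites.  Long-range (dominant) repression then scales it by
#' `(1 - beta_lr_j * O_j)` over all repressor sites, giving `E'`.
#'
#' @param occ occupancies from [site_occupancies()] (aligned with `sites`).
#' @param sites the site table the occupancies were computed for.
#' @param spec a [thermo_spec()].
#' @return `list(E, E_prime, activity)` where `activity` is a per-site
#'   data.frame: activator rows carry the barrier-reduction contribution
#'   `alpha * O_eff`, repressor rows the interaction-strength reduction
#'   fraction `beta_lr * O`.
#' @export
interaction_strength <- function(occ, sites, spec) {
  check_sites_in_spec(sites, spec)
  n <- nrow(sites)
  stopifnot(length(occ) == n)
  roles <- vapply(spec$tfs[sites$tf], `[[`, character(1), "role")
  is_rep <- roles == "repressor"
  o_eff <- as.numeric(occ)
  if (any(is_rep) && any(!is_rep)) {
    for (i in which(!is_rep)) {
      for (j in which(is_rep)) {
        tfj <- spec$tfs[[sites$tf[j]]]
        d <- max(sites$start[j] - sites$end[i],
                 sites$start[i] - sites$end[j], 0)
        if (d <= tfj$quench_range)
          o_eff[i] <- o_eff[i] * (1 - tfj$gamma * occ[j])
      }
      o_eff[i] <- max(o_eff[i], 0)
    }
  }
  alpha <- ifelse(is_rep, 0,
                  vapply(spec$tfs[sites$tf], function(tf)
                    if (tf$role == "activator") tf$alpha else 0, numeric(1)))
  E <- sum(alpha[!is_rep] * o_eff[!is_rep])
  longrange <- 1
  rep_frac <- rep(NA_real_, n)
  for (j in which(is_rep)) {
    b <- spec$tfs[[sites$tf[j]]]$beta_lr
    rep_frac[j] <- b * occ[j]
    longrange <- longrange * (1 - rep_frac[j])
  }
  activity <- data.frame(
    tf = sites$tf, start = sites$start, end = sites$end, role = roles,
    occupancy = as.numeric(occ), effective_occupancy = o_eff,
    barrier_reduction = ifelse(is_rep, NA_real_, alpha * o_eff),
    strength_reduction = rep_frac, stringsAsFactors = FALSE)
  list(E = E, E_prime = E * longrange, activity = activity)
}

#' Transcription rate from interaction strength
#'
#' Initiation is modelled as an enzymatic reaction with an activation
#' barrier `theta` that bound activators lower:
#' `rate = r_max * exp(-max(0, theta - E'))`.  The basal rate is
#' `r_max * exp(-theta)` at `E' = 0`; the rate saturates at `r_max` for
#' `E' >= theta`.
#'
#' @param e_prime post-repression interaction strength (nonnegative;
#'   vectorized).
#' @param spec a [thermo_spec()].
#' @return transcription rate(s) in `(0, r_max]`.
#' @export
transcription_rate <- function(e_prime, spec) {
  if (any(e_prime < 0)) stop("`e_prime` must be nonnegative")
  spec$r_max * exp(-pmax(0, spec$theta - e_prime))
}

#' Predict activity of a reporter construct
#'
#' Concatenates the promoter, a site-free spacer (vector backbone
#' stand-in, `N` bases), and the distal CRM into one coordinate frame, and
#' runs scan, occupancy, interaction strength, and rate.  The fold is the
#' construct rate over the promoter-alone rate in the same condition.
#'
#' @param promoter a promoter [crm_record()].
#' @param distal a distal CRM [crm_record()], or `NULL` for the
#'   promoter-only construct.
#' @param spec a [thermo_spec()].
#' @param matrices list of [alignment_matrix()] objects.
#' @param condition condition name.
#' @param spacer_bp spacer length between promoter and distal CRM
#'   (default 2000).
#' @param q_min site-calling threshold.
#' @return a `transcription_prediction`: list with `E`, `E_prime`, `rate`,
#'   `fold_vs_promoter_only`, `site_activity`, `sites`, `condition`.
#' @export
predict_construct <- function(promoter, distal = NULL, spec, matrices,
                              condition, spacer_bp = 2000, q_min = 0.01) {
  conc_for(spec, condition)  # validate early
  seqs <- promoter$sequence
  id <- promoter$id
  if (!is.null(distal)) {
    seqs <- paste0(promoter$sequence, strrep("N", spacer_bp),
                   distal$sequence)
    id <- paste0(promoter$id, "+", distal$id)
  }
  construct <- crm_record(id, seqs, "construct")
  rate_of <- function(rec) {
    sites <- scan_sites(rec, matrices, q_min)
    occ <- site_occupancies(sites, spec, condition)
    st <- interaction_strength(occ, sites, spec)
    list(rate = transcription_rate(st$E_prime, spec), st = st,
         sites = sites)
  }
  full <- rate_of(construct)
  base <- if (is.null(distal)) full else rate_of(promoter)
  structure(list(E = full$st$E, E_prime = full$st$E_prime,
                 rate = full$rate,
                 fold_vs_promoter_only = full$rate / base$rate,
                 site_activity = full$st$activity, sites = full$sites,
                 condition = condition, construct = id),
            class = "transcription_prediction")
}

#' @export
print.transcription_prediction <- function(x, ...) {
  cat(sprintf("<prediction> %s [%s]: rate %.4g, fold vs promoter %.3f\n",
              x$construct, x$condition, x$rate, x$fold_vs_promoter_only))
  invisible(x)
}

#' Predicted fold-changes for a series of constructs
#'
#' One fold per construct and condition, each normalized to the
#' promoter-only construct in that condition.
#'
#' @param promoter a promoter [crm_record()].
#' @param distals named list of distal CRM records (`NULL` entries denote
#'   the promoter-only construct).
#' @inheritParams predict_construct
#' @param conditions condition names (default: all in the spec).
#' @return data.frame with columns `construct`, `condition`, `fold`.
#' @export
predict_mutant_series <- function(promoter, distals, spec, matrices,
                                  conditions = colnames(spec$concentrations),
                                  spacer_bp = 2000, q_min = 0.01) {
  stopifnot(length(names(distals)) == length(distals))
  rows <- lapply(names(distals), function(nm) {
    folds <- vapply(conditions, function(cond) {
      predict_construct(promoter, distals[[nm]], spec, matrices, cond,
                        spacer_bp, q_min)$fold_vs_promoter_only
    }, numeric(1))
    data.frame(construct = nm, condition = conditions, fold = folds,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
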