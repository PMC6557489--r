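#' Transcription-factor specification for the thermodynamic model
#'
#' Each factor is either an activator or a repressor.  Activators carry an
#' activation efficiency `alpha` (the weight of their occupancy in the
#' interaction strength, in units of the barrier `theta`).  Repressors
#' carry a quenching efficiency `gamma` acting within `quench_range` bp
#' (edge-to-edge) of activator sites, and a long-range repression
#' efficiency `beta_lr` that scales down the interaction strength
#' irrespective of distance (dominant repression).  `K` is the binding
#' scale multiplying relative affinity and concentration in a site's
#' statistical weight.
#'
#' @param name TF name; must match the `tf` column of site tables.
#' @param role `"activator"` or `"repressor"`.
#' @param K positive binding scale.
#' @param alpha activation efficiency (activators), nonnegative.
#' @param gamma quenching efficiency in `[0, 1]` (repressors).
#' @param quench_range quenching distance in bp (default 150).
#' @param beta_lr long-range repression efficiency in `[0, 1]` (repressors).
#' @param cooperativity optional `list(partner =, omega =, max_gap =)`
#'   declaring a cooperative partner pair (`omega >= 0`, gap in bp,
#'   default gap 50).
#' @return a `tf_spec`.
#' @export
tf_spec <- function(name, role = c("activator", "repressor"), K = 1,
                    alpha = 1, gamma = 0.5, quench_range = 150,
                    beta_lr = 0.5, cooperativity = NULL) {
  role <- match.arg(role)
  if (!is.numeric(K) || K <= 0) stop("`K` must be positive")
  out <- list(name = as.character(name), role = role, K = K,
              alpha = NULL, gamma = NULL, quench_range = NULL,
              beta_lr = NULL, cooperativity = cooperativity)
  if (role == "activator") {
    if (alpha < 0) stop("`alpha` must be nonnegative")
    out$alpha <- alpha
  } else {
    if (gamma < 0 || gamma > 1) stop("`gamma` must be in [0, 1]")
    if (beta_lr < 0 || beta_lr > 1) stop("`beta_lr` must be in [0, 1]")
    if (quench_range < 0) stop("`quench_range` must be nonnegative")
    out$gamma <- gamma
    out$quench_range <- quench_range
    out$beta_lr <- beta_lr
  }
  if (!is.null(cooperativity)) {
    if (is.null(cooperativity$partner) || is.null(cooperativity$omega))
      stop("cooperativity needs `partner` and `omega`")
    if (cooperativity$omega < 0) stop("`omega` must be >= 0")
    if (is.null(cooperativity$max_gap)) out$cooperativity$max_gap <- 50
  }
  structure(out, class = "tf_spec")
}

#' Full thermodynamic model specification
#'
#' @param tfs list of [tf_spec()] objects (unique names).
#' @param theta positive activation-energy barrier.
#' @param r_max positive maximal transcription rate.
#' @param concentrations numeric matrix of TF concentrations, rows named by
#'   TF, columns named by condition; all values nonnegative.
#' @return a `thermo_spec`.
#' @export
thermo_spec <- function(tfs, theta, r_max = 1, concentrations) {
  if (inherits(tfs, "tf_spec")) tfs <- list(tfs)
  nm <- vapply(tfs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("TF names must be unique")
  names(tfs) <- nm
  if (!is.numeric(theta) || theta <= 0) stop("`theta` must be positive")
  if (!is.numeric(r_max) || r_max <= 0) stop("`r_max` must be positive")
  concentrations <- as.matrix(concentrations)
  if (is.null(rownames(concentrations)) || is.null(colnames(concentrations)))
    stop("`concentrations` must have TF row names and condition col names")
  missing_tf <- setdiff(nm, rownames(concentrations))
  if (length(missing_tf))
    stop("no concentrations for TF(s): ", paste(missing_tf, collapse = ", "))
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and nonnegative")
  structure(list(tfs = tfs, theta = theta, r_max = r_max,
                 concentrations = concentrations),
            class = "thermo_spec")
}

#' @export
print.thermo_spec <- function(x, ...) {
  roles <- vapply(x$tfs, `[[`, character(1), "role")
  cat("<thermo_spec>", length(x$tfs), "TFs (",
      sum(roles == "activator"), "activators,",
      sum(roles == "repressor"), "repressors ), theta =", x$theta,
      ", conditions:", paste(colnames(x$concentrations), collapse = ", "),
      "\n")
  invisible(x)
}

conc_for <- function(spec, condition) {
  if (!condition %in% colnames(spec$concentrations))
    stop("no concentration vector for condition '", condition, "'")
  setNames(spec$concentrations[, condition],
           rownames(spec$concentrations))
}

check_sites_in_spec <- function(sites, spec) {
  unknown <- setdiff(unique(sites$tf), names(spec$tfs))
  if (length(unknown))
    stop("site TF(s) not in the model spec: ",
         paste(unknown, collapse = ", "))
}

#' Read a model specification from a YAML file
#'
#' The file carries `theta`, `r_max`, a `tfs` list (each entry: `name`,
#' `role`, `K`, and role-specific fields as in [tf_spec()]), and a
#' `concentrations` mapping of condition name to named TF values.
#'
#' @param path YAML file.
#' @return a [thermo_spec()].
#' @export
read_thermo_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("theta", "tfs", "concentrations"))
    if (is.null(cfg[[f]])) stop("model spec is missing field `", f, "`")
  tfs <- lapply(cfg$tfs, function(tf) {
    args <- tf
    do.call(tf_spec, args)
  })
  nm <- vapply(tfs, `[[`, character(1), "name")
  conc <- matrix(NA_real_, length(nm), length(cfg$concentrations),
                 dimnames = list(nm, names(cfg$concentrations)))
  for (cond in names(cfg$concentrations)) {
    v <- unlist(cfg$concentrations[[cond]])[nm]
    if (anyNA(v)) stop("condition '", cond,
                       "' is missing concentrations for some TFs")
    conc[, cond] <- v
  }
  thermo_spec(tfs, theta = cfg$theta,
              r_max = if (is.null(cfg$r_max)) 1 else cfg$r_max,
              concentrations = conc)
}
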