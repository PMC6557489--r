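#' Load a dual-luciferase luminescence table
#'
#' Reads a CSV in the supplementary-dataset dialect: `Luc`/`Firefly` and
#' `Ren`/`Renilla` luminescence columns, a `Construct` column (`"0"` is
#' the promoter-only reference), and either an explicit `Condition` column
#' or `OHT` (true/false) plus `Cytokine` columns, which are mapped to
#' canonical condition names (`uninduced`, `IL3+OHT`, `GCSF+OHT`; tables
#' without cytokine information map induced rows to `G1ME`).  An optional
#' `Note` column carries wildtype/mutated-site annotations.  Rows with
#' non-finite luminescence are dropped with a message.
#'
#' @param path CSV file.
#' @param condition_map optional named character vector overriding the
#'   `oht:cytokine` to condition mapping, e.g.
#'   `c("false:IL3" = "uninduced")`.
#' @return data.frame with columns `firefly`, `renilla`, `construct`,
#'   `condition`, `note`.
#' @export
load_luminescence_table <- function(path, condition_map = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  pick <- function(aliases, required = TRUE) {
    hit <- intersect(aliases, names(raw))
    if (!length(hit)) {
      if (required)
        stop("missing required column: one of ",
             paste(aliases, collapse = "/"))
      return(NULL)
    }
    raw[[hit[1L]]]
  }
  firefly <- suppressWarnings(as.numeric(pick(c("luc", "firefly"))))
  renilla <- suppressWarnings(as.numeric(pick(c("ren", "renilla"))))
  construct <- as.character(pick(c("construct")))
  if (any(!nzchar(construct))) stop("construct ids must be non-empty")
  note <- pick(c("note"), required = FALSE)
  condition <- pick(c("condition"), required = FALSE)
  if (is.null(condition)) {
    oht <- pick(c("oht"), required = FALSE)
    cytokine <- pick(c("cytokine"), required = FALSE)
    if (is.null(oht))
      stop("missing required column: condition (or oht/cytokine)")
    oht <- tolower(as.character(oht)) %in% c("true", "t", "1", "yes")
    key <- paste(ifelse(oht, "true", "false"),
                 if (is.null(cytokine)) "" else toupper(cytokine),
                 sep = ":")
    map <- c("false:IL3" = "uninduced", "false:GCSF" = "uninduced",
             "false:" = "uninduced", "true:IL3" = "IL3+OHT",
             "true:GCSF" = "GCSF+OHT", "true:" = "G1ME")
    if (!is.null(condition_map)) map[names(condition_map)] <- condition_map
    condition <- unname(map[key])
    if (anyNA(condition))
      stop("unmapped oht/cytokine combination(s): ",
           paste(unique(key[is.na(condition)]), collapse = ", "))
  }
  out <- data.frame(firefly = firefly, renilla = renilla,
                    construct = construct, condition = condition,
                    note = if (is.null(note)) NA_character_ else note,
                    stringsAsFactors = FALSE)
  bad <- !is.finite(out$firefly) | !is.finite(out$renilla)
  if (any(bad)) {
    message("dropping ", sum(bad), " row(s) with non-finite luminescence")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Fold-change of a construct relative to the promoter-only reference
#'
#' Construct activity is the robust EIV slope of Firefly against Renilla
#' luminescence for its replicate group; the fold-change is its ratio to
#' the promoter-only slope.  Two normalization conventions are supported:
#' `vs_uninduced_promoter` divides by the promoter in uninduced
#' conditions for every condition, `vs_same_condition_promoter` divides
#' by the promoter assayed in the same condition.  The confidence
#' interval pairs independent bootstrap replicate streams of numerator
#' and denominator by replicate index and applies the basic bootstrap to
#' the ratio.
#'
#' @param table a [load_luminescence_table()] data.frame.
#' @param construct construct id.
#' @param condition condition name.
#' @param mode normalization convention (see above).
#' @param config a [robust_config()].
#' @param seed integer seed; when supplied a bootstrap CI is attached.
#' @param reference_construct promoter-only id (default `"0"`).
#' @param reference_condition condition of the reference group under
#'   `vs_uninduced_promoter` (default `"uninduced"`).
#' @return one-row data.frame: `construct`, `condition`, `mode`, `value`,
#'   `ci_low`, `ci_high`, `n`, `n_ref`.
#' @export
fold_change <- function(table, construct, condition,
                        mode = c("vs_same_condition_promoter",
                                 "vs_uninduced_promoter"),
                        config = robust_config(), seed = NULL,
                        reference_construct = "0",
                        reference_condition = "uninduced") {
  mode <- match.arg(mode)
  ref_cond <- switch(mode, vs_same_condition_promoter = condition,
                     vs_uninduced_promoter = reference_condition)
  num <- table[table$construct == construct &
                 table$condition == condition, , drop = FALSE]
  ref <- table[table$construct == reference_construct &
                 table$condition == ref_cond, , drop = FALSE]
  if (nrow(ref) == 0L)
    stop("missing reference group (", reference_construct, ", ", ref_cond,
         ")")
  if (nrow(num) < 3L || nrow(ref) < 3L)
    stop("both groups need at least 3 replicates")
  fit_n <- eiv_slope(num$renilla, num$firefly, config)
  fit_r <- eiv_slope(ref$renilla, ref$firefly, config)
  value <- fit_n$beta / fit_r$beta
  ci_low <- ci_high <- NA_real_
  if (!is.null(seed)) {
    reps_n <- boot_replicates(fit_n, config, seed)
    reps_r <- boot_replicates(fit_r, config, seed + 1L)
    ratio <- reps_n / reps_r
    ok <- is.finite(ratio)
    if (sum(!ok) > 0.1 * config$n_boot)
      stop(sum(!ok), " of ", config$n_boot,
           " bootstrap ratio replicates failed")
    a <- (1 - config$ci_level) / 2
    qs <- quantile(ratio[ok], c(1 - a, a), names = FALSE)
    ci_low <- 2 * value - qs[1]
    ci_high <- 2 * value - qs[2]
  }
  data.frame(construct = construct, condition = condition, mode = mode,
             value = value, ci_low = ci_low, ci_high = ci_high,
             n = nrow(num), n_ref = nrow(ref), stringsAsFactors = FALSE)
}

#' Classify constructs as enhancers, silencers, or neutral
#'
#' A construct is an enhancer if its fold-change CI lies above 1 in any
#' condition; a silencer if the CI lies below 1 in any condition and it is
#' never an enhancer; neutral otherwise.  Constructs showing both
#' patterns are flagged as conflicting.
#'
#' @param folds data.frame of [fold_change()] rows (CIs required).
#' @return data.frame with one row per construct: `construct`, `class`,
#'   `conflict`.
#' @export
classify_crm <- function(folds) {
  if (any(!is.finite(folds$ci_low)) || any(!is.finite(folds$ci_high)))
    stop("classification requires confidence intervals")
  out <- lapply(split(folds, folds$construct), function(g) {
    enh <- any(g$ci_low > 1)
    sil <- any(g$ci_high < 1)
    data.frame(construct = g$construct[1L],
               class = if (enh) "enhancer" else if (sil) "silencer"
                       else "neutral",
               conflict = enh && sil, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' qPCR relative expression normalized to uninduced samples
#'
#' Per-sample relative expression of the target against the reference
#' gene, `2^-(Ct_target - Ct_reference)`, normalized so the mean over
#' uninduced replicates is 1.
#'
#' @param records data.frame with columns `ct_target`, `ct_reference` and
#'   a logical `oht` column (`FALSE` = uninduced); other columns (time,
#'   replicate, cytokine) are carried through.
#' @return the input with `raw` and `relative` columns appended.
#' @export
qpcr_relative_expression <- function(records) {
  need <- c("ct_target", "ct_reference", "oht")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  ct_t <- records$ct_target
  ct_r <- records$ct_reference
  if (any(!is.finite(ct_t)) || any(!is.finite(ct_r)))
    stop("both Ct values must be present for every record")
  if (any(ct_t <= 0 | ct_t >= 45 | ct_r <= 0 | ct_r >= 45))
    stop("Ct values must lie in (0, 45)")
  raw <- 2^(-(ct_t - ct_r))
  unind <- !records$oht
  if (!any(unind))
    stop("no uninduced replicates to normalize against")
  records$raw <- raw
  records$relative <- raw / mean(raw[unind])
  records
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact two-sided distribution when the combined sample size is at most
#' 20 and there are no ties; mid-rank handling with the normal
#' approximation and continuity correction otherwise.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return `list(statistic, p_value, exact)`.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= 20L
  ht <- wilcox.test(a, b, exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = exact)
}
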