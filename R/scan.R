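#' Annotate binding sites on a CRM sequence
#'
#' Scans both strands of a sequence with a set of alignment matrices and
#' reports every window whose affinity relative to the consensus site is at
#' least `q_min`.  Coordinates are 0-based, half-open, on the forward
#' strand.  Windows overlapping an `N` base are never reported.  When the
#' same matrix matches both strands at the same start, only the better
#' strand is kept; hits of the same matrix at different starts are all
#' kept.
#'
#' @param crm a [crm_record()].
#' @param matrices list of [alignment_matrix()] objects.
#' @param q_min site-calling threshold on relative affinity, in (0, 1].
#'   The default 0.01 keeps the weak sites a thermodynamic model uses.
#' @return a data.frame with columns `tf`, `start`, `end`, `strand`,
#'   `site_seq`, `q`, `llr`, sorted by `start`.
#' @export
scan_sites <- function(crm, matrices, q_min = 0.01) {
  stopifnot(inherits(crm, "crm_record"))
  if (length(matrices) == 0L)
    stop("no alignment matrices supplied (configuration error)")
  if (!is.numeric(q_min) || length(q_min) != 1L || q_min <= 0 || q_min > 1)
    stop("`q_min` must be in (0, 1]")
  fwd <- crm$sequence
  rev <- revcomp(fwd)
  n <- nchar(fwd)
  code_f <- encode_dna(fwd)
  code_r <- encode_dna(rev)
  hits <- lapply(matrices, function(am) {
    rbind(scan_one(am, code_f, fwd, n, "+"),
          scan_one(am, code_r, rev, n, "-"))
  })
  out <- do.call(rbind, hits)
  if (is.null(out) || nrow(out) == 0L) return(empty_sites())
  out <- out[out$q >= q_min, , drop = FALSE]
  if (nrow(out) == 0L) return(empty_sites())
  # same matrix, same start, both strands: keep the better strand
  out <- out[order(out$tf, out$start, -out$q, out$strand), , drop = FALSE]
  dup <- duplicated(out[, c("tf", "start")])
  out <- out[!dup, , drop = FALSE]
  out <- out[order(out$start, out$tf, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_sites <- function() {
  data.frame(tf = character(), start = integer(), end = integer(),
             strand = character(), site_seq = character(), q = numeric(),
             llr = numeric(), stringsAsFactors = FALSE)
}

# scan one strand; codes/seq are in the scanned orientation, coordinates are
# mapped back to the forward strand.
scan_one <- function(am, codes, seq, n, strand) {
  L <- nrow(am$freq)
  if (n < L) return(NULL)
  n_win <- n - L + 1L
  pos <- seq_len(L)
  log_ratio <- log(am$freq) - log(am$freq[cbind(pos, am$consensus)])
  log_bg <- log(am$freq) - rep(log(am$background), each = L)
  score <- numeric(n_win)
  llr <- numeric(n_win)
  for (o in pos) {
    b <- codes[o:(o + n_win - 1L)]
    v <- log_ratio[o, ][b]     # NA for N bases propagates
    score <- score + v
    llr <- llr + log_bg[o, ][b]
  }
  keep <- which(!is.na(score))
  if (!length(keep)) return(NULL)
  start_scan <- keep - 1L               # 0-based in scanned orientation
  if (strand == "+") {
    start <- start_scan
  } else {
    start <- n - start_scan - L
  }
  site_seq <- substring(seq, keep, keep + L - 1L)
  data.frame(tf = am$tf_name, start = start, end = start + L,
             strand = strand, site_seq = site_seq,
             q = pmin(exp(score[keep]), 1), llr = llr[keep],
             stringsAsFactors = FALSE)
}
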