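#' Design a site-killing mutation
#'
#' Replaces every nucleotide of a binding site with the base having the
#' lowest pseudocounted frequency in the cognate alignment matrix (ties
#' broken alphabetically; the wildtype base itself is never chosen, so each
#' position carries a real substitution).  The mutated sequence is then
#' re-scanned with all supplied matrices to verify that (i) the target site
#' drops below `q_min` for its own matrix, and (ii) no site absent from the
#' wildtype scan has been created for any matrix.  Where the all-lowest
#' choice violates these checks, second-lowest bases are substituted at the
#' implicated positions only, searching combinations with the fewest
#' fallbacks first.  Sites not overlapping the target are untouched because
#' every edit lies inside the target.
#'
#' @param crm a [crm_record()].
#' @param target one row of the [scan_sites()] table for `crm` (the site to
#'   abolish).
#' @param matrices list of [alignment_matrix()] objects; must contain the
#'   target's matrix.
#' @param q_min site-calling threshold used for the verification re-scan.
#' @return a `mutation_plan` with `edits` (data.frame of 0-based
#'   `position`, `old_base`, `new_base`) and `fallback_positions`.
#' @export
design_site_mutation <- function(crm, target, matrices, q_min = 0.01) {
  stopifnot(inherits(crm, "crm_record"))
  target <- as.list(target[1, , drop = FALSE])
  am <- find_matrix(matrices, target$tf)
  L <- nrow(am$freq)
  if (target$end - target$start != L)
    stop("target span does not match the matrix length")
  wt_keys <- site_keys(scan_sites(crm, matrices, q_min))

  # per strand-space position: ranked bases by ascending frequency,
  # excluding the wildtype base so old_base != new_base always holds
  wt_site <- strand_window(crm$sequence, target$start, L, target$strand)
  wt_codes <- encode_dna(wt_site)
  choices <- lapply(seq_len(L), function(i) {
    ord <- order(am$freq[i, ])        # stable: alphabetical tie-break
    setdiff(ord, wt_codes[i])[1:2]
  })

  primary <- vapply(choices, `[`, integer(1), 1L)
  attempt <- function(use_second) {
    codes <- ifelse(use_second, vapply(choices, `[`, integer(1), 2L), primary)
    mutant_seq <- paste(DNA_BASES[codes], collapse = "")
    edits <- site_edits(crm, target, mutant_seq)
    mut <- apply_edits(crm, edits)
    new_sites <- scan_sites(mut, matrices, q_min)
    created <- new_sites[!(site_keys(new_sites) %in% wt_keys), , drop = FALSE]
    tq <- site_q(am, strand_window(mut$sequence, target$start, L,
                                   target$strand))
    list(ok = tq < q_min && nrow(created) == 0L, edits = edits,
         created = created, target_q = tq)
  }

  first <- attempt(rep(FALSE, L))
  if (first$ok) {
    return(new_mutation_plan(target, first$edits, integer(0)))
  }
  # positions implicated in a violation: inside any created site, or all of
  # them when only the target's own score failed to drop
  impl <- implicated_positions(target, first$created, L)
  if (first$target_q >= q_min) impl <- seq_len(L)
  if (length(impl) > 16L) impl <- impl[seq_len(16L)]  # combinatorial guard
  combos <- expand_fallbacks(impl, L)
  for (use_second in combos) {
    res <- attempt(use_second)
    if (res$ok) {
      fb_rel <- which(use_second)
      fb_abs <- strand_positions(target, fb_rel, L)
      return(new_mutation_plan(target, res$edits, sort(fb_abs)))
    }
  }
  stop("no combination of lowest/second-lowest substitutions satisfies the ",
       "design checks for site ", target$tf, " [", target$start, ", ",
       target$end, "); violating sites after the all-lowest attempt: ",
       paste(site_keys(first$created), collapse = ", "))
}

new_mutation_plan <- function(target, edits, fallback_positions) {
  structure(list(target_site = target, edits = edits,
                 fallback_positions = fallback_positions),
            class = "mutation_plan")
}

#' @export
print.mutation_plan <- function(x, ...) {
  cat("<mutation_plan>", x$target_site$tf,
      sprintf("[%d, %d) %s:", x$target_site$start, x$target_site$end,
              x$target_site$strand),
      nrow(x$edits), "edits,", length(x$fallback_positions),
      "fallback position(s)\n")
  invisible(x)
}

#' Apply a mutation plan to a sequence
#'
#' @param crm a [crm_record()].
#' @param plan a mutation plan from [design_site_mutation()].
#' @return a new [crm_record()] with the edits applied; positions outside
#'   the edits are untouched and the length is unchanged.
#' @export
apply_mutation_plan <- function(crm, plan) {
  stopifnot(inherits(plan, "mutation_plan"))
  apply_edits(crm, plan$edits)
}

apply_edits <- function(crm, edits) {
  chars <- strsplit(crm$sequence, "", fixed = TRUE)[[1L]]
  if (nrow(edits)) {
    idx <- edits$position + 1L
    if (any(idx < 1L | idx > length(chars)))
      stop("edit position outside the sequence")
    if (!all(chars[idx] == edits$old_base))
      stop("old_base mismatch: the plan was built on a different sequence")
    chars[idx] <- edits$new_base
  }
  crm_record(crm$id, paste(chars, collapse = ""), crm$role)
}

site_keys <- function(sites) {
  if (nrow(sites) == 0L) return(character(0))
  paste(sites$tf, sites$start, sites$strand, sep = ":")
}

find_matrix <- function(matrices, tf) {
  for (am in matrices) if (am$tf_name == tf) return(am)
  stop("no alignment matrix named ", tf)
}

# window in the site's own strand orientation
strand_window <- function(sequence, start, L, strand) {
  w <- substring(sequence, start + 1L, start + L)
  if (strand == "-") revcomp(w) else w
}

# forward 0-based position of strand-space position i (1..L)
strand_positions <- function(target, i, L) {
  if (target$strand == "+") target$start + i - 1L
  else target$start + L - i
}

# edits mapping a strand-space mutant site back onto the forward strand
site_edits <- function(crm, target, mutant_site) {
  L <- nchar(mutant_site)
  fwd_new <- if (target$strand == "-") revcomp(mutant_site) else mutant_site
  old <- strsplit(substring(crm$sequence, target$start + 1L,
                            target$start + L), "", fixed = TRUE)[[1L]]
  new <- strsplit(fwd_new, "", fixed = TRUE)[[1L]]
  keep <- old != new
  data.frame(position = (target$start + seq_len(L) - 1L)[keep],
             old_base = old[keep], new_base = new[keep],
             stringsAsFactors = FALSE)
}

implicated_positions <- function(target, created, L) {
  if (nrow(created) == 0L) return(integer(0))
  abs_pos <- strand_positions(target, seq_len(L), L)
  hit <- rep(FALSE, L)
  for (r in seq_len(nrow(created))) {
    hit <- hit | (abs_pos >= created$start[r] & abs_pos < created$end[r])
  }
  which(hit)
}

# all TRUE/FALSE vectors over positions `impl`, ordered by number of
# fallbacks used (fewest first), excluding the all-FALSE combination
expand_fallbacks <- function(impl, L) {
  k <- length(impl)
  if (k == 0L) return(list())
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  grid <- grid[order(rowSums(grid)), , drop = FALSE]
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r) {
    v <- rep(FALSE, L)
    v[impl] <- as.logical(grid[r, ])
    v
  })
}
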