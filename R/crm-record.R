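#' A CRM, promoter, or reporter-construct sequence
#'
#' @param id identifier.
#' @param sequence DNA string over A, C, G, T, N.
#' @param role one of `"promoter"`, `"distal_crm"`, `"construct"`.
#' @return a `crm_record`.
#' @export
crm_record <- function(id, sequence,
                       role = c("construct", "promoter", "distal_crm")) {
  role <- match.arg(role)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("sequence must have length >= 1")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence may contain only A, C, G, T, N")
  structure(list(id = as.character(id), sequence = sequence, role = role),
            class = "crm_record")
}

#' @export
print.crm_record <- function(x, ...) {
  cat("<crm_record>", x$id, sprintf("[%s, %d bp]", x$role,
                                    nchar(x$sequence)), "\n")
  invisible(x)
}

#' Read CRM sequences from FASTA
#'
#' Headers of the form `id role=promoter` (or `distal_crm`, `construct`)
#' carry the construct role; headers without a role default to
#' `"construct"`.
#'
#' @param path FASTA file.
#' @return a named list of [crm_record()] objects.
#' @export
read_crm_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    id <- strsplit(header, "\\s+")[[1L]][1L]
    role <- "construct"
    m <- regmatches(header, regexpr("role=\\S+", header))
    if (length(m)) role <- sub("^role=", "", m)
    crm_record(id, as.character(seqs[[i]]), role)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write CRM sequences to FASTA
#'
#' @param records a [crm_record()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_crm_fasta <- function(records, path) {
  if (inherits(records, "crm_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1),
                                         "sequence"))
  names(set) <- vapply(records, function(r)
    paste0(r$id, " role=", r$role), character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
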