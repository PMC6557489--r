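#' Alignment (count) matrix for a transcription factor
#'
#' Stores the per-position base counts of a TF's aligned binding sites, the
#' source of both relative-affinity scores and mutation design choices.
#' Frequencies are computed after adding a pseudocount to every cell;
#' the consensus base at a position is the most frequent one, ties broken
#' alphabetically (A < C < G < T).
#'
#' @param counts numeric matrix, positions x 4 (columns A, C, G, T),
#'   nonnegative counts.
#' @param tf_name name of the factor.
#' @param pseudocount nonnegative value added to every count before
#'   frequencies are formed (default 0.5).
#' @param background background base probabilities (A, C, G, T), summing
#'   to 1; used only for log-likelihood-ratio reporting.
#' @return an `alignment_matrix` object.
#' @export
alignment_matrix <- function(counts, tf_name, pseudocount = 0.5,
                             background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("`counts` must have 4 columns (A, C, G, T)")
  if (nrow(counts) < 4L)
    stop("alignment matrix must have length >= 4, got ", nrow(counts))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be finite and nonnegative")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("`pseudocount` must be a single nonnegative number")
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("`background` must be 4 probabilities summing to 1")
  colnames(counts) <- DNA_BASES
  adj <- counts + pseudocount
  if (any(rowSums(adj) <= 0))
    stop("every position must have a positive column sum after pseudocount")
  freq <- adj / rowSums(adj)
  consensus <- apply(freq, 1L, which.max)  # first max = alphabetical tie-break
  structure(
    list(tf_name = as.character(tf_name), counts = counts,
         pseudocount = pseudocount,
         background = setNames(as.numeric(background), DNA_BASES),
         freq = freq, consensus = consensus),
    class = "alignment_matrix"
  )
}

DNA_BASES <- c("A", "C", "G", "T")

#' @export
print.alignment_matrix <- function(x, ...) {
  cat("<alignment_matrix>", x$tf_name, "- length", nrow(x$counts),
      "- consensus", consensus_seq(x), "\n")
  invisible(x)
}

#' Consensus sequence of an alignment matrix
#' @param am an [alignment_matrix()].
#' @return a character scalar.
#' @export
consensus_seq <- function(am) {
  paste(DNA_BASES[am$consensus], collapse = "")
}

#' Relative affinity of a site sequence
#'
#' The affinity of a site relative to the consensus site,
#' `q = prod_i p_i(base_i) / p_i(consensus_i)` over pseudocounted
#' frequencies; `q = 1` iff the site is the consensus.
#'
#' @param am an [alignment_matrix()].
#' @param site_seq character scalar over ACGT, same length as the matrix.
#' @return relative affinity in (0, 1].
#' @export
site_q <- function(am, site_seq) {
  codes <- encode_dna(site_seq)
  L <- nrow(am$freq)
  if (length(codes) != L)
    stop("site length ", length(codes), " != matrix length ", L)
  if (anyNA(codes)) stop("site sequence must contain only A, C, G, T")
  pos <- seq_len(L)
  prod(am$freq[cbind(pos, codes)] / am$freq[cbind(pos, am$consensus)])
}

# A=1 C=2 G=3 T=4, N (or anything else) = NA
encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  match(chars, DNA_BASES)
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", seq), "",
                     fixed = TRUE)[[1L]]), collapse = "")
}

#' Read a plain-text count matrix
#'
#' Accepts two common dialects: JASPAR-style, with four rows labelled
#' `A [ ... ]` etc. (an optional `>` header line carries the TF name), and
#' TRANSFAC-style, with one row per position in four columns A C G T
#' (numbered rows with a `PO`/`P0` column header, `XX`/`//` terminators and
#' `ID`/`NA` fields recognized).
#'
#' @param path file to read.
#' @param format `"auto"` (default), `"jaspar"` or `"transfac"`.
#' @param tf_name override for the factor name; defaults to the name found
#'   in the file, or the file name.
#' @inheritParams alignment_matrix
#' @return an [alignment_matrix()].
#' @export
read_count_matrix <- function(path, format = c("auto", "jaspar", "transfac"),
                              tf_name = NULL, pseudocount = 0.5,
                              background = rep(0.25, 4)) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (format == "auto") {
    format <- if (any(grepl("^[ACGT]\\b", lines))) "jaspar" else "transfac"
  }
  if (format == "jaspar") {
    name <- sub("^>\\s*", "", grep("^>", lines, value = TRUE)[1L])
    rows <- lapply(DNA_BASES, function(b) {
      ln <- grep(paste0("^", b, "\\b"), lines, value = TRUE)[1L]
      if (is.na(ln)) stop("JASPAR matrix is missing the ", b, " row")
      ln <- gsub("[][]", " ", sub(paste0("^", b, "\\s*"), "", ln))
      as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("JASPAR rows have unequal lengths")
    counts <- do.call(cbind, rows)
  } else {
    name <- NA_character_
    id <- grep("^(ID|NA)\\s+", lines, value = TRUE)
    if (length(id)) name <- sub("^(ID|NA)\\s+", "", id[1L])
    keep <- grepl("^[0-9]+\\s", lines)
    if (!any(keep)) {  # bare L x 4 numeric table
      keep <- grepl("^[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines)
    }
    if (!any(keep)) stop("no matrix rows found in ", path)
    counts <- t(vapply(strsplit(lines[keep], "\\s+"), function(f) {
      v <- suppressWarnings(as.numeric(f))
      v <- v[!is.na(v)]
      if (length(v) == 5L) v <- v[-1L]  # leading position number
      if (length(v) != 4L) stop("malformed TRANSFAC row")
      v
    }, numeric(4)))
  }
  if (is.null(tf_name)) {
    tf_name <- if (!is.na(name) && nzchar(name)) {
      strsplit(name, "\\s+")[[1L]][1L]
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  alignment_matrix(counts, tf_name, pseudocount, background)
}

#' Write a count matrix in JASPAR style
#'
#' @param am an [alignment_matrix()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(am, path) {
  rows <- vapply(seq_len(4L), function(j)
    paste0(DNA_BASES[j], " [ ",
           paste(format(am$counts[, j], trim = TRUE), collapse = " "), " ]"),
    character(1))
  writeLines(c(paste0(">", am$tf_name), rows), path)
  invisible(path)
}
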