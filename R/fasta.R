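#' Read a FASTA file into a named character vector
#'
#' Records are returned as uppercase strings named by the header ID (the
#' header text up to the first whitespace).  The alphabet is validated:
#' DNA sequences may contain only `A, C, G, T, N`; protein sequences the 20
#' standard residues plus `X` (flagged with a warning) and a trailing/internal
#' `*` when `allow_stop = TRUE`.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"DNA"` or `"protein"`.
#' @param allow_stop for protein input, permit `*` characters.
#' @return named character vector of sequences with attribute
#'   `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "protein"),
                       allow_stop = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA parse error: no records in '", path, "'")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("FASTA parse error: duplicate record ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs)))
    stop("FASTA parse error: empty sequence for record ",
         ids[!nzchar(seqs)][1L])
  allowed <- if (alphabet == "DNA") {
    names(.IUPAC_DNA)   # full IUPAC accepted on read; scanning treats N strictly
  } else {
    c(.AA_LETTERS, "X", if (allow_stop) "*")
  }
  bad <- vapply(seqs, function(s) {
    chars <- unique(strsplit(s, "")[[1]])
    any(!chars %in% allowed)
  }, logical(1))
  if (any(bad))
    stop("FASTA parse error: illegal ", alphabet, " character in record ",
         ids[bad][1L])
  if (alphabet == "protein" && any(grepl("X", seqs, fixed = TRUE)))
    warning("protein record(s) contain ambiguous residue X")
  attr(seqs, "alphabet") <- alphabet
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width in characters.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
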