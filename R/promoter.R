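# Catalogue-driven cis-acting element scanning and SSR detection.

.IUPAC_LETTERS <- names(.IUPAC_DNA)

#' Load a cis-element catalogue
#'
#' The catalogue replaces a motif web service: a TSV with columns `name`
#' (unique), `pattern` (IUPAC DNA string) and `category` (function label,
#' e.g. "gibberellin-responsive element").
#'
#' @param path catalogue TSV with a header row.
#' @return data.frame with `name`, `pattern`, `category`.
#' @export
load_catalogue <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "pattern", "category")
  if (!all(req %in% names(tab)))
    stop("catalogue must have columns: ", paste(req, collapse = ", "))
  tab <- tab[, req]
  tab$pattern <- toupper(tab$pattern)
  validate_catalogue(tab)
  tab
}

#' Validate a cis-element catalogue
#'
#' @param catalogue data.frame with `name`, `pattern`, `category`.
#' @return the catalogue, invisibly; errors on illegal IUPAC codes,
#'   empty patterns or duplicate names.
#' @export
validate_catalogue <- function(catalogue) {
  if (anyDuplicated(catalogue$name))
    stop("duplicate motif name(s): ",
         paste(unique(catalogue$name[duplicated(catalogue$name)]),
               collapse = ", "))
  if (any(!nzchar(catalogue$pattern))) stop("empty motif pattern")
  for (i in seq_len(nrow(catalogue))) {
    chars <- strsplit(catalogue$pattern[i], "")[[1]]
    bad <- setdiff(chars, .IUPAC_LETTERS)
    if (length(bad) > 0L)
      stop("illegal IUPAC code '", bad[1L], "' in pattern of motif '",
           catalogue$name[i], "'")
  }
  invisible(catalogue)
}

# All start positions (1-based) where an IUPAC pattern matches a plain DNA
# subject.  N in the subject matches only pattern letter N.
.iupac_match <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject),
                                fixed = "subject")
  Biostrings::start(m)
}

#' Scan promoters for catalogue motifs
#'
#' Every occurrence of every pattern is reported, overlaps included.  A
#' minus-strand hit means the reverse complement of the promoter window
#' matches the pattern; it is reported with plus-strand coordinates and the
#' plus-strand substring.  `N` bases in a promoter match no IUPAC code
#' except `N` itself.
#'
#' @param promoters named character vector of promoter sequences, or the
#'   data.frame from [extract_promoters()].
#' @param catalogue motif catalogue (see [load_catalogue()]).
#' @param strands strands to scan, subset of `c("+", "-")`.
#' @param dedupe collapse identical `(seq_id, motif, start, strand)` rows.
#' @return data.frame with `seq_id`, `motif`, `category`, `start`
#'   (0-based), `end` (half-open), `strand`, `match` (plus-strand
#'   substring).
#' @export
scan_motifs <- function(promoters, catalogue, strands = c("+", "-"),
                        dedupe = FALSE) {
  if (is.data.frame(promoters))
    promoters <- setNames(promoters$seq, promoters$gene_id)
  validate_catalogue(catalogue)
  stopifnot(all(strands %in% c("+", "-")))
  out <- list()
  for (sid in names(promoters)) {
    subject <- promoters[[sid]]
    if (!nzchar(subject)) next
    for (i in seq_len(nrow(catalogue))) {
      pat <- catalogue$pattern[i]
      w <- nchar(pat)
      for (strand in strands) {
        eff_pat <- if (strand == "+") pat else revcomp(pat)
        starts1 <- .iupac_match(eff_pat, subject)
        if (length(starts1) == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          seq_id = sid, motif = catalogue$name[i],
          category = catalogue$category[i],
          start = starts1 - 1L, end = starts1 - 1L + w, strand = strand,
          match = substring(subject, starts1, starts1 + w - 1L),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  hits <- if (length(out) == 0L) {
    data.frame(seq_id = character(0), motif = character(0),
               category = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               match = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, out)
  if (dedupe)
    hits <- hits[!duplicated(hits[, c("seq_id", "motif", "start",
                                      "strand")]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Per-gene per-category cis-element counts
#'
#' @param hits data.frame from [scan_motifs()].
#' @param catalogue the catalogue used for scanning.
#' @param seq_ids optional full set of sequence IDs so genes without hits
#'   appear as all-zero rows.
#' @return contingency matrix gene x category; `sum()` equals the number
#'   of hits.
#' @export
categorize_hits <- function(hits, catalogue, seq_ids = NULL) {
  cats <- unique(catalogue$category)
  ids <- if (is.null(seq_ids)) unique(hits$seq_id) else seq_ids
  tab <- matrix(0L, nrow = length(ids), ncol = length(cats),
                dimnames = list(ids, cats))
  if (nrow(hits) > 0L) {
    cnt <- table(factor(hits$seq_id, levels = ids),
                 factor(hits$category, levels = cats))
    tab[] <- as.integer(cnt)
  }
  tab
}

.canonical_rotation <- function(unit) {
  n <- nchar(unit)
  if (n == 1L) return(unit)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(unit, i, n), substr(unit, 1, i - 1L)), character(1))
  min(rots)
}

.min_period <- function(unit) {
  n <- nchar(unit)
  for (p in seq_len(n - 1L)) {
    if (n %% p != 0L) next
    if (strrep(substr(unit, 1, p), n / p) == unit) return(p)
  }
  n
}

#' Find simple sequence repeats (microsatellites)
#'
#' Maximal perfect tandem repeats with unit length 1-6 bp meeting a
#' unit-length-specific minimum repeat count.  Units are reported in their
#' observed phase with the canonical form (lexicographically least
#' rotation) alongside; a unit that is itself a repeat of a shorter unit is
#' only reported at the shorter unit.  Scanning is left-to-right greedy and
#' non-overlapping within one unit-length class.
#'
#' @param seqs named character vector of DNA sequences.
#' @param min_repeats named integer vector: minimum repeat count per unit
#'   length `"1"`..`"6"`.
#' @return data.frame with `seq_id`, `unit` (observed phase), `canonical`,
#'   `n_repeats`, `start` (0-based), `end` (half-open).
#' @export
find_ssrs <- function(seqs,
                      min_repeats = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                      `4` = 5L, `5` = 5L, `6` = 5L)) {
  stopifnot(!is.null(names(seqs)))
  out <- list()
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    L <- nchar(s)
    chars <- strsplit(s, "")[[1]]
    for (ul in as.integer(names(min_repeats))) {
      need <- min_repeats[[as.character(ul)]]
      i <- 1L
      while (i + ul * need - 1L <= L) {
        unit <- substr(s, i, i + ul - 1L)
        if (grepl("[^ACGT]", unit) || .min_period(unit) < ul) {
          i <- i + 1L
          next
        }
        # count consecutive repeats of unit starting at i
        r <- 1L
        while (i + (r + 1L) * ul - 1L <= L &&
               substr(s, i + r * ul, i + (r + 1L) * ul - 1L) == unit)
          r <- r + 1L
        if (r >= need) {
          out[[length(out) + 1L]] <- data.frame(
            seq_id = sid, unit = unit,
            canonical = .canonical_rotation(unit), n_repeats = r,
            start = i - 1L, end = i - 1L + r * ul,
            stringsAsFactors = FALSE
          )
          i <- i + r * ul
        } else {
          i <- i + 1L
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(0), unit = character(0),
                      canonical = character(0), n_repeats = integer(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$seq_id, res$start, nchar(res$unit)), , drop = FALSE]
}
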