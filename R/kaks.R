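# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Conventions (the dominant NG86 ones):
#   * site counting: at each codon position the fraction of synonymous
#     single-base changes is taken over the changes that do NOT create a
#     stop codon (stop mutations are excluded from the denominator), so
#     every compared codon contributes exactly 3 sites and S + N = 3 x
#     codons;
#   * difference counting: all minimal substitution pathways between two
#     codons are enumerated; pathways passing through a stop codon are
#     excluded and the remaining pathways weighted equally (if every
#     pathway is blocked, all pathways are used);
#   * aligned codons containing a gap, and codon columns where either
#     sequence has a stop, are dropped before counting.

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.codon_aa <- function(codon) {
  tab <- .famscan_cache$codon_aa
  if (is.null(tab)) {
    tab <- .codon_table()
    .famscan_cache$codon_aa <- tab
  }
  tab[codon]
}

# Fraction of synonymous sites per codon (sums the per-position synonymous
# fractions); memoized over the 61 sense codons.
.syn_sites <- function(codon) {
  tab <- .famscan_cache$syn_sites
  if (!is.null(tab) && !is.na(tab[codon])) return(unname(tab[codon]))
  bases <- strsplit(codon, "")[[1]]
  aa0 <- .codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; denom <- 0L
    for (b in setdiff(.DNA_BASES, bases[pos])) {
      mut <- bases
      mut[pos] <- b
      mcodon <- paste(mut, collapse = "")
      if (mcodon %in% .STOP_CODONS) next
      denom <- denom + 1L
      if (.codon_aa(mcodon) == aa0) syn <- syn + 1L
    }
    if (denom > 0L) s <- s + syn / denom
  }
  if (is.null(tab)) tab <- setNames(rep(NA_real_, 64L),
                                    names(.codon_table()))
  tab[codon] <- s
  .famscan_cache$syn_sites <- tab
  s
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# Synonymous / nonsynonymous difference counts between two sense codons,
# averaged over minimal substitution pathways; memoized per codon pair.
.codon_diffs <- function(c1, c2) {
  key <- paste(c1, c2, sep = "|")
  cache <- .famscan_cache$codon_diffs
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .famscan_cache$codon_diffs <- cache
  }
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(b1 != b2)
  k <- length(diff_pos)
  if (k == 0L) {
    res <- c(sd = 0, nd = 0)
  } else {
    paths <- lapply(.permutations(k), function(p) diff_pos[p])
    tally <- function(order_, allow_stop) {
      cur <- b1
      sd <- 0; nd <- 0
      for (pos in order_) {
        nxt <- cur
        nxt[pos] <- b2[pos]
        ncodon <- paste(nxt, collapse = "")
        if (!allow_stop && ncodon %in% .STOP_CODONS &&
            !identical(nxt, b2)) return(NULL)
        if (.codon_aa(paste(cur, collapse = "")) == .codon_aa(ncodon))
          sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    counted <- Filter(Negate(is.null), lapply(paths, tally,
                                              allow_stop = FALSE))
    if (length(counted) == 0L)
      counted <- lapply(paths, tally, allow_stop = TRUE)
    mat <- do.call(rbind, counted)
    res <- c(sd = mean(mat[, 1]), nd = mean(mat[, 2]))
  }
  cache[[key]] <- res
  res
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) log(1 - 4 p / 3)`.  Proportions of 0.75 or more are
#' saturated and return `NA`.
#'
#' @param p proportion of differing sites (`0 <= p`).
#' @return corrected distance, or `NA_real_` when saturated.
#' @export
jc_correct <- function(p) {
  if (any(p < 0)) stop("jc_correct: negative proportion")
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' NG86 Ka/Ks on a codon alignment
#'
#' Nei-Gojobori (1986) counting: synonymous (`S`) and nonsynonymous (`N`)
#' site counts averaged over the two sequences, synonymous (`Sd`) and
#' nonsynonymous (`Nd`) differences averaged over equally weighted minimal
#' substitution pathways, Jukes-Cantor corrected into `ka` and `ks`, and
#' their ratio `omega` (`NA` when `ks` is zero or saturated).
#'
#' @param aln_a,aln_b gap-padded CDS strings of equal length (gaps in
#'   whole-codon units); ungapped input of equal length is also accepted.
#' @return one-row data.frame with `n_codons`, `S`, `N`, `Sd`, `Nd`, `ps`,
#'   `pn`, `ka`, `ks`, `omega`, `saturated_ks`, `saturated_ka`.
#' @export
ng86 <- function(aln_a, aln_b) {
  if (nchar(aln_a) != nchar(aln_b))
    stop("ng86: aligned sequences differ in length")
  if (nchar(aln_a) %% 3L != 0L)
    stop("ng86: alignment length not divisible by 3")
  n <- nchar(aln_a) / 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  ca <- substring(aln_a, starts, starts + 2L)
  cb <- substring(aln_b, starts, starts + 2L)
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE) &
    !(ca %in% .STOP_CODONS) & !(cb %in% .STOP_CODONS)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0L) stop("ng86: no comparable codons")
  if (any(!grepl("^[ACGT]{3}$", c(ca, cb))))
    stop("ng86: non-ACGT codon in alignment")
  S <- (sum(vapply(ca, .syn_sites, numeric(1))) +
        sum(vapply(cb, .syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) .codon_diffs(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  omega <- if (is.na(ks) || is.na(ka) || ks == 0) NA_real_ else ka / ks
  data.frame(n_codons = length(ca), S = S, N = N, Sd = Sd, Nd = Nd,
             ps = ps, pn = pn, ka = ka, ks = ks, omega = omega,
             saturated_ks = is.na(ks) && ps >= 0.75,
             saturated_ka = is.na(ka) && pn >= 0.75)
}

#' Global protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Thin wrapper around [Biostrings::pairwiseAlignment()] with BLOSUM62 and
#' affine gap costs: a gap of length `L` costs `gap_open + L * gap_extend`.
#'
#' @param a,b protein sequences.
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap parameters (positive costs).
#' @return list with gapped strings `a`, `b` and the optimal `score`.
#' @export
align_proteins <- function(a, b, matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  stopifnot(nzchar(a), nzchar(b))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

#' Back-translate a protein alignment onto the CDS pair
#'
#' Each aligned residue becomes its source codon and each protein gap a
#' `"---"` codon gap, yielding a codon alignment whose ungapped sides
#' recover the input CDS exactly.
#'
#' @param protein_aln list with gapped protein strings `a` and `b` (as from
#'   [align_proteins()]).
#' @param cds_a,cds_b the CDS whose translations were aligned (trailing
#'   stop codons allowed and ignored).
#' @return list of gap-padded CDS strings `a`, `b`.
#' @export
backtranslate_alignment <- function(protein_aln, cds_a, cds_b) {
  pad_one <- function(gapped, cds, label) {
    cds_nostop <- sub("(TAA|TAG|TGA)$", "", cds)
    codons <- substring(cds_nostop, seq(1, nchar(cds_nostop), 3),
                        seq(3, nchar(cds_nostop), 3))
    res <- strsplit(gapped, "")[[1]]
    out <- character(length(res))
    j <- 0L
    for (i in seq_along(res)) {
      if (res[i] == "-") {
        out[i] <- "---"
      } else {
        j <- j + 1L
        if (j > length(codons))
          stop("backtranslate: protein ", label, " longer than its CDS")
        aa <- .codon_aa(codons[j])
        if (aa != res[i])
          stop("backtranslate: residue ", i, " ('", res[i], "') of ", label,
               " does not match codon ", j, " ('", codons[j], "' -> ", aa, ")")
        out[i] <- codons[j]
      }
    }
    if (j != length(codons))
      stop("backtranslate: CDS of ", label, " longer than aligned protein")
    paste(out, collapse = "")
  }
  list(a = pad_one(protein_aln$a, cds_a, "a"),
       b = pad_one(protein_aln$b, cds_b, "b"))
}

#' Ka/Ks for one gene pair
#'
#' Extracts both CDS, aligns the proteins, back-translates to a codon
#' alignment and applies [ng86()].  Symmetric in its arguments.
#'
#' @param gene_a,gene_b gene IDs.
#' @param models gene-model data.frame.
#' @param genome named character vector of chromosome sequences.
#' @param cache optional environment memoizing results per unordered pair.
#' @return one-row data.frame: `gene_a`, `gene_b` plus the [ng86()] columns.
#' @export
pair_kaks <- function(gene_a, gene_b, models, genome, cache = NULL) {
  key <- paste(sort(c(gene_a, gene_b)), collapse = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) {
    res <- cache[[key]]
  } else {
    xa <- extract_cds_and_protein(models, gene_a, genome)
    xb <- extract_cds_and_protein(models, gene_b, genome)
    paln <- align_proteins(unname(xa$protein), unname(xb$protein))
    caln <- backtranslate_alignment(paln, unname(xa$cds), unname(xb$cds))
    res <- ng86(caln$a, caln$b)
    if (!is.null(cache)) cache[[key]] <- res
  }
  cbind(data.frame(gene_a = gene_a, gene_b = gene_b,
                   stringsAsFactors = FALSE), res)
}

#' Ka/Ks over a table of gene pairs
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @inheritParams pair_kaks
#' @return data.frame with one [pair_kaks()] row per input pair.
#' @export
kaks_table <- function(pairs, models, genome) {
  cache <- new.env(parent = emptyenv())
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    pair_kaks(pairs$gene_a[i], pairs$gene_b[i], models, genome, cache)
  }))
}
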