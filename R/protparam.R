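# Protein physicochemical properties in the ExPASy ProtParam style:
# average-mass molecular weight, Bjellqvist theoretical pI, Kyte-Doolittle
# GRAVY, Guruprasad instability index, and the aliphatic index.

.check_protein <- function(seq, what, skip_ambiguous = FALSE) {
  if (!nzchar(seq)) stop(what, ": empty protein sequence")
  chars <- strsplit(seq, "")[[1]]
  amb <- !chars %in% .AA_LETTERS
  if (any(amb)) {
    if (!skip_ambiguous)
      stop(what, ": ambiguous/non-standard residue(s) ",
           paste(unique(chars[amb]), collapse = ", "),
           " (use skip_ambiguous = TRUE to drop them)")
    warning(what, ": dropping ", sum(amb), " ambiguous residue(s)")
    chars <- chars[!amb]
    if (length(chars) == 0L) stop(what, ": no standard residues left")
  }
  chars
}

#' Molecular weight of a protein (average masses)
#'
#' Sum of average residue masses plus one water (18.0153 Da), the ExPASy
#' convention.
#'
#' @param seq protein sequence (single string).
#' @param skip_ambiguous drop non-standard residues with a warning instead
#'   of erroring.
#' @return mass in Dalton.
#' @export
molecular_weight <- function(seq, skip_ambiguous = FALSE) {
  chars <- .check_protein(seq, "molecular_weight", skip_ambiguous)
  sum(.AA_MASS[chars]) + .WATER_MASS
}

# Net charge of a protein at a given pH (Henderson-Hasselbalch sum over
# the N-terminus, C-terminus and titratable side chains).
.net_charge <- function(counts, nterm_res, pH) {
  pos_pka <- c(.PKA_SIDE_POS,
               nterm = unname(.PKA_NTERM[nterm_res] %||% .PKA_NTERM_DEFAULT))
  neg_pka <- c(.PKA_SIDE_NEG, cterm = .PKA_CTERM)
  pos_n <- c(counts[names(.PKA_SIDE_POS)], nterm = 1)
  neg_n <- c(counts[names(.PKA_SIDE_NEG)], cterm = 1)
  sum(pos_n / (1 + 10^(pH - pos_pka))) -
    sum(neg_n / (1 + 10^(neg_pka - pH)))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Theoretical isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge over the termini
#' and the D, E, C, Y, H, K, R side chains is zero, using the Bjellqvist
#' pKa set and solved by bisection on `[0, 14]`.
#'
#' @inheritParams molecular_weight
#' @param tol bisection tolerance in pH units.
#' @return pI in pH units (report to 2 decimals).
#' @export
isoelectric_point <- function(seq, tol = 0.001, skip_ambiguous = FALSE) {
  chars <- .check_protein(seq, "isoelectric_point", skip_ambiguous)
  counts <- table(factor(chars, levels = .AA_LETTERS))
  counts <- setNames(as.numeric(counts), .AA_LETTERS)
  nterm <- chars[1L]
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.net_charge(counts, nterm, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values; positive values
#' indicate hydrophobic proteins.
#'
#' @inheritParams molecular_weight
#' @return dimensionless GRAVY score.
#' @export
gravy <- function(seq, skip_ambiguous = FALSE) {
  chars <- .check_protein(seq, "gravy", skip_ambiguous)
  mean(.KD_HYDROPATHY[chars])
}

#' Guruprasad instability index
#'
#' `II = (10 / L) * sum` of the dipeptide instability weight values over the
#' `L - 1` overlapping dipeptides.  Proteins with `II < 40` are predicted
#' stable.
#'
#' @inheritParams molecular_weight
#' @return dimensionless instability index.
#' @export
instability_index <- function(seq, skip_ambiguous = FALSE) {
  chars <- .check_protein(seq, "instability_index", skip_ambiguous)
  L <- length(chars)
  if (L < 2L) stop("instability_index: need at least 2 residues")
  (10 / L) * sum(.DIWV[cbind(chars[-L], chars[-1L])])
}

#' Aliphatic index
#'
#' `AI = X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` with `X` the mole percent
#' of the residue: the relative volume occupied by aliphatic side chains.
#'
#' @inheritParams molecular_weight
#' @return dimensionless aliphatic index.
#' @export
aliphatic_index <- function(seq, skip_ambiguous = FALSE) {
  chars <- .check_protein(seq, "aliphatic_index", skip_ambiguous)
  x <- 100 * c(A = mean(chars == "A"), V = mean(chars == "V"),
               I = mean(chars == "I"), L = mean(chars == "L"))
  unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"]))
}

#' Physicochemical property table for a set of proteins
#'
#' One row per protein, mirroring the shape of a family property
#' supplementary table: length, molecular weight (kDa), pI, GRAVY,
#' instability index with stability call, aliphatic index.
#'
#' @param proteins named character vector of protein sequences.
#' @param skip_ambiguous drop non-standard residues with a warning.
#' @return data.frame with columns `id`, `length`, `mw_kda`, `pi`, `gravy`,
#'   `instability_index`, `stable`, `aliphatic_index`.
#' @export
protein_properties <- function(proteins, skip_ambiguous = FALSE) {
  stopifnot(!is.null(names(proteins)))
  rows <- lapply(names(proteins), function(id) {
    s <- proteins[[id]]
    ii <- instability_index(s, skip_ambiguous)
    data.frame(
      id = id, length = nchar(s),
      mw_kda = molecular_weight(s, skip_ambiguous) / 1000,
      pi = round(isoelectric_point(s, skip_ambiguous = skip_ambiguous), 2),
      gravy = gravy(s, skip_ambiguous),
      instability_index = ii, stable = ii < 40,
      aliphatic_index = aliphatic_index(s, skip_ambiguous),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
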