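# Expression summarization: TPM, log2(TPM+1), per-gene row scaling for
# heatmaps, and Livak 2^-ddCT fold changes for qPCR.

#' Transcripts per million
#'
#' `rate_g = count_g / length_g`; `tpm_g = rate_g / sum(rates) * 1e6` per
#' sample, so every column sums to one million.
#'
#' @param counts genes x samples numeric matrix (or data.frame) of
#'   non-negative read counts; rownames are gene IDs.
#' @param lengths named numeric vector of transcript lengths in bp, one
#'   per gene (`> 0`).
#' @return TPM matrix of the same shape, with attribute `mode = "tpm"`.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  lens <- lengths[rownames(counts)]
  if (any(is.na(lens))) stop("missing transcript length for gene(s): ",
                             paste(rownames(counts)[is.na(lens)][1L]))
  if (any(lens <= 0)) stop("non-positive transcript length")
  rates <- counts / lens
  totals <- colSums(rates)
  if (any(totals == 0)) stop("all-zero sample column(s): ",
                             paste(colnames(counts)[totals == 0],
                                   collapse = ", "))
  out <- sweep(rates, 2, totals, "/") * 1e6
  attr(out, "mode") <- "tpm"
  out
}

#' log2(x + 1) transform of a TPM matrix
#'
#' @param tpm_matrix matrix of non-negative values.
#' @return transformed matrix, attribute `mode = "log_tpm"`.
#' @export
log_transform <- function(tpm_matrix) {
  if (any(tpm_matrix < 0)) stop("negative expression values")
  out <- log2(tpm_matrix + 1)
  attr(out, "mode") <- "log_tpm"
  out
}

#' Per-gene row scaling ("Normalized"/scale heatmap convention)
#'
#' Each row is centred by its mean and divided by its sample standard
#' deviation (n-1 denominator).  Constant rows become all-zero and are
#' flagged in the `constant_rows` attribute.
#'
#' @param mat genes x samples matrix with at least 2 columns.
#' @return scaled matrix, attributes `mode = "scaled"` and
#'   `constant_rows` (character vector of flagged gene IDs).
#' @export
row_scale <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("row scaling needs at least 2 samples")
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  constant <- s == 0 | is.na(s)
  s[constant] <- 1
  out <- (mat - mu) / s
  out[constant, ] <- 0
  attr(out, "mode") <- "scaled"
  attr(out, "constant_rows") <- rownames(mat)[constant]
  out
}

#' 2^-ddCT relative expression (Livak method)
#'
#' Per replicate `dCT = ct_target - ct_reference`; replicate dCTs are
#' averaged per condition; `ddCT = dCT_condition - dCT_calibrator` and the
#' fold change is `2^-ddCT`, so the calibrator condition has fold change 1
#' for every gene.
#'
#' @param records data.frame with columns `gene`, `condition`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @param calibrator_condition the calibrator (reference) condition.
#' @return list with `fold` (data.frame `gene`, `condition`, `dct`,
#'   `ddct`, `fold_change`) and `per_replicate` (replicate-level fold
#'   changes, for error bars).
#' @export
ddct_fold_change <- function(records, calibrator_condition) {
  req <- c("gene", "condition", "replicate", "ct_target", "ct_reference")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  if (any(!is.finite(records$ct_target)) ||
      any(!is.finite(records$ct_reference)))
    stop("non-finite CT value")
  records$dct <- records$ct_target - records$ct_reference
  agg <- aggregate(dct ~ gene + condition, data = records, FUN = mean)
  calib <- agg[agg$condition == calibrator_condition, , drop = FALSE]
  if (nrow(calib) == 0L)
    stop("calibrator condition '", calibrator_condition, "' absent")
  missing <- setdiff(unique(agg$gene), calib$gene)
  if (length(missing) > 0L)
    stop("calibrator condition missing for gene(s): ",
         paste(missing, collapse = ", "))
  calib_dct <- setNames(calib$dct, calib$gene)
  agg$ddct <- agg$dct - calib_dct[agg$gene]
  agg$fold_change <- 2^(-agg$ddct)
  per_rep <- records
  per_rep$ddct <- per_rep$dct - calib_dct[per_rep$gene]
  per_rep$fold_change <- 2^(-per_rep$ddct)
  list(fold = agg[order(agg$gene, agg$condition), ],
       per_replicate = per_rep)
}

#' Order matrix rows by the leaf order of a Newick tree
#'
#' The tree is parsed for ordering only (e.g. to lay out a heatmap matrix
#' in phylogeny order); tips absent from the matrix are ignored and genes
#' absent from the tree keep their position at the end.
#'
#' @param mat matrix with gene rownames.
#' @param newick_path path to a Newick file.
#' @return the reordered matrix.
#' @export
order_by_tree <- function(mat, newick_path) {
  txt <- paste(readLines(newick_path, warn = FALSE), collapse = "")
  # tip labels in newick appearance order
  tips <- regmatches(txt, gregexpr("[(,]\\s*([^(),:;]+)", txt))[[1]]
  tips <- trimws(sub("^[(,]\\s*", "", tips))
  tips <- tips[nzchar(tips)]
  ord <- c(intersect(tips, rownames(mat)), setdiff(rownames(mat), tips))
  mat[ord, , drop = FALSE]
}
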