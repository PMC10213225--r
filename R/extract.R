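# CDS / protein / promoter extraction from gene models.

.model_row <- function(models, gene_id) {
  i <- match(gene_id, models$gene_id)
  if (is.na(i)) stop("gene '", gene_id, "' not found in models")
  models[i, , drop = FALSE]
}

#' Extract the spliced CDS and translated protein of one gene
#'
#' Exon intervals are spliced in genomic order; minus-strand genes are
#' reverse-complemented after splicing so the CDS reads 5'->3' in the coding
#' direction.  Translation uses the standard genetic code; a trailing stop
#' codon is stripped from the protein.
#'
#' @param models gene-model data.frame.
#' @param gene_id the gene to extract.
#' @param genome named character vector of chromosome sequences.
#' @return list with elements `cds` and `protein`, each a named
#'   length-1 character vector.
#' @export
extract_cds_and_protein <- function(models, gene_id, genome) {
  m <- .model_row(models, gene_id)
  cds_mat <- m$cds[[1L]]
  if (nrow(cds_mat) == 0L) stop("gene '", gene_id, "' has no CDS")
  chrom_seq <- genome[[m$chrom]]
  if (is.null(chrom_seq)) stop("chromosome '", m$chrom, "' not in genome")
  pieces <- substring(chrom_seq, cds_mat[, 1L] + 1L, cds_mat[, 2L])
  cds <- paste(pieces, collapse = "")
  if (m$strand == "-") cds <- revcomp(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length of gene '", gene_id, "' not divisible by 3")
  protein <- translate_cds(cds, gene_id)
  list(cds = setNames(cds, gene_id), protein = setNames(protein, gene_id))
}

#' Translate a CDS with the standard genetic code
#'
#' @param cds in-frame CDS string (length divisible by 3).
#' @param id label used in error messages.
#' @return protein string with any trailing stop codon stripped; an
#'   internal stop codon is an error.
#' @export
translate_cds <- function(cds, id = "CDS") {
  if (nchar(cds) %% 3L != 0L)
    stop("length of ", id, " not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  aa <- sub("\\*$", "", aa)
  if (grepl("*", aa, fixed = TRUE))
    stop("internal stop codon in ", id)
  if (!nzchar(aa)) stop(id, " encodes no residues")
  aa
}

#' Extract all CDS and proteins of a gene set
#'
#' @param models gene-model data.frame.
#' @param genome named character vector of chromosome sequences.
#' @param gene_ids genes to extract (default: all with CDS).
#' @return list with named character vectors `cds` and `protein`.
#' @export
extract_all_cds <- function(models, genome, gene_ids = NULL) {
  if (is.null(gene_ids)) {
    has_cds <- vapply(models$cds, nrow, integer(1)) > 0L
    gene_ids <- models$gene_id[has_cds]
  }
  res <- lapply(gene_ids, extract_cds_and_protein,
                models = models, genome = genome)
  list(cds = unlist(lapply(res, `[[`, "cds")),
       protein = unlist(lapply(res, `[[`, "protein")))
}

#' Extract the promoter (upstream sequence) of one gene
#'
#' For a plus-strand gene the `length` bases ending immediately before the
#' gene start; for a minus-strand gene the reverse complement of the
#' `length` bases beginning immediately after the gene end.  The promoter
#' is truncated (never padded) at sequence boundaries and emitted 5'->3'
#' relative to the gene.
#'
#' @param models gene-model data.frame.
#' @param gene_id the gene.
#' @param genome named character vector of chromosome sequences.
#' @param length promoter length in bp (default 2000).
#' @return list with `gene_id`, `seq` (possibly empty string), `length`,
#'   and logical `truncated`.
#' @export
extract_promoter <- function(models, gene_id, genome, length = 2000L) {
  m <- .model_row(models, gene_id)
  chrom_seq <- genome[[m$chrom]]
  if (is.null(chrom_seq)) stop("chromosome '", m$chrom, "' not in genome")
  L <- nchar(chrom_seq)
  if (m$strand == "-") {
    from <- m$end                     # 0-based
    to <- min(m$end + length, L)      # exclusive
    s <- if (to > from) revcomp(substr(chrom_seq, from + 1L, to)) else ""
  } else {
    from <- max(m$start - length, 0L)
    to <- m$start
    s <- if (to > from) substr(chrom_seq, from + 1L, to) else ""
  }
  list(gene_id = gene_id, seq = s, length = nchar(s),
       truncated = nchar(s) < length)
}

#' Extract promoters for a set of genes
#'
#' @inheritParams extract_promoter
#' @param gene_ids genes to extract (default all).
#' @return data.frame with columns `gene_id`, `seq`, `length`, `truncated`.
#' @export
extract_promoters <- function(models, genome, gene_ids = models$gene_id,
                              length = 2000L) {
  rows <- lapply(gene_ids, extract_promoter, models = models,
                 genome = genome, length = length)
  data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    seq = vapply(rows, `[[`, character(1), "seq"),
    length = vapply(rows, `[[`, integer(1), "length"),
    truncated = vapply(rows, `[[`, logical(1), "truncated"),
    stringsAsFactors = FALSE
  )
}
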