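# Gene models from GFF3 annotation.
#
# Internally all coordinates are 0-based half-open; GFF3 is read (and
# written) 1-based inclusive.  A gene model is one row of a data.frame with
# a list-column `cds` holding a two-column matrix (start, end) of exon CDS
# intervals sorted by genomic position.

#' Read gene models from a GFF3 file
#'
#' One model per `gene` feature.  When a gene carries several mRNAs, the
#' isoform with the longest summed CDS represents the gene.  Coordinates are
#' converted from GFF3 1-based inclusive to 0-based half-open.
#'
#' @param path path to a GFF3 file with gene/mRNA/CDS features.
#' @param genome optional named character vector of chromosome sequences
#'   (from [read_fasta()]); when supplied, every gene's chromosome must be
#'   present and the gene span must fit inside it.
#' @param scaffold_pattern regular expression identifying unanchored
#'   scaffold names; everything else counts as a placed chromosome.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `is_placed`, `rank` (`NA` until
#'   [assign_ranks()]), and list-column `cds`.
#' @export
read_gff3 <- function(path, genome = NULL,
                      scaffold_pattern = "scaffold|contig|ctg|^un") {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in '", path,
                                          "': ", conditionMessage(e)))
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  mrnas <- gr[type %in% c("mRNA", "transcript")]
  cdss  <- gr[type == "CDS"]
  if (length(genes) == 0L) stop("GFF3 contains no gene features: ", path)
  gene_ids <- as.character(genes$ID)
  if (anyDuplicated(gene_ids)) stop("GFF3 duplicate gene ID")

  mrna_ids <- as.character(mrnas$ID)
  mrna_parent <- vapply(as.list(mrnas$Parent), function(p) p[1L], character(1))
  cds_parent <- vapply(as.list(cdss$Parent), function(p) p[1L], character(1))

  models <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    gid <- gene_ids[i]
    g <- genes[i]
    # transcripts of this gene; CDS parented directly to the gene form an
    # extra implicit transcript
    tx <- mrna_ids[mrna_parent == gid]
    tx_cds <- lapply(tx, function(t) cdss[cds_parent == t])
    direct <- cdss[cds_parent == gid]
    if (length(direct) > 0L) tx_cds <- c(tx_cds, list(direct))
    tx_cds <- Filter(function(x) length(x) > 0L, tx_cds)
    if (length(tx_cds) == 0L) {
      cds_mat <- matrix(numeric(0), ncol = 2)
    } else {
      lens <- vapply(tx_cds, function(x) sum(GenomicRanges::width(x)),
                     numeric(1))
      best <- tx_cds[[which.max(lens)]]
      st <- GenomicRanges::start(best) - 1L
      en <- GenomicRanges::end(best)
      o <- order(st)
      st <- st[o]; en <- en[o]
      if (any(st[-1] < en[-length(en)]))
        stop("overlapping CDS intervals for gene ", gid)
      if (min(st) < GenomicRanges::start(g) - 1L ||
          max(en) > GenomicRanges::end(g))
        stop("CDS outside gene span for gene ", gid)
      cds_mat <- cbind(start = st, end = en)
    }
    chrom <- as.character(GenomicRanges::seqnames(g))
    if (!is.null(genome) && !chrom %in% names(genome))
      stop("chromosome '", chrom, "' (gene ", gid,
           ") absent from genome FASTA")
    models[[i]] <- list(
      gene_id = gid, chrom = chrom,
      start = GenomicRanges::start(g) - 1L, end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)), cds = cds_mat
    )
  }
  out <- data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    chrom   = vapply(models, `[[`, character(1), "chrom"),
    start   = vapply(models, `[[`, numeric(1), "start"),
    end     = vapply(models, `[[`, numeric(1), "end"),
    strand  = vapply(models, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) stop("gene with non-positive span")
  out$is_placed <- !grepl(scaffold_pattern, out$chrom, ignore.case = TRUE)
  out$rank <- NA_integer_
  out$cds <- lapply(models, `[[`, "cds")
  assign_ranks(out)
}

#' Assign per-chromosome gene ranks
#'
#' On each chromosome genes sorted by start receive ranks `0..n-1`; ties are
#' broken by end coordinate, then gene ID.  Rank distance is the unit used
#' by the duplication classifier.
#'
#' @param models gene-model data.frame (see [read_gff3()]).
#' @return the models with the `rank` column filled in.
#' @export
assign_ranks <- function(models) {
  models$rank <- NA_integer_
  for (ch in unique(models$chrom)) {
    idx <- which(models$chrom == ch)
    o <- order(models$start[idx], models$end[idx], models$gene_id[idx])
    models$rank[idx[o]] <- seq_along(idx) - 1L
  }
  models
}

# Sort key for chromosome names: placed chromosomes first in natural
# (numeric) order, then scaffolds sorted by name.
.chrom_order <- function(chrom, is_placed) {
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*", "",
                                         sub("[^0-9]*$", "", chrom))))
  num[is.na(num)] <- Inf
  order(!is_placed, num, chrom)
}

#' Rename family members by chromosomal order
#'
#' Members are sorted by (placed chromosomes first, natural chromosome
#' order, start coordinate) and numbered `<prefix>1 .. <prefix>N`; genes on
#' unanchored scaffolds follow all chromosome-placed genes.  The numbering
#' is a pure function of coordinates, invariant to the order of
#' `member_ids`.
#'
#' @param models gene-model data.frame with ranks assigned.
#' @param member_ids character vector of family member gene IDs.
#' @param prefix family name prefix (e.g. `"AtMYB"`).
#' @return data.frame with columns `original_id`, `family_name`, `chrom`,
#'   `start`, `end`, `strand`, `rank`.
#' @export
rename_family <- function(models, member_ids, prefix = "FAM") {
  missing <- setdiff(member_ids, models$gene_id)
  if (length(missing) > 0L)
    stop("member ID(s) absent from annotation: ",
         paste(missing, collapse = ", "))
  m <- models[match(unique(member_ids), models$gene_id), , drop = FALSE]
  # chromosome-level order first, then start (ties by end then id) within
  m <- m[.chrom_order(m$chrom, m$is_placed), , drop = FALSE]
  m <- m[order(match(m$chrom, unique(m$chrom)), m$start, m$end, m$gene_id), ,
         drop = FALSE]
  data.frame(
    original_id = m$gene_id,
    family_name = paste0(prefix, seq_len(nrow(m))),
    chrom = m$chrom, start = m$start, end = m$end, strand = m$strand,
    rank = m$rank, stringsAsFactors = FALSE
  )
}

#' Write a family naming table as TSV
#'
#' @param naming result of [rename_family()].
#' @param path output path.
#' @export
write_naming_table <- function(naming, path) {
  write.table(naming, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
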