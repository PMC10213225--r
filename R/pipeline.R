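# Pipeline orchestration: run every stage in dependency order against
# files on disk, write one TSV per stage plus a JSON manifest, and join a
# per-member family summary.

#' Pipeline configuration
#'
#' @param genome,gff3,members paths to the genome FASTA, annotation GFF3
#'   and member-ID list (one per line); required.
#' @param hits path to the self-homology hit table (BLAST outfmt-6 style
#'   or 4-column); enables the synteny/Ka-Ks/classification stages.
#' @param catalogue path to the cis-element catalogue TSV; enables the
#'   promoter stage.
#' @param counts,lengths paths to the count matrix TSV (gene_id column +
#'   one column per sample named `stage<s>_rep<r>`) and transcript length
#'   TSV; enables the expression stage.
#' @param ct_table path to a qPCR CT TSV (`gene`, `condition`,
#'   `replicate`, `ct_target`, `ct_reference`); enables the ddCT stage.
#' @param tree optional Newick file used only to order expression output
#'   rows.
#' @param out_dir output directory.
#' @param prefix family name prefix.
#' @param promoter_length,evalue_max,top_n,min_anchors,max_gap,
#'   proximal_rank_lt stage parameters (see the stage functions).
#' @param ks_window numeric `(lo, hi)`: the externally dated WGD Ks
#'   window; required when `hits` is given.
#' @param calibrator_condition calibrator for the ddCT stage.
#' @param seed seed stamped into the manifest (the pipeline itself is
#'   deterministic).
#' @return config list (class `famscan_pipeline_config`).
#' @export
pipeline_config <- function(genome, gff3, members,
                            hits = NULL, catalogue = NULL,
                            counts = NULL, lengths = NULL,
                            ct_table = NULL, tree = NULL,
                            out_dir = "famscan_out", prefix = "FAM",
                            promoter_length = 2000L,
                            evalue_max = 1e-5, top_n = 5L,
                            min_anchors = 5L, max_gap = 25L,
                            proximal_rank_lt = 20L,
                            ks_window = NULL,
                            calibrator_condition = NULL,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!is.null(cfg$hits) && is.null(cfg$ks_window))
    stop("configuration error: ks_window (lo, hi) is required when the ",
         "synteny stage is enabled")
  for (p in c("genome", "gff3", "members"))
    if (!file.exists(cfg[[p]]))
      stop("configuration error: missing input file for '", p, "': ",
           cfg[[p]])
  structure(cfg, class = "famscan_pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full characterization pipeline
#'
#' Executes genome/annotation loading, member renaming, protein
#' properties, promoter extraction + motif/SSR scanning, hit filtering,
#' block detection, Ka/Ks on anchors and partner pairs, duplication
#' classification with WGD/segmental refinement, and expression
#' summarization, writing one TSV per stage and a JSON run manifest with
#' parameters, seed and input checksums.  Reruns with identical config and
#' inputs produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of in-memory stage results (`naming`,
#'   `properties`, `promoters`, `motif_hits`, `ssrs`, `blocks`, `kaks`,
#'   `calls`, `expression`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "famscan_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stages_done <- character(0)

  genome <- .stage("genome_io", read_fasta(config$genome, "DNA"))
  models <- .stage("genome_io", read_gff3(config$gff3, genome))
  members <- .stage("genome_io", {
    m <- readLines(config$members, warn = FALSE)
    m[nzchar(m)]
  })
  res$naming <- .stage("genome_io",
                       rename_family(models, members, config$prefix))
  .write_tsv(res$naming, config$out_dir, "naming.tsv")
  stages_done <- c(stages_done, "genome_io")

  seqs <- .stage("protparam", extract_all_cds(models, genome, members))
  res$properties <- .stage("protparam", protein_properties(seqs$protein))
  .write_tsv(res$properties, config$out_dir, "protein_properties.tsv")
  write_fasta(seqs$protein, file.path(config$out_dir, "proteins.fa"))
  write_fasta(seqs$cds, file.path(config$out_dir, "cds.fa"))
  stages_done <- c(stages_done, "protparam")

  res$promoters <- .stage("promoter_analysis",
                          extract_promoters(models, genome, members,
                                            config$promoter_length))
  write_fasta(setNames(res$promoters$seq, res$promoters$gene_id)[
    nzchar(res$promoters$seq)],
    file.path(config$out_dir, "promoters.fa"))
  if (!is.null(config$catalogue)) {
    cat_tab <- .stage("promoter_analysis", load_catalogue(config$catalogue))
    res$motif_hits <- .stage("promoter_analysis",
                             scan_motifs(res$promoters, cat_tab))
    .write_tsv(res$motif_hits, config$out_dir, "motif_hits.tsv")
    cat_counts <- categorize_hits(res$motif_hits, cat_tab, members)
    .write_tsv(data.frame(gene_id = rownames(cat_counts), cat_counts,
                          check.names = FALSE),
               config$out_dir, "element_categories.tsv")
    res$category_counts <- cat_counts
  }
  gene_seqs <- vapply(members, function(g) {
    i <- match(g, models$gene_id)
    substr(genome[[models$chrom[i]]], models$start[i] + 1L, models$end[i])
  }, character(1))
  res$ssrs <- .stage("promoter_analysis", find_ssrs(gene_seqs))
  .write_tsv(res$ssrs, config$out_dir, "ssrs.tsv")
  stages_done <- c(stages_done, "promoter_analysis")

  if (!is.null(config$hits)) {
    raw_hits <- .stage("synteny_dup", read_hits(config$hits))
    fh <- .stage("synteny_dup",
                 filter_hits(raw_hits, config$evalue_max, config$top_n))
    blocks <- .stage("synteny_dup",
                     detect_blocks(fh, models, config$min_anchors,
                                   config$max_gap))
    anchor_pairs <- unique(do.call(rbind, lapply(blocks, function(b)
      b$anchors[, c("gene_a", "gene_b")])))
    member_pairs <- unique(data.frame(
      gene_a = pmin(fh$query, fh$subject),
      gene_b = pmax(fh$query, fh$subject),
      stringsAsFactors = FALSE))
    member_pairs <- member_pairs[member_pairs$gene_a %in% members |
                                   member_pairs$gene_b %in% members, ,
                                 drop = FALSE]
    pairs <- unique(rbind(anchor_pairs, member_pairs))
    res$kaks <- .stage("kaks", kaks_table(pairs, models, genome))
    .write_tsv(res$kaks, config$out_dir, "kaks.tsv")
    blocks <- add_block_ks(blocks, res$kaks)
    calls <- .stage("synteny_dup",
                    classify_duplicates(members, fh, blocks, models,
                                        config$proximal_rank_lt))
    refined <- .stage("synteny_dup",
                      assign_wgd_segmental(blocks, calls,
                                           config$ks_window,
                                           config$min_anchors))
    res$blocks <- refined$blocks
    res$calls <- refined$calls
    .write_tsv(block_summary(res$blocks), config$out_dir, "blocks.tsv")
    .write_tsv(res$calls, config$out_dir, "duplication_calls.tsv")
    .write_tsv(dotplot_table(res$blocks), config$out_dir, "dotplot.tsv")
    stages_done <- c(stages_done, "synteny_dup", "kaks")
  }

  if (!is.null(config$counts) && !is.null(config$lengths)) {
    res$expression <- .stage("expression", {
      ct <- read.delim(config$counts, check.names = FALSE)
      lt <- read.delim(config$lengths)
      counts <- as.matrix(ct[, -1, drop = FALSE])
      rownames(counts) <- ct[[1L]]
      lens <- setNames(lt$length, lt$gene_id)
      tp <- tpm(counts, lens)
      lg <- log_transform(tp)
      sc <- row_scale(lg)
      if (!is.null(config$tree)) sc <- order_by_tree(sc, config$tree)
      list(tpm = tp, log_tpm = lg, scaled = sc)
    })
    .write_tsv(data.frame(gene_id = rownames(res$expression$tpm),
                          round(res$expression$tpm, 3),
                          check.names = FALSE),
               config$out_dir, "tpm.tsv")
    .write_tsv(data.frame(gene_id = rownames(res$expression$scaled),
                          round(res$expression$scaled, 4),
                          check.names = FALSE),
               config$out_dir, "expression_scaled.tsv")
    stages_done <- c(stages_done, "expression")
  }

  if (!is.null(config$ct_table)) {
    recs <- .stage("expression_qpcr",
                   read.delim(config$ct_table, stringsAsFactors = FALSE))
    res$ddct <- .stage("expression_qpcr",
                       ddct_fold_change(recs,
                                        config$calibrator_condition))
    .write_tsv(res$ddct$fold, config$out_dir, "ddct_fold_changes.tsv")
    stages_done <- c(stages_done, "expression_qpcr")
  }

  res$summary <- summarize_family(res, members)
  .write_tsv(res$summary, config$out_dir, "family_summary.tsv")

  params <- config[!vapply(config, is.null, logical(1))]
  inputs <- unlist(params[names(params) %in%
                            c("genome", "gff3", "members", "hits",
                              "catalogue", "counts", "lengths",
                              "ct_table", "tree")])
  res$manifest <- list(
    package = "famscan",
    version = as.character(utils::packageVersion("famscan")),
    seed = config$seed,
    parameters = params[setdiff(names(params), names(inputs))],
    inputs = as.list(tools::md5sum(inputs)),
    stages_completed = stages_done
  )
  jsonlite::write_json(res$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

# Monotone-trend call from a TPM matrix with stage<s>_rep<r> columns.
.expression_trend <- function(tpm_mat, min_fold = 1.5) {
  stages <- sub("_rep.*$", "", colnames(tpm_mat))
  means <- sapply(unique(stages), function(s)
    rowMeans(tpm_mat[, stages == s, drop = FALSE]))
  apply(means, 1, function(m) {
    if (all(diff(m) > 0) && m[length(m)] >= min_fold * (m[1] + 1e-9))
      "up"
    else if (all(diff(m) < 0) && m[1] >= min_fold * (m[length(m)] + 1e-9))
      "down"
    else "flat"
  })
}

#' Per-member family summary
#'
#' One row per member joining naming, protein properties, duplication
#' label, omega, cis-element and SSR counts, and expression trend; the
#' attribute `label_counts` holds the label frequency table whose mode is
#' the family's dominant duplication type.
#'
#' @param res result list from [run_pipeline()] (or a compatible list).
#' @param members member gene IDs.
#' @return summary data.frame.
#' @export
summarize_family <- function(res, members) {
  out <- data.frame(gene_id = members, stringsAsFactors = FALSE)
  nm <- res$naming
  out$family_name <- nm$family_name[match(members, nm$original_id)]
  pp <- res$properties
  for (cc in c("length", "mw_kda", "pi", "gravy", "instability_index",
               "aliphatic_index"))
    out[[cc]] <- pp[[cc]][match(members, pp$id)]
  if (!is.null(res$calls)) {
    out$duplication <- res$calls$label[match(members, res$calls$gene_id)]
    if (!is.null(res$kaks)) {
      omega_of <- function(g) {
        rows <- res$kaks[res$kaks$gene_a == g | res$kaks$gene_b == g, ]
        if (nrow(rows) == 0L || all(is.na(rows$omega))) NA_real_
        else median(rows$omega, na.rm = TRUE)
      }
      out$omega <- vapply(members, omega_of, numeric(1))
    }
  }
  if (!is.null(res$category_counts)) {
    cc <- res$category_counts
    out$n_cis_elements <- rowSums(cc)[match(members, rownames(cc))]
  }
  if (!is.null(res$ssrs))
    out$n_ssrs <- vapply(members, function(g)
      sum(res$ssrs$seq_id == g), numeric(1))
  if (!is.null(res$expression)) {
    tr <- .expression_trend(res$expression$tpm)
    out$trend <- unname(tr[match(members, names(tr))])
    out$trend[is.na(out$trend)] <- NA_character_
  }
  if (!is.null(out$duplication))
    attr(out, "label_counts") <- sort(table(out$duplication),
                                      decreasing = TRUE)
  out
}
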