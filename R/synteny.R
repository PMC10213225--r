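# Collinear-block detection and duplication-mode classification.
#
# Anchors are homology hits mapped to per-chromosome gene ranks; blocks are
# maximum-score monotone chains of anchors (both orientations), found by
# dynamic programming per chromosome pair.  Duplication modes follow the
# successive re-labeling rules: every duplicate starts as "dispersed" and is
# upgraded to "proximal" (same-chromosome rank distance 2..<20), "tandem"
# (rank distance 1) or "wgd_or_segmental" (anchor in a collinear block),
# taking the highest label any partner supports.  Genes without surviving
# hits are singletons.

#' Read a BLAST outfmt-6 style hit table
#'
#' Only the query, subject, E-value and bitscore columns are consumed.
#'
#' @param path tabular hit file (no header, >= 12 columns, or a 4-column
#'   table `query, subject, evalue, bitscore`).
#' @return data.frame with columns `query`, `subject`, `evalue`, `bitscore`.
#' @export
read_hits <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) >= 12L) {
    out <- tab[, c(1L, 2L, 11L, 12L)]
  } else if (ncol(tab) == 4L) {
    out <- tab
  } else stop("hit table must have 4 or >= 12 columns: ", path)
  names(out) <- c("query", "subject", "evalue", "bitscore")
  out$evalue <- as.numeric(out$evalue)
  out$bitscore <- as.numeric(out$bitscore)
  if (any(!is.finite(out$evalue))) stop("non-finite E-value in ", path)
  out
}

#' Filter homology hits
#'
#' Removes self-hits, applies the strict E-value cutoff (`evalue <
#' evalue_max` is kept), retains per query only the `top_n` subjects by
#' bitscore (ties broken by subject ID), and symmetrizes the result: if
#' a->b survives, b->a is present too.
#'
#' @param hits data.frame with `query`, `subject`, `evalue`, `bitscore`.
#' @param evalue_max strict upper bound on the E-value (default `1e-5`).
#' @param top_n subjects kept per query (default 5).
#' @return filtered, symmetrized hit data.frame.
#' @export
filter_hits <- function(hits, evalue_max = 1e-5, top_n = 5L) {
  h <- hits[hits$query != hits$subject & hits$evalue < evalue_max, ,
            drop = FALSE]
  if (nrow(h) > 0L) {
    # best record per (query, subject)
    h <- h[order(h$query, h$subject, -h$bitscore), , drop = FALSE]
    h <- h[!duplicated(h[, c("query", "subject")]), , drop = FALSE]
    h <- h[order(h$query, -h$bitscore, h$subject), , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(h)), h$query),
                          function(i) head(i, top_n)))
    h <- h[sort(keep), , drop = FALSE]
  }
  # symmetrize
  key <- paste(h$query, h$subject)
  rev_missing <- !(paste(h$subject, h$query) %in% key)
  if (any(rev_missing)) {
    extra <- h[rev_missing, , drop = FALSE]
    h <- rbind(h, data.frame(query = extra$subject, subject = extra$query,
                             evalue = extra$evalue,
                             bitscore = extra$bitscore,
                             stringsAsFactors = FALSE))
  }
  rownames(h) <- NULL
  h
}

# Maximum-score monotone chain among anchors by dynamic programming.
# anchors: data.frame with rank_a, rank_b.  Returns indices of the best
# chain (possibly length 1) and its score, or NULL when no anchors.
.best_chain <- function(anchors, orientation, max_gap, match_score,
                        gap_penalty) {
  n <- nrow(anchors)
  if (n == 0L) return(NULL)
  o <- order(anchors$rank_a, anchors$rank_b)
  ra <- anchors$rank_a[o]; rb <- anchors$rank_b[o]
  best <- rep(match_score, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[j] >= ra[i]) next
      ok <- if (orientation == "same") rb[j] < rb[i] else rb[j] > rb[i]
      if (!ok) next
      ga <- ra[i] - ra[j] - 1L
      gb <- abs(rb[i] - rb[j]) - 1L
      if (ga > max_gap || gb > max_gap) next
      cand <- best[j] + match_score - gap_penalty * (ga + gb)
      if (cand > best[i]) {
        best[i] <- cand
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)
  chain <- integer(0)
  i <- end
  while (!is.na(i)) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  list(idx = o[chain], score = best[end])
}

#' Detect collinear blocks from homology hits
#'
#' For every chromosome pair, anchors (hit pairs mapped to gene ranks) are
#' chained by dynamic programming; chains are scored `match_score` per
#' anchor minus `gap_penalty` per skipped rank step beyond adjacency
#' (MCScanX-style 50 : 1 weighting), both orientations are searched, chains
#' shorter than `min_anchors` are discarded, and each anchor joins at most
#' one block per orientation.
#'
#' @param hits filtered hit data.frame (see [filter_hits()]).
#' @param models gene-model data.frame with ranks assigned.
#' @param min_anchors minimum anchors per block (default 5).
#' @param max_gap maximum skipped ranks between consecutive anchors on
#'   either side (default 25).
#' @param match_score,gap_penalty chain scoring weights.
#' @return list of blocks (class `collinear_blocks`); each block is a list
#'   with `block_id`, `chrom_a`, `chrom_b`, `orientation`, `score`,
#'   `anchors` (data.frame `gene_a`, `gene_b`, `rank_a`, `rank_b`),
#'   `median_ks` (`NA` until [add_block_ks()]).
#' @export
detect_blocks <- function(hits, models, min_anchors = 5L, max_gap = 25L,
                          match_score = 50, gap_penalty = 1) {
  idx <- match(hits$query, models$gene_id)
  jdx <- match(hits$subject, models$gene_id)
  keep <- !is.na(idx) & !is.na(jdx)
  h <- data.frame(
    gene_a = hits$query[keep], gene_b = hits$subject[keep],
    chrom_a = models$chrom[idx[keep]], chrom_b = models$chrom[jdx[keep]],
    rank_a = models$rank[idx[keep]], rank_b = models$rank[jdx[keep]],
    stringsAsFactors = FALSE
  )
  # canonical anchor orientation: chrom_a <= chrom_b, and rank_a < rank_b
  # within a chromosome; one anchor per unordered gene pair
  swap <- h$chrom_a > h$chrom_b |
    (h$chrom_a == h$chrom_b & h$rank_a > h$rank_b)
  h[swap, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")] <-
    h[swap, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rank_b", "rank_a")]
  h <- h[h$gene_a != h$gene_b, , drop = FALSE]
  h <- h[!duplicated(paste(h$gene_a, h$gene_b)), , drop = FALSE]

  blocks <- list()
  bid <- 0L
  for (cp in unique(paste(h$chrom_a, h$chrom_b, sep = "\r"))) {
    sub <- h[paste(h$chrom_a, h$chrom_b, sep = "\r") == cp, , drop = FALSE]
    for (orientation in c("same", "inverted")) {
      pool <- sub
      repeat {
        res <- .best_chain(pool, orientation, max_gap, match_score,
                           gap_penalty)
        if (is.null(res) || length(res$idx) < min_anchors) break
        anchors <- pool[res$idx, , drop = FALSE]
        rownames(anchors) <- NULL
        bid <- bid + 1L
        blocks[[bid]] <- list(
          block_id = paste0("block", bid),
          chrom_a = anchors$chrom_a[1L], chrom_b = anchors$chrom_b[1L],
          orientation = orientation, score = res$score,
          anchors = anchors[, c("gene_a", "gene_b", "rank_a", "rank_b")],
          median_ks = NA_real_, n_ks_excluded = NA_integer_,
          class = NA_character_
        )
        pool <- pool[-res$idx, , drop = FALSE]
      }
    }
  }
  structure(blocks, class = "collinear_blocks")
}

.block_gene_set <- function(blocks) {
  unique(unlist(lapply(blocks, function(b) c(b$anchors$gene_a,
                                             b$anchors$gene_b))))
}

.LABEL_PRECEDENCE <- c(singleton = 0, dispersed = 1, proximal = 2,
                       tandem = 3, wgd_or_segmental = 4)

#' Classify duplication mode of family members
#'
#' Every member with no surviving hit is a singleton.  Members with hits
#' start as dispersed duplicates and are upgraded by precedence
#' `dispersed < proximal < tandem < wgd_or_segmental`: a same-chromosome
#' partner at rank distance 1 supports tandem, rank distance in
#' `[2, proximal_rank_lt)` supports proximal, and membership as an anchor
#' of any collinear block supports wgd_or_segmental.  Cross-chromosome
#' partners are never proximal or tandem.
#'
#' @param members character vector of member gene IDs.
#' @param hits filtered hit data.frame.
#' @param blocks `collinear_blocks` from [detect_blocks()].
#' @param models gene-model data.frame with ranks.
#' @param proximal_rank_lt strict upper bound on the proximal rank
#'   distance (default 20).
#' @return data.frame with `gene_id`, `label`, `partner`, `rank_distance`,
#'   `block_id`.
#' @export
classify_duplicates <- function(members, hits, blocks, models,
                                proximal_rank_lt = 20L) {
  missing <- setdiff(members, models$gene_id)
  if (length(missing) > 0L)
    stop("member(s) absent from models: ", paste(missing, collapse = ", "))
  anchor_genes <- .block_gene_set(blocks)
  gene_block <- list()
  for (b in blocks) {
    for (g in unique(c(b$anchors$gene_a, b$anchors$gene_b)))
      gene_block[[g]] <- c(gene_block[[g]], b$block_id)
  }
  chrom_of <- setNames(models$chrom, models$gene_id)
  rank_of <- setNames(models$rank, models$gene_id)

  rows <- lapply(members, function(g) {
    partners <- unique(c(hits$subject[hits$query == g],
                         hits$query[hits$subject == g]))
    partners <- setdiff(partners, g)
    if (length(partners) == 0L)
      return(data.frame(gene_id = g, label = "singleton",
                        partner = NA_character_, rank_distance = NA_integer_,
                        block_id = NA_character_, stringsAsFactors = FALSE))
    label <- "dispersed"
    partner <- partners[1L]
    rank_distance <- NA_integer_
    same <- partners[!is.na(chrom_of[partners]) &
                       chrom_of[partners] == chrom_of[g]]
    if (length(same) > 0L) {
      d <- abs(rank_of[same] - rank_of[g])
      if (any(d >= 2 & d < proximal_rank_lt) &&
          .LABEL_PRECEDENCE[label] < .LABEL_PRECEDENCE["proximal"]) {
        label <- "proximal"
        i <- which(d >= 2 & d < proximal_rank_lt)[1L]
        partner <- same[i]; rank_distance <- unname(d[i])
      }
      if (any(d == 1)) {
        label <- "tandem"
        partner <- same[which(d == 1)[1L]]; rank_distance <- 1L
      }
    }
    block_id <- NA_character_
    if (g %in% anchor_genes) {
      label <- "wgd_or_segmental"
      block_id <- gene_block[[g]][1L]
    }
    data.frame(gene_id = g, label = label, partner = partner,
               rank_distance = rank_distance, block_id = block_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Median Ks of one block
#'
#' Median over the anchor pairs' Ks; anchors with undefined (saturated or
#' missing) Ks are excluded and counted.
#'
#' @param block one block from [detect_blocks()].
#' @param kaks_results data.frame with `gene_a`, `gene_b`, `ks` (as from
#'   [kaks_table()]).
#' @return list with `median_ks` (`NA` when every anchor is undefined) and
#'   `n_excluded`.
#' @export
block_median_ks <- function(block, kaks_results) {
  if (nrow(block$anchors) == 0L) stop("empty block")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ks <- kaks_results$ks[match(key(block$anchors$gene_a,
                                  block$anchors$gene_b),
                              key(kaks_results$gene_a,
                                  kaks_results$gene_b))]
  defined <- !is.na(ks)
  list(median_ks = if (any(defined)) median(ks[defined]) else NA_real_,
       n_excluded = sum(!defined))
}

#' Attach median Ks to every block
#'
#' @param blocks `collinear_blocks`.
#' @param kaks_results data.frame with `gene_a`, `gene_b`, `ks`.
#' @return the blocks with `median_ks` and `n_ks_excluded` filled in.
#' @export
add_block_ks <- function(blocks, kaks_results) {
  for (i in seq_along(blocks)) {
    m <- block_median_ks(blocks[[i]], kaks_results)
    blocks[[i]]$median_ks <- m$median_ks
    blocks[[i]]$n_ks_excluded <- m$n_excluded
  }
  blocks
}

#' Refine wgd_or_segmental calls into WGD vs segmental
#'
#' A block whose median Ks falls inside the dated WGD window
#' `[ks_window[1], ks_window[2]]` and that has at least `min_anchors_wgd`
#' anchors is labeled `wgd`; all other blocks are `segmental`.  Member
#' calls of `wgd_or_segmental` follow their best block: most anchors, ties
#' broken by lowest median Ks.
#'
#' @param blocks `collinear_blocks` with median Ks attached.
#' @param calls classification data.frame from [classify_duplicates()].
#' @param ks_window numeric length-2 `(lo, hi)` Ks window of the WGD event
#'   (taken from an external dating of the genome; mandatory).
#' @param min_anchors_wgd minimum anchors for a WGD block (default 5).
#' @return list with elements `blocks` (class labels filled) and `calls`
#'   (labels refined to `wgd` / `segmental`).
#' @export
assign_wgd_segmental <- function(blocks, calls, ks_window,
                                 min_anchors_wgd = 5L) {
  if (length(blocks) > 0L &&
      (missing(ks_window) || length(ks_window) != 2L))
    stop("ks_window (lo, hi) is required when blocks exist")
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    is_wgd <- !is.na(b$median_ks) &&
      b$median_ks >= ks_window[1L] && b$median_ks <= ks_window[2L] &&
      nrow(b$anchors) >= min_anchors_wgd
    blocks[[i]]$class <- if (is_wgd) "wgd" else "segmental"
  }
  binfo <- data.frame(
    block_id = vapply(blocks, `[[`, character(1), "block_id"),
    n_anchors = vapply(blocks, function(b) nrow(b$anchors), integer(1)),
    median_ks = vapply(blocks, `[[`, numeric(1), "median_ks"),
    class = vapply(blocks, `[[`, character(1), "class"),
    stringsAsFactors = FALSE
  )
  gene_blocks <- list()
  for (b in blocks) {
    for (g in unique(c(b$anchors$gene_a, b$anchors$gene_b)))
      gene_blocks[[g]] <- c(gene_blocks[[g]], b$block_id)
  }
  for (i in seq_len(nrow(calls))) {
    if (calls$label[i] != "wgd_or_segmental") next
    ids <- gene_blocks[[calls$gene_id[i]]]
    cand <- binfo[binfo$block_id %in% ids, , drop = FALSE]
    cand <- cand[order(-cand$n_anchors, cand$median_ks), , drop = FALSE]
    calls$label[i] <- cand$class[1L]
    calls$block_id[i] <- cand$block_id[1L]
  }
  list(blocks = blocks, calls = calls)
}

#' Dot-plot table of block anchors
#'
#' One row per anchor: ranks, chromosomes, block ID and the block's median
#' Ks — the table behind a within-genome homologous collinearity dot-plot.
#'
#' @param blocks `collinear_blocks`.
#' @return data.frame `rank_a`, `rank_b`, `chrom_a`, `chrom_b`,
#'   `block_id`, `median_ks`.
#' @export
dotplot_table <- function(blocks) {
  if (length(blocks) == 0L)
    return(data.frame(rank_a = integer(0), rank_b = integer(0),
                      chrom_a = character(0), chrom_b = character(0),
                      block_id = character(0), median_ks = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(blocks, function(b) {
    a <- b$anchors
    if (b$orientation == "inverted") a <- a[order(a$rank_a), , drop = FALSE]
    data.frame(rank_a = a$rank_a, rank_b = a$rank_b,
               chrom_a = b$chrom_a, chrom_b = b$chrom_b,
               block_id = b$block_id, median_ks = b$median_ks,
               stringsAsFactors = FALSE)
  }))
}

#' Summary data.frame of blocks
#'
#' @param blocks `collinear_blocks`.
#' @return one row per block: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_anchors`, `score`, `median_ks`, `class`.
#' @export
block_summary <- function(blocks) {
  if (length(blocks) == 0L)
    return(data.frame(block_id = character(0), chrom_a = character(0),
                      chrom_b = character(0), orientation = character(0),
                      n_anchors = integer(0), score = numeric(0),
                      median_ks = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(blocks, function(b) data.frame(
    block_id = b$block_id, chrom_a = b$chrom_a, chrom_b = b$chrom_b,
    orientation = b$orientation, n_anchors = nrow(b$anchors),
    score = b$score, median_ks = b$median_ks, class = b$class,
    stringsAsFactors = FALSE
  )))
}
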