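test_that("hit filtering removes self-hits, applies the strict E-value cut, keeps top-N and symmetrizes", {
  hits <- data.frame(
    query = c("g1", "g1", "g1", "g2", "g3"),
    subject = c("g1", "g2", "g3", "g4", "g4"),
    evalue = c(1e-40, 1e-5, 1e-30, 1e-6, 2e-5),
    bitscore = c(500, 90, 100, 80, 70),
    stringsAsFactors = FALSE
  )
  f <- filter_hits(hits)
  expect_false(any(f$query == f$subject))
  expect_false(any(f$query == "g1" & f$subject == "g2"))  # 1e-5 removed
  expect_true(any(f$query == "g1" & f$subject == "g3"))
  expect_true(any(f$query == "g3" & f$subject == "g1"))   # symmetrized
  expect_false(any(f$subject == "g3" & f$query == "g4"))  # 2e-5 removed

  # top-N by bitscore with ties broken by subject id
  many <- data.frame(
    query = "q", subject = paste0("s", 1:7), evalue = 1e-20,
    bitscore = c(100, 100, 90, 80, 70, 60, 50), stringsAsFactors = FALSE
  )
  f2 <- filter_hits(many, top_n = 5)
  kept <- f2$subject[f2$query == "q"]
  expect_setequal(kept, c("s1", "s2", "s3", "s4", "s5"))
})

test_that("a clean rank diagonal forms one block and four anchors do not", {
  m <- make_models(data.frame(
    gene_id = c(paste0("x", 1:8), paste0("y", 1:8)),
    chrom = rep(c("chr1", "chr2"), each = 8),
    start = rep(seq(1000, by = 1000, length.out = 8), 2),
    end = rep(seq(1500, by = 1000, length.out = 8), 2),
    strand = "+", stringsAsFactors = FALSE
  ))
  diag_hits <- data.frame(query = paste0("x", 1:6),
                          subject = paste0("y", 1:6),
                          evalue = 1e-30, bitscore = 100,
                          stringsAsFactors = FALSE)
  b <- detect_blocks(diag_hits, m)
  expect_length(b, 1)
  expect_equal(nrow(b[[1]]$anchors), 6)
  expect_equal(b[[1]]$orientation, "same")

  b4 <- detect_blocks(diag_hits[1:4, ], m)
  expect_length(b4, 0)
})

test_that("an anti-diagonal with noise yields one inverted block matching exhaustive search", {
  m <- make_models(data.frame(
    gene_id = c(paste0("x", 1:12), paste0("y", 1:12)),
    chrom = rep(c("chr1", "chr2"), each = 12),
    start = rep(seq(1000, by = 1000, length.out = 12), 2),
    end = rep(seq(1500, by = 1000, length.out = 12), 2),
    strand = "+", stringsAsFactors = FALSE
  ))
  anti <- data.frame(query = paste0("x", 1:8),
                     subject = paste0("y", 8:1),
                     evalue = 1e-30, bitscore = 100,
                     stringsAsFactors = FALSE)
  noise <- data.frame(query = c("x2", "x9", "x11"),
                      subject = c("y11", "y2", "y12"),
                      evalue = 1e-30, bitscore = 100,
                      stringsAsFactors = FALSE)
  hits <- rbind(anti, noise)
  blocks <- detect_blocks(hits, m)
  inv <- Filter(function(b) b$orientation == "inverted", blocks)
  expect_gte(length(inv), 1)
  expect_equal(nrow(inv[[1]]$anchors), 8)
  # oracle: exhaustive chain enumeration over the same anchors
  ra <- m$rank[match(hits$query, m$gene_id)]
  rb <- m$rank[match(hits$subject, m$gene_id)]
  want <- oracle_best_chain_score(ra, rb, "inverted")
  expect_equal(inv[[1]]$score, want)
})

test_that("chaining DP equals exhaustive chain enumeration on random instances", {
  set.seed(2024)
  m <- make_models(data.frame(
    gene_id = c(paste0("x", 1:30), paste0("y", 1:30)),
    chrom = rep(c("chr1", "chr2"), each = 30),
    start = rep(seq(1000, by = 1000, length.out = 30), 2),
    end = rep(seq(1500, by = 1000, length.out = 30), 2),
    strand = "+", stringsAsFactors = FALSE
  ))
  for (trial in 1:60) {
    n <- sample(5:12, 1)
    hits <- unique(data.frame(
      query = paste0("x", sample(30, n, replace = TRUE)),
      subject = paste0("y", sample(30, n, replace = TRUE)),
      evalue = 1e-30, bitscore = 100, stringsAsFactors = FALSE))
    blocks <- detect_blocks(hits, m, min_anchors = 1L)
    ra <- m$rank[match(hits$query, m$gene_id)]
    rb <- m$rank[match(hits$subject, m$gene_id)]
    for (orient in c("same", "inverted")) {
      got <- max(c(-Inf, vapply(Filter(function(b)
        b$orientation == orient, blocks), `[[`, numeric(1), "score")))
      want <- oracle_best_chain_score(ra, rb, orient)
      expect_equal(got, want, label = paste("trial", trial, orient))
    }
  }
})

test_that("anchors obey the block monotonicity contract in simulated genomes", {
  sim <- simulate_genome(small_sim_config(seed = 31))
  hits <- make_hits(sim$truth, sim$models$gene_id, 0.05, seed = 31)
  blocks <- detect_blocks(filter_hits(hits), sim$models)
  expect_gt(length(blocks), 0)
  for (b in blocks) {
    expect_true(all(diff(b$anchors$rank_a) > 0))
    d <- diff(b$anchors$rank_b)
    if (b$orientation == "same") expect_true(all(d > 0))
    else expect_true(all(d < 0))
    expect_true(all(diff(b$anchors$rank_a) - 1 <= 25))
    expect_true(all(abs(d) - 1 <= 25))
  }
})

test_that("the classifier reproduces the constructed micro-genome labels exactly", {
  mg <- micro_genome()
  fh <- filter_hits(mg$hits)
  blocks <- detect_blocks(fh, mg$models)
  expect_length(blocks, 1)
  expect_equal(nrow(blocks[[1]]$anchors), 5)
  calls <- classify_duplicates(names(mg$truth), fh, blocks, mg$models)
  expect_equal(setNames(calls$label, calls$gene_id), mg$truth)
  # every member gets exactly one label
  expect_equal(nrow(calls), length(mg$truth))
  expect_false(any(duplicated(calls$gene_id)))
})

test_that("rank-distance boundaries: distance 1 tandem, 2..19 proximal, 20 dispersed", {
  m <- make_models(data.frame(
    gene_id = paste0("g", 1:30), chrom = "chr1",
    start = seq(1000, by = 1000, length.out = 30),
    end = seq(1500, by = 1000, length.out = 30),
    strand = "+", stringsAsFactors = FALSE
  ))
  pair <- function(q, s) data.frame(query = q, subject = s, evalue = 1e-30,
                                    bitscore = 100, stringsAsFactors = FALSE)
  calls <- classify_duplicates(
    c("g1", "g2", "g5", "g24"),
    filter_hits(rbind(pair("g1", "g2"), pair("g5", "g24"))),
    structure(list(), class = "collinear_blocks"), m)
  lab <- setNames(calls$label, calls$gene_id)
  expect_equal(unname(lab["g1"]), "tandem")
  expect_equal(unname(lab["g2"]), "tandem")
  expect_equal(unname(lab["g5"]), "proximal")   # distance 19
  calls20 <- classify_duplicates(
    c("g1", "g21"), filter_hits(pair("g1", "g21")),
    structure(list(), class = "collinear_blocks"), m)
  expect_equal(calls20$label, c("dispersed", "dispersed"))  # distance 20
})

test_that("block median Ks handles odd, even and undefined anchors", {
  anchors <- data.frame(gene_a = c("a", "b", "c", "d"),
                        gene_b = c("w", "x", "y", "z"),
                        rank_a = 1:4, rank_b = 1:4,
                        stringsAsFactors = FALSE)
  blk <- list(block_id = "b1", anchors = anchors)
  kk <- data.frame(gene_a = c("a", "b", "c", "d"),
                   gene_b = c("w", "x", "y", "z"),
                   ks = c(0.1, 0.3, 0.2, NA), stringsAsFactors = FALSE)
  r <- block_median_ks(blk, kk)
  expect_equal(r$median_ks, 0.2)
  expect_equal(r$n_excluded, 1)
  kk$ks <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(block_median_ks(blk, kk)$median_ks, 0.25)
  kk$ks <- NA_real_
  r3 <- block_median_ks(blk, kk)
  expect_true(is.na(r3$median_ks))
  expect_equal(r3$n_excluded, 4)
})

test_that("WGD assignment follows the Ks window and the lowest-median tie-break", {
  mk_block <- function(id, genes_a, genes_b, med) {
    n <- length(genes_a)
    list(block_id = id, chrom_a = "chr1", chrom_b = "chr2",
         orientation = "same", score = 50 * n,
         anchors = data.frame(gene_a = genes_a, gene_b = genes_b,
                              rank_a = seq_len(n), rank_b = seq_len(n),
                              stringsAsFactors = FALSE),
         median_ks = med, n_ks_excluded = 0L, class = NA_character_)
  }
  b1 <- mk_block("b1", paste0("p", 1:5), paste0("q", 1:5), 1.3)
  b2 <- mk_block("b2", paste0("p", 1:5), paste0("r", 1:5), 0.2)
  blocks <- structure(list(b1, b2), class = "collinear_blocks")
  calls <- data.frame(gene_id = "p1", label = "wgd_or_segmental",
                      partner = NA, rank_distance = NA,
                      block_id = "b1", stringsAsFactors = FALSE)
  ref <- assign_wgd_segmental(blocks, calls, ks_window = c(1.0, 1.6))
  cls <- setNames(vapply(ref$blocks, `[[`, character(1), "class"),
                  vapply(ref$blocks, `[[`, character(1), "block_id"))
  expect_equal(unname(cls["b1"]), "wgd")
  expect_equal(unname(cls["b2"]), "segmental")
  # equal-size blocks: member follows the lower-median block
  expect_equal(ref$calls$label, "segmental")
  expect_equal(ref$calls$block_id, "b2")
  expect_error(assign_wgd_segmental(blocks, calls), "ks_window")
})

test_that("the dot-plot table mirrors blocks and handles the empty case", {
  mg <- micro_genome()
  blocks <- detect_blocks(filter_hits(mg$hits), mg$models)
  dp <- dotplot_table(blocks)
  expect_equal(nrow(dp), 5)
  expect_equal(length(unique(dp$block_id)), 1)
  empty <- dotplot_table(structure(list(), class = "collinear_blocks"))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("rank_a", "rank_b", "block_id", "median_ks") %in%
                    names(empty)))
})
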