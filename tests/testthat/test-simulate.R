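test_that("the generator is deterministic in (config, seed)", {
  s1 <- simulate_genome(small_sim_config(seed = 5))
  s2 <- simulate_genome(small_sim_config(seed = 5))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$models$gene_id, s2$models$gene_id)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_genome(small_sim_config(seed = 6))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("a zero-event configuration yields only singleton-eligible genes", {
  cfg <- simulation_config(seed = 3, n_chromosomes = 2L,
                           genes_per_chromosome = 30L,
                           cds_length_codons = 60L,
                           wgd = list(enabled = FALSE, event_ks = 1.2,
                                      retention = 0.3),
                           n_tandem = 0L, n_proximal = 0L, n_dispersed = 0L)
  sim <- simulate_genome(cfg)
  expect_true(all(sim$truth$true_label == "singleton"))
  expect_true(all(is.na(sim$truth$parent)))
  expect_equal(nrow(sim$models), 60)
})

test_that("planted labels are re-derivable from the emitted geometry", {
  sim <- simulate_genome(small_sim_config(seed = 17))
  tr <- sim$truth
  rank_of <- setNames(sim$models$rank, sim$models$gene_id)
  chrom_of <- setNames(sim$models$chrom, sim$models$gene_id)
  tandem <- tr[tr$true_label == "tandem", ]
  expect_equal(nrow(tandem), 2)
  expect_true(all(chrom_of[tandem$gene_id] == chrom_of[tandem$parent]))
  expect_true(all(abs(rank_of[tandem$gene_id] -
                        rank_of[tandem$parent]) == 1))
  prox <- tr[tr$true_label == "proximal", ]
  d <- abs(rank_of[prox$gene_id] - rank_of[prox$parent])
  expect_true(all(chrom_of[prox$gene_id] == chrom_of[prox$parent]))
  expect_true(all(d >= 2 & d < 20))
  disp <- tr[tr$true_label == "dispersed", ]
  expect_true(all(chrom_of[disp$gene_id] != chrom_of[disp$parent]))
})

test_that("full retention doubles the chromosome count and pairs every gene", {
  cfg <- simulation_config(seed = 8, n_chromosomes = 2L,
                           genes_per_chromosome = 20L,
                           cds_length_codons = 60L,
                           wgd = list(enabled = TRUE, event_ks = 1.0,
                                      retention = 1.0),
                           n_tandem = 0L, n_proximal = 0L, n_dispersed = 0L)
  sim <- simulate_genome(cfg)
  expect_equal(length(sim$genome), 4)
  expect_equal(sum(sim$truth$true_label == "wgd"), 40)
  ancestors <- sim$truth$parent[sim$truth$true_label == "wgd"]
  expect_setequal(ancestors,
                  sim$models$gene_id[sim$models$chrom %in%
                                       c("chr1", "chr2")])
})

test_that("evolve_cds respects the zero-target and omega = 0 limits", {
  set.seed(10)
  cds <- famscan:::.random_cds(100)
  expect_identical(evolve_cds(cds, 0, 0.2), cds)
  mut <- evolve_cds(cds, 0.3, omega = 0, seed = 99)
  r <- ng86(cds, mut)
  # with omega = 0 every accepted change is synonymous; the only
  # nonsynonymous counts NG86 can report come from pathway averaging over
  # codons hit more than once, so Nd stays a small fraction of Sd
  expect_lt(r$Nd, 0.1 * r$Sd)
  expect_gt(r$Sd, 0)
  expect_identical(evolve_cds(cds, 0.3, 0.5, seed = 1),
                   evolve_cds(cds, 0.3, 0.5, seed = 1))
})

test_that("true pairs survive hit filtering and spurious pairs never do", {
  sim <- simulate_genome(small_sim_config(seed = 23))
  hits <- make_hits(sim$truth, sim$models$gene_id, noise_rate = 0.5,
                    seed = 23)
  f <- filter_hits(hits, top_n = 1000L)
  key <- paste(f$query, f$subject)
  tp <- sim$truth[!is.na(sim$truth$parent), ]
  expect_true(all(paste(tp$parent, tp$gene_id) %in% key))
  noise <- hits[hits$evalue >= 1e-5, ]
  expect_gt(nrow(noise), 0)
  expect_false(any(paste(noise$query, noise$subject) %in% key))
})

test_that("planted promoter features are exactly recallable", {
  cat_tab <- test_catalogue()
  sim <- plant_promoter_features(6, cat_tab, length = 2000, n_motifs = 5,
                                 n_ssrs = 1, seed = 41)
  hits <- scan_motifs(sim$promoters, cat_tab)
  for (i in seq_len(nrow(sim$motif_truth))) {
    t <- sim$motif_truth[i, ]
    expect_true(any(hits$seq_id == t$seq_id & hits$motif == t$motif &
                      hits$start == t$start & hits$strand == t$strand),
                label = paste("planted motif", t$motif, "at", t$start))
  }
  ssrs <- find_ssrs(sim$promoters)
  for (i in seq_len(nrow(sim$ssr_truth))) {
    t <- sim$ssr_truth[i, ]
    expect_true(any(ssrs$seq_id == t$seq_id & ssrs$start <= t$start &
                      ssrs$n_repeats >= t$n_repeats &
                      ssrs$canonical ==
                        famscan:::.canonical_rotation(t$unit)),
                label = paste("planted SSR", t$unit, "at", t$start))
  }
})

test_that("motif-free backgrounds scan clean", {
  cat_tab <- test_catalogue()
  sim <- plant_promoter_features(3, cat_tab, length = 1200, n_motifs = 0,
                                 n_ssrs = 0, seed = 55)
  expect_equal(nrow(scan_motifs(sim$promoters, cat_tab)), 0)
  expect_equal(nrow(find_ssrs(sim$promoters)), 0)
})

test_that("simulated counts carry the planted monotone stage trends", {
  cfg <- small_sim_config(seed = 61)
  cfg$expression$stage_effect_size <- 8
  expr <- simulate_counts(cfg, paste0("g", 1:200), seed = 61)
  tt <- tpm(expr$counts, expr$lengths)
  stages <- sub("_rep.*", "", colnames(tt))
  means <- sapply(unique(stages), function(s)
    rowMeans(tt[, stages == s, drop = FALSE]))
  down <- expr$trend$gene_id[expr$trend$trend == "down"]
  expect_gt(length(down), 0)
  frac_monotone <- mean(apply(means[down, , drop = FALSE], 1,
                              function(m) all(diff(m) < 0)))
  expect_gt(frac_monotone, 0.9)
  expect_identical(simulate_counts(cfg, paste0("g", 1:20), seed = 2)$counts,
                   simulate_counts(cfg, paste0("g", 1:20), seed = 2)$counts)
})
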