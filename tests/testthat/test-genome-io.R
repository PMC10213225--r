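test_that("FASTA reading keeps IDs to first whitespace, folds case, and round-trips", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">g1 some description", "ac", "gt", ">g2", "ACGTN"), p)
  seqs <- read_fasta(p, "DNA")
  expect_identical(names(seqs), c("g1", "g2"))
  expect_identical(unname(seqs[["g1"]]), "ACGT")
  p2 <- tempfile(fileext = ".fa")
  write_fasta(seqs, p2)
  expect_identical(as.character(read_fasta(p2, "DNA")), as.character(seqs))
})

test_that("FASTA parse errors are raised for duplicates, empties and bad characters", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">g1", "ACGT", ">g1", "GGTT"), p)
  expect_error(read_fasta(p, "DNA"), "duplicate")
  writeLines(character(0), p)
  expect_error(read_fasta(p, "DNA"), "FASTA")
  writeLines(c(">g1", "AC1T"), p)
  expect_error(read_fasta(p, "DNA"), "illegal|parse")
})

test_that("GFF3 coordinates convert to 0-based half-open and the longest isoform wins", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\tCDS\t1001\t1300\t.\t+\t0\tID=c1;Parent=g1.t1",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\tsrc\tCDS\t1001\t1600\t.\t+\t0\tID=c2;Parent=g1.t2"
  ), p)
  genome <- c(chr1 = strrep("A", 3000))
  m <- read_gff3(p, genome)
  expect_equal(m$start, 1000)
  expect_equal(m$end, 2000)
  expect_equal(m$end - m$start, 1000)
  expect_equal(sum(m$cds[[1]][, "end"] - m$cds[[1]][, "start"]), 600)
})

test_that("GFF3 referencing a chromosome absent from the genome errors with its name", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr9\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1",
    "chr9\tsrc\tCDS\t100\t399\t.\t+\t0\tID=c1;Parent=g1"
  ), p)
  expect_error(read_gff3(p, c(chr1 = "ACGT")), "chr9")
})

test_that("ranks are a 0-based permutation per chromosome with documented tie-breaks", {
  m <- make_models(data.frame(
    gene_id = c("x", "y", "z", "t1", "t2", "w"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(900, 100, 500, 100, 100, 700),
    end = c(1000, 200, 600, 300, 200, 800),
    strand = "+", stringsAsFactors = FALSE
  ))
  expect_equal(m$rank[m$gene_id == "y"], 0L)
  expect_equal(m$rank[m$gene_id == "z"], 1L)
  expect_equal(m$rank[m$gene_id == "x"], 2L)
  # equal starts: shorter end first
  expect_equal(m$rank[m$gene_id == "t2"], 0L)
  expect_equal(m$rank[m$gene_id == "t1"], 1L)
  expect_equal(m$rank[m$gene_id == "w"], 2L)
  for (ch in unique(m$chrom))
    expect_setequal(m$rank[m$chrom == ch], seq_len(sum(m$chrom == ch)) - 1L)
})

test_that("family renaming follows chromosome order, puts scaffolds last, and ignores input order", {
  m <- make_models(data.frame(
    gene_id = c("gA", "gB", "gC", "gS", "gD"),
    chrom = c("chr2", "chr1", "chr10", "scaffold_7", "chr12"),
    start = c(5000, 1000, 9000, 10, 50),
    end = c(5900, 1900, 9900, 900, 950),
    strand = "+", stringsAsFactors = FALSE
  ))
  n1 <- rename_family(m, c("gA", "gB", "gC", "gS", "gD"), prefix = "FAM")
  # natural order: chr1 < chr2 < chr10 < chr12, scaffold last
  expect_equal(n1$original_id, c("gB", "gA", "gC", "gD", "gS"))
  expect_equal(n1$family_name, paste0("FAM", 1:5))
  n2 <- rename_family(m, rev(c("gA", "gB", "gC", "gS", "gD")), "FAM")
  expect_equal(n1$family_name[match(n2$original_id, n1$original_id)],
               n2$family_name)
  expect_error(rename_family(m, "nope", "FAM"), "nope")
})

test_that("members within one chromosome are numbered by start coordinate", {
  m <- make_models(data.frame(
    gene_id = c("p", "q", "r"), chrom = "chr1",
    start = c(5000, 1000, 9000), end = c(5900, 1900, 9900),
    strand = "+", stringsAsFactors = FALSE
  ))
  n <- rename_family(m, c("p", "q", "r"), "X")
  expect_equal(n$original_id, c("q", "p", "r"))
})

test_that("CDS extraction honors strand and translation strips the trailing stop", {
  cds <- "ATGGCTTAA"
  genome <- c(chr1 = paste0("GGGG", cds, "CCCC"),
              chr2 = paste0("GGGG", revcomp(cds), "CCCC"))
  m <- make_models(data.frame(
    gene_id = c("plus", "minus"), chrom = c("chr1", "chr2"),
    start = 4, end = 13, strand = c("+", "-"), stringsAsFactors = FALSE
  ))
  xp <- extract_cds_and_protein(m, "plus", genome)
  xm <- extract_cds_and_protein(m, "minus", genome)
  expect_equal(unname(xp$cds), "ATGGCTTAA")
  expect_equal(unname(xp$protein), "MA")
  expect_equal(unname(xm$protein), unname(xp$protein))
  expect_error(translate_cds("ATGTAAGCT"), "internal stop")
  expect_error(translate_cds("ATGGC"), "divisible")
})

test_that("promoter extraction truncates at boundaries and respects strand", {
  chrom <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                 collapse = "")
  genome <- c(chr1 = chrom)
  m <- make_models(data.frame(
    gene_id = c("mid", "edge", "neg"), chrom = "chr1",
    start = c(5000, 1000, 3000), end = c(5500, 1500, 4000),
    strand = c("+", "+", "-"), stringsAsFactors = FALSE
  ))
  pm <- extract_promoter(m, "mid", genome)
  expect_equal(pm$length, 2000L)
  expect_false(pm$truncated)
  expect_equal(pm$seq, substr(chrom, 3001, 5000))
  pe <- extract_promoter(m, "edge", genome)
  expect_equal(pe$length, 1000L)
  expect_true(pe$truncated)
  expect_equal(pe$seq, substr(chrom, 1, 1000))
  pn <- extract_promoter(m, "neg", genome)
  expect_equal(pn$seq, revcomp(substr(chrom, 4001, 6000)))
})

test_that("a gene abutting the sequence edge yields an empty, flagged promoter", {
  genome <- c(chr1 = strrep("ACGT", 300))
  m <- make_models(data.frame(
    gene_id = "g0", chrom = "chr1", start = 0, end = 600, strand = "+",
    stringsAsFactors = FALSE
  ))
  p <- extract_promoter(m, "g0", genome)
  expect_equal(p$seq, "")
  expect_true(p$truncated)
})

test_that("every simulated CDS translates without internal stops", {
  sim <- simulate_genome(small_sim_config(seed = 11))
  for (g in sample(sim$models$gene_id, 20)) {
    x <- extract_cds_and_protein(sim$models, g, sim$genome)
    expect_gt(nchar(x$protein), 0)
  }
})
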