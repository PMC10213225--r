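# Fixture builders, all generated in code.

# Minimal gene-model table from (gene_id, chrom, start, end, strand);
# ranks assigned, CDS spanning the whole gene unless given.
make_models <- function(df) {
  df$strand <- if (is.null(df$strand)) "+" else df$strand
  df$is_placed <- !grepl("scaffold", df$chrom, ignore.case = TRUE)
  df$rank <- NA_integer_
  df$cds <- lapply(seq_len(nrow(df)), function(i)
    cbind(start = df$start[i], end = df$end[i]))
  assign_ranks(df)
}

# The 12-gene micro-genome used for classifier exactness: on chrA a
# tandem pair (a01,a02), a proximal pair at distance 7 (a04,a11), a
# dispersed partner a03 <-> b10 on chrB, a five-anchor collinear block
# a06..a10 <-> b01..b05, and two hit-less genes (a05, a12).
micro_genome <- function() {
  a <- sprintf("a%02d", 1:12)
  b <- sprintf("b%02d", 1:10)
  models <- make_models(data.frame(
    gene_id = c(a, b),
    chrom = c(rep("chrA", 12), rep("chrB", 10)),
    start = c(seq(1000, by = 5000, length.out = 12),
              seq(1000, by = 5000, length.out = 10)),
    end = c(seq(1900, by = 5000, length.out = 12),
            seq(1900, by = 5000, length.out = 10)),
    strand = "+", stringsAsFactors = FALSE
  ))
  pair <- function(q, s) data.frame(query = q, subject = s,
                                    evalue = 1e-30, bitscore = 100,
                                    stringsAsFactors = FALSE)
  hits <- rbind(
    pair("a01", "a02"),                      # tandem, rank distance 1
    pair("a04", "a11"),                      # proximal, rank distance 7
    pair("a03", "b10"),                      # dispersed, cross-chromosome
    pair("a06", "b01"), pair("a07", "b02"),  # 5-anchor block
    pair("a08", "b03"), pair("a09", "b04"), pair("a10", "b05"),
    pair("a06", "a07")                       # adjacent anchors: precedence
  )
  truth <- c(a01 = "tandem", a02 = "tandem", a03 = "dispersed",
             a04 = "proximal", a05 = "singleton",
             a06 = "wgd_or_segmental", a07 = "wgd_or_segmental",
             a08 = "wgd_or_segmental", a09 = "wgd_or_segmental",
             a10 = "wgd_or_segmental", a11 = "proximal",
             a12 = "singleton")
  list(models = models, hits = hits, truth = truth)
}

# A small, fast simulation configuration for pipeline-level tests.
small_sim_config <- function(seed) {
  simulation_config(
    seed = seed, n_chromosomes = 2L, genes_per_chromosome = 40L,
    cds_length_codons = 100L, intergenic_bp = 2100L,
    wgd = list(enabled = TRUE, event_ks = 1.2, retention = 0.4),
    n_tandem = 2L, n_proximal = 2L, n_dispersed = 3L
  )
}

# Default cis-element catalogue fixture (classic plant promoter motifs).
test_catalogue <- function() {
  data.frame(
    name = c("ABRE", "CGTCA-motif", "TGACG-motif", "GARE-motif", "P-box",
             "TATC-box", "AuxRR-core", "TGA-element", "GCN4-motif",
             "CAT-box", "LTR", "ARE", "WUN-motif", "O2-site"),
    pattern = c("ACGTGGC", "CGTCA", "TGACG", "TCTGTTG", "CCTTTTG",
                "TATCCCA", "GGTCCAT", "AACGAC", "TGAGTCA",
                "GCCACT", "CCGAAA", "AAACCA", "AAATTTCCT", "GATGAYRTGR"),
    category = c("abscisic acid responsiveness", "MeJA responsiveness",
                 "MeJA responsiveness", "gibberellin responsiveness",
                 "gibberellin responsiveness", "gibberellin responsiveness",
                 "auxin responsiveness", "auxin responsiveness",
                 "endosperm expression", "meristem expression",
                 "low-temperature responsiveness", "anaerobic induction",
                 "wound responsiveness", "zein metabolism regulation"),
    stringsAsFactors = FALSE
  )
}

write_tmp_fasta <- function(seqs, dir = tempdir()) {
  path <- tempfile("seq", fileext = ".fa", tmpdir = dir)
  write_fasta(seqs, path)
  path
}
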