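# Ground-truthed input simulator.
#
# A multi-chromosome genome with planted duplication events of known type,
# age (Ks) and selection (omega): a whole-genome duplication is applied
# first (duplicating every chromosome and fractionating each copy
# independently), then tandem, proximal and dispersed copies are inserted,
# so small-scale copies of WGD survivors exist and the classifier's
# precedence order is exercised.  Every generator is a pure function of
# (config, seed).

.SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), .STOP_CODONS)

#' Simulation configuration
#'
#' Defaults define the package's reference simulation: 4 chromosomes of
#' 250 genes, a WGD at Ks 1.2 with retention fraction 0.3, 15 tandem, 15
#' proximal and 30 dispersed duplication events, 300-codon CDS evolved
#' under purifying selection (omega 0.2), and a 3-stage x 3-replicate
#' count matrix.
#'
#' @param seed mandatory RNG seed.
#' @param n_chromosomes number of ancestral chromosomes.
#' @param genes_per_chromosome ancestral genes per chromosome.
#' @param cds_length_codons sense codons per CDS (a stop codon is added).
#' @param intergenic_bp spacer between genes (>= promoter length keeps
#'   promoters untruncated).
#' @param wgd list `enabled`, `event_ks`, `retention`.
#' @param n_tandem,n_proximal,n_dispersed small-scale event counts.
#' @param tandem_ks,proximal_ks,dispersed_ks mean event ages (Ks).
#' @param omega nonsynonymous/synonymous rate ratio for evolved copies.
#' @param ks_jitter relative half-width of the per-event Ks draw
#'   (`ks ~ U((1-j) m, (1+j) m)`).
#' @param noise_rate spurious hits per gene emitted by [make_hits()].
#' @param expression list `n_stages`, `n_reps`, `stage_effect_size`,
#'   `dispersion`, `trend_fraction`.
#' @return config list (class `famscan_sim_config`).
#' @export
simulation_config <- function(seed,
                              n_chromosomes = 4L,
                              genes_per_chromosome = 250L,
                              cds_length_codons = 300L,
                              intergenic_bp = 2200L,
                              wgd = list(enabled = TRUE, event_ks = 1.2,
                                         retention = 0.3),
                              n_tandem = 15L, n_proximal = 15L,
                              n_dispersed = 30L,
                              tandem_ks = 0.15, proximal_ks = 0.3,
                              dispersed_ks = 0.6,
                              omega = 0.2, ks_jitter = 0.1,
                              noise_rate = 0.05,
                              expression = list(n_stages = 3L, n_reps = 3L,
                                                stage_effect_size = 4,
                                                dispersion = 0.1,
                                                trend_fraction = 0.2)) {
  if (missing(seed)) stop("simulation seed is mandatory")
  stopifnot(wgd$retention > 0, wgd$retention <= 1,
            omega > 0, ks_jitter >= 0, ks_jitter < 1)
  structure(as.list(environment()), class = "famscan_sim_config")
}

.random_cds <- function(n_codons) {
  body <- sample(.SENSE_CODONS, n_codons - 1L, replace = TRUE)
  paste(c("ATG", body), collapse = "")
}

.random_dna <- function(n) {
  paste(sample(.DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Evolve a CDS to a target synonymous divergence
#'
#' Codon-level substitution process: single-base changes are proposed
#' uniformly; synonymous changes are accepted with relative rate 1,
#' nonsynonymous with rate `omega`, and stop-creating changes rejected.
#' The process runs until the number of accepted synonymous substitutions
#' reaches `target_ks` times the ancestor's NG86 synonymous site count, so
#' the expected NG86 Ks of (ancestor, output) is `target_ks`.
#'
#' @param cds stop-free in-frame CDS.
#' @param target_ks target synonymous substitutions per synonymous site
#'   (>= 0).
#' @param omega relative acceptance rate of nonsynonymous changes.
#' @param seed optional seed for a self-contained deterministic call.
#' @return the mutated CDS string.
#' @export
evolve_cds <- function(cds, target_ks, omega, seed = NULL) {
  if (target_ks < 0) stop("target_ks must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (target_ks == 0) return(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  if (any(codons %in% .STOP_CODONS)) stop("CDS contains a stop codon")
  S <- sum(vapply(codons, .syn_sites, numeric(1)))
  needed <- target_ks * S
  syn_count <- 0
  while (syn_count < needed) {
    ci <- sample.int(length(codons), 1L)
    pos <- sample.int(3L, 1L)
    old <- codons[ci]
    b <- substr(old, pos, pos)
    alt <- sample(setdiff(.DNA_BASES, b), 1L)
    new <- old
    substr(new, pos, pos) <- alt
    if (new %in% .STOP_CODONS) next
    if (.codon_aa(new) == .codon_aa(old)) {
      codons[ci] <- new
      syn_count <- syn_count + 1
    } else if (runif(1) < omega) {
      codons[ci] <- new
    }
  }
  paste(codons, collapse = "")
}

.draw_ks <- function(mean_ks, jitter) {
  mean_ks * runif(1, 1 - jitter, 1 + jitter)
}

#' Simulate a genome with planted duplication events
#'
#' See [simulation_config()] for the event model.  The WGD duplicates
#' every chromosome (copies named after the ancestral count), deletes each
#' duplicated gene independently with probability `1 - retention`, and
#' evolves survivors to the event Ks.  Tandem copies are inserted at the
#' adjacent rank, proximal copies at a uniform rank offset in 2..19,
#' dispersed copies on a different chromosome.  Insertions are never
#' placed inside a previously planted pair, so recorded geometries stay
#' valid.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (named character vector), `models`
#'   (gene-model data.frame with ranks), `truth` (data.frame `gene_id`,
#'   `true_label`, `parent`, `event_ks`, `omega`), and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "famscan_sim_config"))
  set.seed(config$seed)
  nchr <- config$n_chromosomes
  npg <- config$genes_per_chromosome

  cds_of <- new.env(parent = emptyenv())
  chrom_genes <- list()   # chromosome name -> ordered gene id vector
  truth <- list()
  add_truth <- function(gene, label, parent = NA_character_,
                        ks = NA_real_, omega = NA_real_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      gene_id = gene, true_label = label, parent = parent,
      event_ks = ks, omega = omega, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nchr)) {
    ids <- sprintf("g%d_%03d", i, seq_len(npg))
    for (g in ids) assign(g, .random_cds(config$cds_length_codons), cds_of)
    chrom_genes[[paste0("chr", i)]] <- ids
  }

  # whole-genome duplication first, fractionating each duplicate
  if (isTRUE(config$wgd$enabled)) {
    for (i in seq_len(nchr)) {
      parent_chr <- paste0("chr", i)
      dup_chr <- paste0("chr", i + nchr)
      retained <- chrom_genes[[parent_chr]][
        runif(npg) < config$wgd$retention]
      copies <- character(0)
      for (p in retained) {
        ks <- .draw_ks(config$wgd$event_ks, config$ks_jitter)
        cp <- paste0(p, "w")
        assign(cp, evolve_cds(get(p, cds_of), ks, config$omega), cds_of)
        add_truth(cp, "wgd", p, ks, config$omega)
        copies <- c(copies, cp)
      }
      chrom_genes[[dup_chr]] <- copies
    }
  }

  # Small-scale events.  The only geometric hazard is an insertion landing
  # strictly inside a previously planted tandem/proximal pair, which would
  # change that pair's rank distance; such spans are recorded (anchored to
  # gene IDs, so rank shifts cannot invalidate them) and insertions inside
  # them rejected.
  spans <- list()   # chromosome -> list of c(left_id, right_id)
  inside_span <- function(chr, insert_at) {
    for (sp in spans[[chr]]) {
      li <- match(sp[1L], chrom_genes[[chr]])
      ri <- match(sp[2L], chrom_genes[[chr]])
      if (li < insert_at && insert_at <= ri) return(TRUE)
    }
    FALSE
  }
  schedule <- c(rep("tandem", config$n_tandem),
                rep("proximal", config$n_proximal),
                rep("dispersed", config$n_dispersed))
  mean_ks <- c(tandem = config$tandem_ks, proximal = config$proximal_ks,
               dispersed = config$dispersed_ks)
  suffix <- c(tandem = "t", proximal = "p", dispersed = "d")
  for (ev in schedule) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      # parent uniform over genes, so event density follows gene density
      sizes <- lengths(chrom_genes)
      chr <- sample(names(chrom_genes), 1L, prob = sizes / sum(sizes))
      genes <- chrom_genes[[chr]]
      if (length(genes) < 21L) next
      pi_ <- sample.int(length(genes), 1L)
      parent <- genes[pi_]
      cp <- paste0(parent, suffix[[ev]])
      if (exists(cp, cds_of)) next     # one copy of a kind per parent
      if (ev == "dispersed") {
        others <- setdiff(names(chrom_genes), chr)
        others <- others[vapply(others, function(x)
          length(chrom_genes[[x]]) >= 21L, logical(1))]
        if (length(others) == 0L) next
        insert_chr <- sample(others, 1L)
        insert_at <- sample.int(length(chrom_genes[[insert_chr]]) + 1L, 1L)
        if (inside_span(insert_chr, insert_at)) next
      } else {
        offset <- if (ev == "tandem") 1L else sample(2:19, 1L)
        insert_at <- pi_ + offset
        if (insert_at > length(genes) + 1L) next
        if (inside_span(chr, insert_at)) next
        insert_chr <- chr
      }
      ks <- .draw_ks(mean_ks[[ev]], config$ks_jitter)
      assign(cp, evolve_cds(get(parent, cds_of), ks, config$omega), cds_of)
      add_truth(cp, ev, parent, ks, config$omega)
      chrom_genes[[insert_chr]] <- append(chrom_genes[[insert_chr]], cp,
                                          after = insert_at - 1L)
      if (ev != "dispersed") {
        spans[[chr]] <- c(spans[[chr]],
                          list(if (insert_at > pi_) c(parent, cp)
                               else c(cp, parent)))
      }
      placed <- TRUE
      break
    }
    if (!placed) stop("simulate_genome: could not place a ", ev,
                      " event; config infeasible")
  }

  # lay genes onto sequences: spacer + CDS per gene, trailing spacer
  genome <- character(0)
  rows <- list()
  for (chr in names(chrom_genes)) {
    pieces <- character(0)
    pos <- 0L
    for (g in chrom_genes[[chr]]) {
      spacer <- .random_dna(config$intergenic_bp)
      cds <- get(g, cds_of)
      cds_stop <- paste0(cds, "TAA")
      strand <- sample(c("+", "-"), 1L)
      placed_seq <- if (strand == "+") cds_stop else revcomp(cds_stop)
      start <- pos + config$intergenic_bp
      end <- start + nchar(cds_stop)
      pieces <- c(pieces, spacer, placed_seq)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, chrom = chr, start = start, end = end,
        strand = strand, stringsAsFactors = FALSE)
      pos <- end
    }
    pieces <- c(pieces, .random_dna(config$intergenic_bp))
    genome[[chr]] <- paste(pieces, collapse = "")
  }
  models <- do.call(rbind, rows)
  models$is_placed <- TRUE
  models$rank <- NA_integer_
  models$cds <- lapply(seq_len(nrow(models)), function(i)
    cbind(start = models$start[i], end = models$end[i]))
  models <- assign_ranks(models)

  truth_df <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(gene_id = character(0), true_label = character(0),
               parent = character(0), event_ks = numeric(0),
               omega = numeric(0), stringsAsFactors = FALSE)
  ancestral <- setdiff(models$gene_id, truth_df$gene_id)
  truth_df <- rbind(truth_df, data.frame(
    gene_id = ancestral, true_label = "singleton", parent = NA_character_,
    event_ks = NA_real_, omega = NA_real_, stringsAsFactors = FALSE))
  truth_df <- truth_df[match(models$gene_id, truth_df$gene_id), ]
  rownames(truth_df) <- NULL

  attr(genome, "alphabet") <- "DNA"
  list(genome = genome, models = models, truth = truth_df, config = config)
}

#' Emit a homology hit table from simulation truth
#'
#' Every (parent, copy) pair from the truth is emitted in both directions
#' with E-value 1e-30 and a bitscore decreasing in the event Ks; spurious
#' pairs are added at E-values at or above 1e-5, which the strict
#' `evalue < 1e-5` filter removes.
#'
#' @param truth truth data.frame from [simulate_genome()].
#' @param gene_ids all gene IDs (for drawing noise pairs).
#' @param noise_rate expected spurious hits per gene.
#' @param seed optional RNG seed.
#' @return hit data.frame `query`, `subject`, `evalue`, `bitscore`.
#' @export
make_hits <- function(truth, gene_ids, noise_rate = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tp <- truth[!is.na(truth$parent), , drop = FALSE]
  hits <- data.frame(
    query = c(tp$parent, tp$gene_id),
    subject = c(tp$gene_id, tp$parent),
    evalue = 1e-30,
    bitscore = round(500 * exp(-c(tp$event_ks, tp$event_ks)), 1),
    stringsAsFactors = FALSE
  )
  n_noise <- round(noise_rate * length(gene_ids))
  if (n_noise > 0L) {
    q <- sample(gene_ids, n_noise, replace = TRUE)
    s <- sample(gene_ids, n_noise, replace = TRUE)
    true_key <- c(paste(hits$query, hits$subject),
                  paste(hits$subject, hits$query))
    keep <- q != s & !(paste(q, s) %in% true_key)
    hits <- rbind(hits, data.frame(
      query = q[keep], subject = s[keep],
      evalue = 10^runif(sum(keep), -5, -2),
      bitscore = round(runif(sum(keep), 30, 60), 1),
      stringsAsFactors = FALSE))
  }
  rownames(hits) <- NULL
  hits
}

#' Generate motif-free promoters and plant motifs and SSRs into them
#'
#' Backgrounds are rejection-sampled until they contain no catalogue match
#' on either strand and no SSR at the given thresholds, making recall
#' assertions exact.  Motif instances (concrete sequences drawn from the
#' IUPAC pattern) and SSR runs are then inserted at recorded,
#' non-overlapping positions.
#'
#' @param n number of promoters.
#' @param catalogue motif catalogue.
#' @param length promoter length in bp.
#' @param n_motifs motifs planted per promoter.
#' @param ssr_units character vector of SSR units to draw from.
#' @param n_ssrs SSRs planted per promoter.
#' @param ssr_repeats repeat count for planted SSRs.
#' @param min_repeats SSR thresholds used for background rejection.
#' @param seed optional RNG seed.
#' @return list with `promoters` (named character vector), `motif_truth`
#'   (`seq_id`, `motif`, `start`, `strand`, `instance`) and `ssr_truth`
#'   (`seq_id`, `unit`, `n_repeats`, `start`).
#' @export
plant_promoter_features <- function(n, catalogue, length = 2000L,
                                    n_motifs = 5L,
                                    ssr_units = c("AT", "AG", "AAG", "ATC"),
                                    n_ssrs = 1L, ssr_repeats = 7L,
                                    min_repeats = c(`1` = 10L, `2` = 6L,
                                                    `3` = 5L, `4` = 5L,
                                                    `5` = 5L, `6` = 5L),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_catalogue(catalogue)
  max_insert <- max(nchar(catalogue$pattern),
                    nchar(ssr_units) * ssr_repeats)
  need_bp <- (n_motifs + n_ssrs) * (max_insert + 20L)
  if (length < need_bp)
    stop("promoter length ", length, " too short for requested insertions")
  clean_background <- function() {
    s <- .random_dna(length)
    for (round in seq_len(50L)) {
      hits <- scan_motifs(setNames(s, "x"), catalogue)
      ssrs <- find_ssrs(setNames(s, "x"), min_repeats)
      if (nrow(hits) == 0L && nrow(ssrs) == 0L) return(s)
      bad <- rbind(hits[, c("start", "end")], ssrs[, c("start", "end")])
      for (k in seq_len(nrow(bad))) {
        w <- bad$end[k] - bad$start[k]
        substr(s, bad$start[k] + 1L, bad$end[k]) <- .random_dna(w)
      }
    }
    stop("could not rejection-sample a clean background")
  }
  instantiate <- function(pattern) {
    paste(vapply(strsplit(pattern, "")[[1]],
                 function(cc) sample(.IUPAC_DNA[[cc]], 1L), character(1)),
          collapse = "")
  }
  promoters <- character(n)
  names(promoters) <- sprintf("prom%03d", seq_len(n))
  mt <- list(); st <- list()
  for (i in seq_len(n)) {
    s <- clean_background()
    occupied <- matrix(numeric(0), ncol = 2)
    place <- function(w) {
      for (try in seq_len(500L)) {
        st0 <- sample.int(length - w + 1L, 1L) - 1L  # 0-based
        lo <- st0 - 10L; hi <- st0 + w + 10L
        if (nrow(occupied) == 0L ||
            all(hi <= occupied[, 1] | lo >= occupied[, 2])) {
          occupied <<- rbind(occupied, c(lo, hi))
          return(st0)
        }
      }
      stop("could not place an insertion")
    }
    midx <- sample.int(nrow(catalogue), n_motifs, replace = TRUE)
    for (m in midx) {
      inst <- instantiate(catalogue$pattern[m])
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") inst else revcomp(inst)
      st0 <- place(nchar(ins))
      substr(s, st0 + 1L, st0 + nchar(ins)) <- ins
      mt[[length(mt) + 1L]] <- data.frame(
        seq_id = names(promoters)[i], motif = catalogue$name[m],
        start = st0, strand = strand, instance = inst,
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_ssrs)) {
      unit <- sample(ssr_units, 1L)
      run <- strrep(unit, ssr_repeats)
      st0 <- place(nchar(run))
      substr(s, st0 + 1L, st0 + nchar(run)) <- run
      st[[length(st) + 1L]] <- data.frame(
        seq_id = names(promoters)[i], unit = unit,
        n_repeats = ssr_repeats, start = st0, stringsAsFactors = FALSE)
    }
    promoters[i] <- s
  }
  list(promoters = promoters,
       motif_truth = do.call(rbind, mt),
       ssr_truth = do.call(rbind, st))
}

#' Simulate a stage-series count matrix
#'
#' Negative-binomial counts with gene-specific baseline means; genes
#' tagged "up" or "down" get monotone stage multipliers reaching
#' `stage_effect_size`; transcript lengths are uniform in 600..3000 bp.
#'
#' @param config a [simulation_config()] (its `expression` element is
#'   used).
#' @param gene_ids genes to simulate.
#' @param seed optional RNG seed.
#' @return list with `counts` (genes x samples matrix, columns
#'   `stage<s>_rep<r>`), `lengths` (named vector) and `trend`
#'   (data.frame `gene_id`, `trend`).
#' @export
simulate_counts <- function(config, gene_ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- config$expression
  n <- length(gene_ids)
  trend <- sample(c("up", "down", "flat"), n, replace = TRUE,
                  prob = c(e$trend_fraction / 2, e$trend_fraction / 2,
                           1 - e$trend_fraction))
  base <- exp(rnorm(n, log(100), 1))
  lengths <- setNames(round(runif(n, 600, 3000)), gene_ids)
  S <- e$n_stages; R <- e$n_reps
  E <- e$stage_effect_size
  cols <- as.vector(outer(seq_len(R), seq_len(S), function(r, s)
    sprintf("stage%d_rep%d", s, r)))
  counts <- matrix(0, nrow = n, ncol = S * R,
                   dimnames = list(gene_ids, cols))
  for (s in seq_len(S)) {
    mult <- ifelse(trend == "up", E^((s - 1) / (S - 1)),
                   ifelse(trend == "down", E^(-(s - 1) / (S - 1)), 1))
    for (r in seq_len(R)) {
      mu <- base * mult
      counts[, sprintf("stage%d_rep%d", s, r)] <-
        rnbinom(n, mu = mu, size = 1 / e$dispersion)
    }
  }
  list(counts = counts, lengths = lengths,
       trend = data.frame(gene_id = gene_ids, trend = trend,
                          stringsAsFactors = FALSE))
}

#' Write a gene-model data.frame as GFF3
#'
#' Emits gene, mRNA and CDS features, converting internal 0-based
#' half-open coordinates back to GFF3 1-based inclusive.
#'
#' @param models gene-model data.frame.
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    line <- function(type, st, en, attrs)
      paste(g$chrom, "famscan", type, st + 1L, en, ".", g$strand, ".",
            attrs, sep = "\t")
    writeLines(line("gene", g$start, g$end,
                    paste0("ID=", g$gene_id)), con)
    writeLines(line("mRNA", g$start, g$end,
                    paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id)),
               con)
    cds <- g$cds[[1L]]
    for (j in seq_len(nrow(cds)))
      writeLines(line("CDS", cds[j, 1L], cds[j, 2L],
                      paste0("ID=", g$gene_id, ".cds;Parent=",
                             g$gene_id, ".t1")), con)
  }
  invisible(path)
}

#' Write all simulation inputs to a directory
#'
#' Emits the exact formats the pipeline consumes: `genome.fa`,
#' `annotation.gff3`, `hits.tsv`, `members.txt` (all planted duplicates
#' plus a sample of ancestral genes), `counts.tsv`, `lengths.tsv`, and
#' `truth.tsv`.
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if needed).
#' @param noise_rate passed to [make_hits()].
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(sim, dir, noise_rate = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gff3(sim$models, file.path(dir, "annotation.gff3"))
  hits <- make_hits(sim$truth, sim$models$gene_id, noise_rate)
  write.table(hits, file.path(dir, "hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  members <- sim$truth$gene_id[sim$truth$true_label != "singleton"]
  writeLines(members, file.path(dir, "members.txt"))
  expr <- simulate_counts(sim$config, sim$models$gene_id)
  counts <- data.frame(gene_id = rownames(expr$counts), expr$counts,
                       check.names = FALSE)
  write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = names(expr$lengths),
                         length = unname(expr$lengths)),
              file.path(dir, "lengths.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
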