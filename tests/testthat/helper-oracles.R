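# Independent brute-force oracles, written before and apart from the
# implementation paths they check.

.oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})
.oracle_stops <- names(.oracle_code)[.oracle_code == "*"]
.oracle_sense <- setdiff(names(.oracle_code), .oracle_stops)

# NG86 synonymous site count of one codon: enumerate the 9 single-base
# changes position by position; changes to stop codons leave the
# denominator.
oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    syn <- 0; denom <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (mut %in% .oracle_stops) next
      denom <- denom + 1
      if (.oracle_code[[mut]] == .oracle_code[[codon]]) syn <- syn + 1
    }
    if (denom > 0) total <- total + syn / denom
  }
  total
}

# NG86 difference counts between two sense codons: depth-first search over
# all orders of applying the differing positions; paths through stop
# intermediates dropped (all paths used when every one is blocked).
oracle_codon_diffs <- function(c1, c2) {
  walk <- function(cur, remaining, syn, non, allow_stop) {
    if (length(remaining) == 0) return(list(c(syn, non)))
    out <- list()
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (!allow_stop && nxt %in% .oracle_stops && nxt != c2) next
      step_syn <- .oracle_code[[cur]] == .oracle_code[[nxt]]
      out <- c(out, walk(nxt, setdiff(remaining, pos),
                         syn + step_syn, non + !step_syn, allow_stop))
    }
    out
  }
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  paths <- walk(c1, pos, 0, 0, allow_stop = FALSE)
  if (length(paths) == 0) paths <- walk(c1, pos, 0, 0, allow_stop = TRUE)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# Exhaustive chain search: every valid monotone chain over <= ~12 anchors
# by DFS extension, scored as match_score per anchor minus gap_penalty per
# skipped rank step.
oracle_best_chain_score <- function(rank_a, rank_b, orientation,
                                    max_gap = 25, match_score = 50,
                                    gap_penalty = 1) {
  n <- length(rank_a)
  if (n == 0) return(-Inf)
  best <- -Inf
  extend <- function(last, score) {
    best <<- max(best, score)
    for (i in seq_len(n)) {
      if (rank_a[i] <= rank_a[last]) next
      ok <- if (orientation == "same") rank_b[i] > rank_b[last]
            else rank_b[i] < rank_b[last]
      if (!ok) next
      ga <- rank_a[i] - rank_a[last] - 1
      gb <- abs(rank_b[i] - rank_b[last]) - 1
      if (ga > max_gap || gb > max_gap) next
      extend(i, score + match_score - gap_penalty * (ga + gb))
    }
  }
  for (i in seq_len(n)) extend(i, match_score)
  best
}

# Exhaustive global alignment score: enumerate every alignment as an
# operation sequence with affine gap bookkeeping (gap of length L costs
# open + L * extend).
oracle_align_score <- function(a, b, mat, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    s <- -Inf
    if (i <= length(av) && j <= length(bv))
      s <- max(s, mat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(av)) {
      cost <- if (last == "D") gap_extend else gap_open + gap_extend
      s <- max(s, -cost + rec(i + 1, j, "D"))
    }
    if (j <= length(bv)) {
      cost <- if (last == "I") gap_extend else gap_open + gap_extend
      s <- max(s, -cost + rec(i, j + 1, "I"))
    }
    s
  }
  rec(1, 1, "M")
}

# Dense pH-grid scan for the isoelectric point, with its own charge
# formula over the package's pKa set.
oracle_pi_grid <- function(seq, step = 0.001) {
  chars <- strsplit(seq, "")[[1]]
  ph <- seq(0, 14, by = step)
  pos_groups <- c(famscan:::.PKA_SIDE_POS,
                  n = unname(ifelse(chars[1] %in% names(famscan:::.PKA_NTERM),
                                    famscan:::.PKA_NTERM[chars[1]],
                                    famscan:::.PKA_NTERM_DEFAULT)))
  pos_counts <- c(sum(chars == "H"), sum(chars == "K"), sum(chars == "R"), 1)
  neg_groups <- c(famscan:::.PKA_SIDE_NEG, c = famscan:::.PKA_CTERM)
  neg_counts <- c(sum(chars == "D"), sum(chars == "E"),
                  sum(chars == "C"), sum(chars == "Y"), 1)
  charge <- rep(0, length(ph))
  for (k in seq_along(pos_groups))
    charge <- charge + pos_counts[k] / (1 + 10^(ph - pos_groups[k]))
  for (k in seq_along(neg_groups))
    charge <- charge - neg_counts[k] / (1 + 10^(neg_groups[k] - ph))
  ph[which.min(abs(charge))]
}

# Sliding-window SSR oracle: for every start and unit length, take the
# maximal run, then filter by threshold, unit periodicity and overlap
# (left-to-right within a unit-length class).
oracle_ssrs <- function(seq, min_repeats = c(`1` = 10, `2` = 6, `3` = 5,
                                             `4` = 5, `5` = 5, `6` = 5)) {
  L <- nchar(seq)
  recs <- list()
  for (ul in as.integer(names(min_repeats))) {
    need <- min_repeats[[as.character(ul)]]
    covered_until <- 0
    start <- 1
    while (start + ul - 1 <= L) {
      if (start <= covered_until) { start <- start + 1; next }
      unit <- substr(seq, start, start + ul - 1)
      smallest <- ul
      for (p in seq_len(ul - 1))
        if (ul %% p == 0 &&
            strrep(substr(unit, 1, p), ul / p) == unit) {
          smallest <- p; break
        }
      if (grepl("[^ACGT]", unit) || smallest < ul) {
        start <- start + 1; next
      }
      reps <- 1
      while (start + (reps + 1) * ul - 1 <= L &&
             substr(seq, start + reps * ul,
                    start + (reps + 1) * ul - 1) == unit)
        reps <- reps + 1
      if (reps >= need) {
        recs[[length(recs) + 1]] <- data.frame(
          unit = unit, n_repeats = reps, start = start - 1,
          end = start - 1 + reps * ul, stringsAsFactors = FALSE)
        covered_until <- start + reps * ul - 1
        start <- start + reps * ul
      } else start <- start + 1
    }
  }
  if (length(recs) == 0)
    return(data.frame(unit = character(0), n_repeats = integer(0),
                      start = integer(0), end = integer(0)))
  out <- do.call(rbind, recs)
  out[order(out$start, nchar(out$unit)), ]
}
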