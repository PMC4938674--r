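# Independent brute-force oracles used by module tests and the
# end-to-end checks. Each is written as the most literal possible
# restatement of the rule it verifies, with no code shared with the
# implementation.

# the default study geometry: 300 kb region, 170 kb and 70 kb deletions
default_model <- function(seed = 1, n_snps = 200L) {
  build_region_model(region_length = 300000L, del1_span = 170000L,
                     del2_span = 70000L, n_snps = n_snps, seed = seed)
}

# a 21-member all-wild-type control pool at 56X, the study's design
wt_pool_spec <- function(n_members = 21L, coverage = 56) {
  sample_spec("pool", mean_coverage = coverage,
              pool_members = rep(list(c("WT", "WT")), n_members))
}

# literal three-condition screen filter, one site at a time
oracle_screen_site <- function(case_ref, case_alt, pool_ref, pool_alt,
                               min_covered_cases = 1L, min_case_depth = 1L) {
  pool_ok <- (pool_ref + pool_alt) >= 1 && pool_alt == 0
  covered <- which(case_ref + case_alt >= min_case_depth)
  cases_ok <- length(covered) >= 1
  for (i in covered) if (case_ref[i] != 0) cases_ok <- FALSE
  pool_ok && cases_ok && length(covered) >= min_covered_cases
}

# literal merge-rule scan for deletion segments over window states
oracle_segments <- function(cn, windows, max_gap = 2L, min_win = 3L,
                            rules = cn_state_ranges()) {
  state <- character(length(cn))
  for (i in seq_along(cn)) {
    x <- cn[i]
    state[i] <- if (is.na(x)) "undefined"
    else if (x < rules$zero_max) "0"
    else if (x >= rules$one[1] && x <= rules$one[2]) "1"
    else if (x >= rules$two[1] && x <= rules$two[2]) "2"
    else "ambiguous"
  }
  out <- NULL
  for (s in c("0", "1")) {
    i <- 1L
    while (i <= length(state)) {
      if (state[i] != s) { i <- i + 1L; next }
      # extend: accept more s-windows separated by short bridgeable gaps
      members <- i
      j <- i + 1L
      gap <- 0L
      last <- i
      while (j <= length(state)) {
        if (state[j] == s) {
          members <- c(members, j); last <- j; gap <- 0L
        } else if (state[j] %in% c("ambiguous", "undefined")) {
          gap <- gap + 1L
          if (gap > max_gap) break
        } else break
        j <- j + 1L
      }
      if (length(members) >= min_win)
        out <- rbind(out, data.frame(
          start = windows$start[members[1]], end = windows$end[last],
          state = as.integer(s), mean_cn = mean(cn[members]),
          n_windows = length(members)))
      i <- last + 1L
    }
  }
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      state = integer(0), mean_cn = numeric(0),
                      n_windows = integer(0)))
  out[order(out$start), , drop = FALSE]
}

# naive quadratic tandem-run scanner, leftmost-greedy whole copies
oracle_motif_runs <- function(seq, motif, min_len) {
  n <- nchar(seq); m <- nchar(motif)
  runs <- NULL
  i <- 1L
  while (i <= n - m + 1L) {
    copies <- 0L
    while (substr(seq, i + copies * m, i + (copies + 1L) * m - 1L) == motif)
      copies <- copies + 1L
    if (copies > 0L) {
      if (copies * m >= min_len)
        runs <- rbind(runs, data.frame(start = i - 1L,
                                       end = i - 1L + copies * m,
                                       copies = copies))
      i <- i + copies * m
    } else i <- i + 1L
  }
  if (is.null(runs))
    data.frame(start = integer(0), end = integer(0), copies = integer(0))
  else runs
}

# gene counting by explicit haplotype expansion
oracle_allele_freqs <- function(counts) {
  alleles <- character(0)
  for (g in names(counts)) {
    pair <- strsplit(g, "/", fixed = TRUE)[[1]]
    alleles <- c(alleles, rep(pair, counts[[g]]))
  }
  c(del1 = sum(alleles == "Del1") / length(alleles),
    del2 = sum(alleles == "Del2") / length(alleles),
    wt = sum(alleles == "WT") / length(alleles))
}

# the genotype composition of the 94-pony random set
random_set_genotypes <- function() {
  c(rep("Del1/WT", 9), rep("Del2/WT", 2), rep("WT/WT", 83))
}

random_set_genotype_list <- function() {
  g <- c(rep(list(c("Del1", "WT")), 9), rep(list(c("Del2", "WT")), 2),
         rep(list(c("WT", "WT")), 83))
  names(g) <- sprintf("rs%02d", seq_along(g))
  g
}
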