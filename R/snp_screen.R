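#' Alternate-allele frequency at one site
#'
#' `alt / (ref + alt)`; `NaN` (undefined) when the site has no reads.
#'
#' @param ref_count,alt_count Non-negative read counts (vectorized).
#' @return Numeric frequency in \[0, 1\], `NaN` at zero depth.
#' @export
site_allele_frequency <- function(ref_count, alt_count) {
  if (any(ref_count < 0) || any(alt_count < 0))
    stop("read counts must be >= 0")
  depth <- ref_count + alt_count
  ifelse(depth > 0, alt_count / depth, NaN)
}

#' Fixed allele-frequency-difference screen, cases versus control pool
#'
#' Flags SNP sites where individually sequenced cases and the pooled
#' controls are fixed for opposite alleles: the pool must carry only
#' reference reads (with at least one read), and every *covered* case
#' (depth >= `min_case_depth`) must carry only alternate reads. Cases
#' with no coverage at a site do not disqualify it — at the causal locus
#' hemizygous cases are readable while homozygous-deleted cases have no
#' reads at all — but at least `min_covered_cases` cases must be
#' covered.
#'
#' `max_discordant_reads` (default 0, i.e. exact fixation) optionally
#' tolerates up to that many opposite-allele reads on each side, for
#' noisy inputs.
#'
#' @param table SNP count table: data.frame with `sample_id`, `pos`,
#'   `ref_count`, `alt_count` (long format, one row per sample/site).
#' @param case_ids Character vector of case sample ids.
#' @param pool_id Pool sample id.
#' @param min_covered_cases Minimum number of covered cases (default 1).
#' @param min_case_depth Depth at which a case counts as covered
#'   (default 1).
#' @param max_discordant_reads Discordant reads tolerated per sample
#'   (default 0).
#' @return data.frame of class `screen_result` with one row per site:
#'   `pos`, `case_alt_frequency` (mean over covered cases, `NaN` if
#'   none), `pool_alt_frequency`, `n_cases_covered`, `passes`.
#' @examples
#' tab <- data.frame(
#'   sample_id = c("c1", "c2", "pool"), pos = 100L,
#'   ref_count = c(0L, 0L, 50L), alt_count = c(6L, 7L, 0L))
#' fixed_difference_screen(tab, c("c1", "c2"), "pool")
#' @export
fixed_difference_screen <- function(table, case_ids, pool_id,
                                    min_covered_cases = 1L,
                                    min_case_depth = 1L,
                                    max_discordant_reads = 0L) {
  stopifnot(all(c("sample_id", "pos", "ref_count", "alt_count") %in%
                  names(table)))
  if (length(case_ids) < 1L) stop("need >= 1 case")
  known <- unique(table$sample_id)
  missing <- setdiff(c(case_ids, pool_id), known)
  if (length(missing) > 0L)
    stop("unknown sample ids: ", paste(missing, collapse = ", "))

  positions <- sort(unique(table$pos))
  samples <- c(case_ids, pool_id)
  # positions x samples count matrices; absent rows count as depth 0
  ref <- matrix(0L, length(positions), length(samples),
                dimnames = list(NULL, samples))
  alt <- ref
  keep <- table$sample_id %in% samples
  ri <- match(table$pos[keep], positions)
  ci <- match(table$sample_id[keep], samples)
  ref[cbind(ri, ci)] <- table$ref_count[keep]
  alt[cbind(ri, ci)] <- table$alt_count[keep]

  pool_depth <- ref[, pool_id] + alt[, pool_id]
  pool_af <- ifelse(pool_depth > 0, alt[, pool_id] / pool_depth, NaN)
  cref <- ref[, case_ids, drop = FALSE]
  calt <- alt[, case_ids, drop = FALSE]
  cdepth <- cref + calt
  covered <- cdepth >= min_case_depth
  n_cov <- rowSums(covered)
  case_af <- ifelse(n_cov > 0,
                    rowSums(ifelse(covered, calt / pmax(cdepth, 1L), 0)) /
                      pmax(n_cov, 1L), NaN)

  pool_fixed_ref <- pool_depth >= 1L & alt[, pool_id] <= max_discordant_reads
  cases_fixed_alt <- n_cov >= 1L &
    rowSums(covered & cref > max_discordant_reads) == 0L
  passes <- pool_fixed_ref & cases_fixed_alt & n_cov >= min_covered_cases
  out <- data.frame(pos = positions, case_alt_frequency = case_af,
                    pool_alt_frequency = pool_af,
                    n_cases_covered = as.integer(n_cov),
                    passes = as.logical(passes))
  class(out) <- c("screen_result", "data.frame")
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Fixed-difference screen: %d sites, %d passing\n",
              nrow(x), sum(x$passes)))
  NextMethod()
}

#' Write screen results as TSV and passing sites as BED
#'
#' @param result A `screen_result`.
#' @param path Output TSV path.
#' @param bed_path Optional BED3 path for passing sites (0-based
#'   half-open single-base intervals).
#' @param chrom Chromosome label for the BED output.
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(result, path, bed_path = NULL,
                                chrom = "region") {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path)) {
    hits <- result[result$passes, , drop = FALSE]
    bed <- data.frame(chrom = chrom, start = hits$pos, end = hits$pos + 1L)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
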