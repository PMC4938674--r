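#' Classify a deletion genotype from region copy numbers
#'
#' The two overlapping deletions define two informative segments: the
#' part unique to the larger deletion (between BP1 and BP2) and the
#' shared distal part (the smaller deletion itself). The copy-state
#' pair over `(unique, shared)` identifies each of the six genotypes:
#'
#' | unique | shared | genotype  |
#' |:------:|:------:|-----------|
#' |   2    |   2    | WT/WT     |
#' |   1    |   1    | Del1/WT   |
#' |   2    |   1    | Del2/WT   |
#' |   0    |   0    | Del1/Del1 |
#' |   1    |   0    | Del1/Del2 |
#' |   2    |   0    | Del2/Del2 |
#'
#' Any other pair — which would violate the nesting of the smaller
#' deletion inside the larger (e.g. more copies lost in the unique
#' segment than in the shared one) — or an ambiguous state yields
#' `"unresolved"`; unresolved is a value, never an error. A sample is
#' affected exactly when both haplotypes carry a deletion allele.
#'
#' The same classifier serves sequencing-derived and ddPCR-derived copy
#' numbers: both modalities use one genotype vocabulary.
#'
#' @param unique_region_cn,shared_region_cn Copy-number estimates over
#'   the two segments (may be `NA`).
#' @param rules Classification ranges, see [cn_state_ranges()].
#' @param sample_id Identifier recorded in the call.
#' @param unique_state,shared_state Optional pre-computed states (e.g. a
#'   multi-assay consensus); default classifies the given copy numbers.
#' @param confidence Optional confidence annotation (e.g.
#'   `"low:few_windows"`); default `"ok"` for resolved calls, `"none"`
#'   for unresolved.
#' @return data.frame with one row: `sample_id`, `genotype`,
#'   `unique_region_cn`, `shared_region_cn`, `unique_state`,
#'   `shared_state`, `affected`, `confidence`.
#' @examples
#' classify_genotype(1.02, 0.04)  # compound heterozygote, affected
#' @export
classify_genotype <- function(unique_region_cn, shared_region_cn,
                              rules = cn_state_ranges(),
                              sample_id = NA_character_,
                              unique_state = classify_cn(unique_region_cn, rules),
                              shared_state = classify_cn(shared_region_cn, rules),
                              confidence = NULL) {
  key <- paste(unique_state, shared_state, sep = ",")
  genotype <- switch(key,
                     "2,2" = "WT/WT",
                     "1,1" = "Del1/WT",
                     "2,1" = "Del2/WT",
                     "0,0" = "Del1/Del1",
                     "1,0" = "Del1/Del2",
                     "2,0" = "Del2/Del2",
                     "unresolved")
  affected <- genotype %in% c("Del1/Del1", "Del1/Del2", "Del2/Del2")
  if (is.null(confidence))
    confidence <- if (genotype == "unresolved") "none" else "ok"
  data.frame(sample_id = sample_id, genotype = genotype,
             unique_region_cn = unique_region_cn,
             shared_region_cn = shared_region_cn,
             unique_state = as.character(unique_state),
             shared_state = as.character(shared_state),
             affected = affected, confidence = confidence)
}

#' Mean copy number over a region
#'
#' Averages window copy numbers over the windows fully contained in a
#' half-open interval, `NA` windows excluded.
#'
#' @param copy_numbers Per-window copy numbers.
#' @param windows data.frame `start`, `end` matching `copy_numbers`.
#' @param region Integer `c(start, end)`, half-open.
#' @return List with `cn` (mean copy number) and `n_windows` (windows
#'   used).
#' @export
summarize_region_cn <- function(copy_numbers, windows, region) {
  stopifnot(length(region) == 2L, region[2L] > region[1L])
  inside <- windows$start >= region[1L] & windows$end <= region[2L]
  if (!any(inside)) {
    # a region smaller than one window: use the window containing it
    inside <- windows$start <= region[1L] & windows$end >= region[2L]
  }
  if (!any(inside)) stop("no windows overlap the region")
  vals <- copy_numbers[inside]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    return(list(cn = NA_real_, n_windows = 0L))
  list(cn = mean(vals), n_windows = length(vals))
}

#' Genotype all cases in a window table
#'
#' Summarizes each case's copy number over the two informative segments
#' of a region model and classifies the six-way deletion genotype.
#' Calls resting on fewer than `min_windows` usable windows in either
#' segment are flagged with lower confidence.
#'
#' @param wt A `window_table`.
#' @param model A `region_model` (defines the two segments).
#' @param rules Classification ranges.
#' @param min_windows Windows needed for full confidence (default 3).
#' @return data.frame of genotype calls, one row per case.
#' @examples
#' rm <- build_region_model(seed = 1)
#' trks <- list(
#'   c1 = simulate_depth(rm, sample_spec("c1", c("Del1", "Del2")), seed = 2),
#'   pool = simulate_depth(rm, sample_spec("pool", mean_coverage = 56,
#'     pool_members = rep(list(c("WT", "WT")), 21)), seed = 3))
#' genotype_cohort(build_window_table(trks, "pool"), rm)
#' @export
genotype_cohort <- function(wt, model, rules = cn_state_ranges(),
                            min_windows = 3L) {
  stopifnot(inherits(wt, "window_table"), inherits(model, "region_model"))
  uq <- del1_unique_interval(model)
  sh <- shared_interval(model)
  out <- lapply(colnames(wt$copy_number), function(id) {
    u <- summarize_region_cn(wt$copy_number[, id], wt$windows, uq)
    s <- summarize_region_cn(wt$copy_number[, id], wt$windows, sh)
    conf <- if (min(u$n_windows, s$n_windows) < min_windows)
      "low:few_windows" else NULL
    classify_genotype(u$cn, s$cn, rules, sample_id = id,
                      confidence = conf)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write genotype calls as TSV
#'
#' @param calls data.frame of genotype calls.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
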