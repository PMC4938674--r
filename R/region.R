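#' Build a model of the deletion region
#'
#' Constructs the coordinate model of a diploid pseudoautosomal segment
#' carrying two nested deletion alleles: a larger deletion (Del-1) placed
#' centrally in the region, and a smaller one (Del-2) that corresponds
#' exactly to the distal part of Del-1, i.e. is right-aligned to Del-1's
#' distal end. Three breakpoints result: BP1 (proximal end of Del-1),
#' BP2 (proximal end of Del-2) and BP3 (the shared distal end). Long
#' (>= 1 kb) perfect TGGA tandem runs are placed immediately distal of
#' BP1 and BP3, mirroring the microsatellite stretches that flank the
#' real breakpoints and that likely mediated the rearrangements. SNP
#' sites with population alternate-allele frequencies are drawn
#' uniformly over the region, outside the repeat runs.
#'
#' All coordinates are 0-based, half-open.
#'
#' @param region_length Region length in bp.
#' @param del1_span Length of the larger deletion (Del-1) in bp.
#' @param del2_span Length of the smaller, nested deletion (Del-2) in bp.
#'   Must be strictly smaller than `del1_span`.
#' @param n_snps Number of polymorphic SNP sites to place.
#' @param snp_freq_sampler Function of one argument `n` returning `n`
#'   population alternate-allele frequencies in \[0, 1\]. The default draws
#'   from Beta(0.8, 0.8), a mildly U-shaped site-frequency spectrum.
#' @param repeat_motif Motif of the breakpoint-flanking tandem runs.
#' @param repeat_run_bp Length (bp) of each breakpoint repeat run; must be
#'   >= 1000 to reflect the >1 kb stretches observed at BP1 and BP3.
#' @param seed Integer seed; fixed seed gives an identical model.
#' @return An object of class `region_model`: a list with elements
#'   `region_length`, `del1` and `del2` (integer `c(start, end)`,
#'   half-open), `breakpoints` (named vector BP1/BP2/BP3), `snp_sites`
#'   (data.frame `pos`, `alt_freq`, positions strictly increasing) and
#'   `repeat_runs` (data.frame `start`, `end`, `motif`, `copies`).
#' @examples
#' rm <- build_region_model(seed = 1)
#' rm$breakpoints
#' @export
build_region_model <- function(region_length = 300000L,
                               del1_span = 170000L,
                               del2_span = 70000L,
                               n_snps = 200L,
                               snp_freq_sampler = function(n) stats::rbeta(n, 0.8, 0.8),
                               repeat_motif = "TGGA",
                               repeat_run_bp = 1200L,
                               seed = 1L) {
  region_length <- as.integer(region_length)
  del1_span <- as.integer(del1_span)
  del2_span <- as.integer(del2_span)
  if (!(del2_span < del1_span))
    stop("del2_span (", del2_span, ") must be strictly smaller than del1_span (",
         del1_span, "): the smaller deletion is nested in the larger one")
  if (!(del1_span < region_length))
    stop("del1_span (", del1_span, ") must be smaller than region_length (",
         region_length, ")")
  if (del1_span <= 0L || del2_span <= 0L)
    stop("deletion spans must be positive")
  if (repeat_run_bp < 1000L)
    stop("repeat_run_bp must be >= 1000 (breakpoint runs exceed 1 kb)")

  # Del-1 central; Del-2 shares Del-1's distal end
  del1_start <- as.integer((region_length - del1_span) %/% 2L)
  del1 <- c(del1_start, del1_start + del1_span)
  del2 <- c(del1[2L] - del2_span, del1[2L])
  bps <- c(BP1 = del1[1L], BP2 = del2[1L], BP3 = del1[2L])

  motif_len <- nchar(repeat_motif)
  copies <- as.integer(ceiling(repeat_run_bp / motif_len))
  run_len <- copies * motif_len
  repeat_runs <- data.frame(
    start = as.integer(c(bps[["BP1"]], bps[["BP3"]])),
    end   = as.integer(c(bps[["BP1"]], bps[["BP3"]]) + run_len),
    motif = repeat_motif,
    copies = copies,
    stringsAsFactors = FALSE
  )
  if (any(repeat_runs$end > region_length))
    stop("repeat run at BP3 extends past region end; enlarge region_length")

  set.seed(as.integer(seed))
  in_repeat <- function(p) {
    out <- rep(FALSE, length(p))
    for (i in seq_len(nrow(repeat_runs)))
      out <- out | (p >= repeat_runs$start[i] & p < repeat_runs$end[i])
    out
  }
  pos <- integer(0)
  while (length(pos) < n_snps) {
    cand <- sample.int(region_length, n_snps * 2L, replace = FALSE) - 1L
    cand <- cand[!in_repeat(cand)]
    pos <- unique(c(pos, cand))
  }
  pos <- sort(pos[seq_len(n_snps)])
  freq <- pmin(1, pmax(0, snp_freq_sampler(n_snps)))

  structure(
    list(region_length = region_length,
         del1 = as.integer(del1),
         del2 = as.integer(del2),
         breakpoints = bps,
         snp_sites = data.frame(pos = pos, alt_freq = freq),
         repeat_runs = repeat_runs),
    class = "region_model"
  )
}

#' @export
print.region_model <- function(x, ...) {
  cat("Region model (", x$region_length, " bp, 0-based half-open)\n", sep = "")
  cat(sprintf("  Del-1: [%d, %d)  span %d bp\n", x$del1[1], x$del1[2],
              diff(x$del1)))
  cat(sprintf("  Del-2: [%d, %d)  span %d bp (distal part of Del-1)\n",
              x$del2[1], x$del2[2], diff(x$del2)))
  cat(sprintf("  Breakpoints: BP1=%d BP2=%d BP3=%d\n",
              x$breakpoints[["BP1"]], x$breakpoints[["BP2"]],
              x$breakpoints[["BP3"]]))
  cat(sprintf("  %d SNP sites; %d repeat runs (%s)\n",
              nrow(x$snp_sites), nrow(x$repeat_runs),
              paste(unique(x$repeat_runs$motif), collapse = ",")))
  invisible(x)
}

#' Per-position haplotype copy indicator
#'
#' For one haplotype allele (`"WT"`, `"Del1"` or `"Del2"`), returns a 0/1
#' integer vector over the region: 1 where the haplotype retains sequence,
#' 0 inside its deletion.
#'
#' @param model A `region_model`.
#' @param allele One of `"WT"`, `"Del1"`, `"Del2"`.
#' @return Integer vector of length `model$region_length`.
#' @export
haplotype_copy_profile <- function(model, allele) {
  stopifnot(inherits(model, "region_model"))
  allele <- match.arg(allele, c("WT", "Del1", "Del2"))
  prof <- rep(1L, model$region_length)
  if (allele == "Del1") {
    prof[(model$del1[1L] + 1L):model$del1[2L]] <- 0L
  } else if (allele == "Del2") {
    prof[(model$del2[1L] + 1L):model$del2[2L]] <- 0L
  }
  prof
}

#' Diploid copy-number profile for a genotype
#'
#' @param model A `region_model`.
#' @param genotype Character vector of two haplotype alleles, e.g.
#'   `c("Del1", "WT")`.
#' @return Integer vector (0/1/2) of length `model$region_length`.
#' @export
genotype_copy_profile <- function(model, genotype) {
  stopifnot(length(genotype) == 2L)
  haplotype_copy_profile(model, genotype[[1L]]) +
    haplotype_copy_profile(model, genotype[[2L]])
}

#' Breakpoint junctions carried by a haplotype allele
#'
#' Del-1 haplotypes join BP1 to BP3; Del-2 haplotypes join BP2 to BP3.
#' Wild-type haplotypes carry no junction.
#'
#' @param allele One of `"WT"`, `"Del1"`, `"Del2"`.
#' @return Character vector of breakpoint labels.
#' @keywords internal
allele_junctions <- function(allele) {
  switch(match.arg(allele, c("WT", "Del1", "Del2")),
         WT = character(0),
         Del1 = c("BP1", "BP3"),
         Del2 = c("BP2", "BP3"))
}

#' The interval unique to the larger deletion
#'
#' The proximal part of Del-1 not shared with Del-2 (between BP1 and BP2).
#' Copy number here distinguishes Del-1 from Del-2 haplotypes.
#'
#' @param model A `region_model`.
#' @return Integer `c(start, end)`, half-open.
#' @export
del1_unique_interval <- function(model) {
  stopifnot(inherits(model, "region_model"))
  c(model$del1[1L], model$del2[1L])
}

#' The interval shared by both deletions
#'
#' The distal segment removed by every deletion haplotype (Del-2 itself).
#'
#' @param model A `region_model`.
#' @return Integer `c(start, end)`, half-open.
#' @export
shared_interval <- function(model) {
  stopifnot(inherits(model, "region_model"))
  model$del2
}

#' Write / read a region model as JSON
#'
#' @param model A `region_model`.
#' @param path Output file path.
#' @return `write_region_model` returns `path` invisibly;
#'   `read_region_model` returns a `region_model`.
#' @export
write_region_model <- function(model, path) {
  stopifnot(inherits(model, "region_model"))
  obj <- list(
    region_length = model$region_length,
    del1 = model$del1, del2 = model$del2,
    breakpoints = as.list(model$breakpoints),
    snp_sites = model$snp_sites,
    repeat_runs = model$repeat_runs
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_region_model
#' @export
read_region_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(region_length = as.integer(obj$region_length),
         del1 = as.integer(obj$del1), del2 = as.integer(obj$del2),
         breakpoints = unlist(obj$breakpoints),
         snp_sites = as.data.frame(obj$snp_sites),
         repeat_runs = as.data.frame(obj$repeat_runs)),
    class = "region_model"
  )
}
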