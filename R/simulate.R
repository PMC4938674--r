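#' Sample specification for the depth simulator
#'
#' Describes one sequenced sample: either an individual with a pair of
#' haplotype alleles, or an equimolar pool described by the explicit
#' deletion genotypes of its members (so equimolarity is exact by
#' construction and the effective allele dosage is `2 * n_members`).
#'
#' Ploidy is 2 for every individual regardless of sex: the region is
#' pseudoautosomal, recombines in both sexes and escapes X-inactivation,
#' so sex never enters the copy-number model.
#'
#' @param sample_id Sample identifier.
#' @param genotype For an individual, character vector of two haplotype
#'   alleles from `c("WT", "Del1", "Del2")`.
#' @param mean_coverage Mean fold-coverage (reads per base) of the sample.
#' @param pool_members For a pool, a list of two-allele genotype vectors,
#'   one per member individual; `genotype` must then be `NULL`.
#' @return An object of class `sample_spec`.
#' @examples
#' sample_spec("case1", c("Del1", "Del1"), mean_coverage = 7)
#' sample_spec("pool", mean_coverage = 56,
#'             pool_members = rep(list(c("WT", "WT")), 21))
#' @export
sample_spec <- function(sample_id, genotype = NULL, mean_coverage = 7,
                        pool_members = NULL) {
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  is_pool <- !is.null(pool_members)
  if (is_pool) {
    if (!is.null(genotype))
      stop("a pool carries member genotypes, not a single haplotype pair")
    if (length(pool_members) < 1L) stop("pool must have >= 1 member")
    lapply(pool_members, check_genotype)
  } else {
    check_genotype(genotype)
  }
  structure(
    list(sample_id = as.character(sample_id), genotype = genotype,
         mean_coverage = mean_coverage, is_pool = is_pool,
         pool_members = pool_members,
         pool_allele_dosage = if (is_pool) 2L * length(pool_members) else 2L),
    class = "sample_spec"
  )
}

check_genotype <- function(genotype) {
  if (length(genotype) != 2L || !all(genotype %in% c("WT", "Del1", "Del2")))
    stop("genotype must be two alleles from WT/Del1/Del2")
  invisible(genotype)
}

#' All haplotype alleles carried by a sample
#' @keywords internal
spec_haplotypes <- function(spec) {
  if (spec$is_pool) unlist(spec$pool_members) else spec$genotype
}

#' Expected per-individual copy-number profile of a sample
#'
#' For an individual this is the 0/1/2 diploid profile; for a pool it is
#' the mean diploid copy number over members (a real number in \[0, 2\]).
#'
#' @param model A `region_model`.
#' @param spec A `sample_spec`.
#' @return Numeric vector of length `model$region_length`.
#' @export
expected_copy_profile <- function(model, spec) {
  haps <- spec_haplotypes(spec)
  counts <- table(factor(haps, levels = c("WT", "Del1", "Del2")))
  n_ind <- length(haps) / 2
  prof <- numeric(model$region_length)
  for (a in names(counts)) {
    if (counts[[a]] > 0L)
      prof <- prof + counts[[a]] * haplotype_copy_profile(model, a)
  }
  prof / n_ind
}

#' Simulate a per-position depth track
#'
#' Per-base read depth is Poisson with mean
#' `mean_coverage * copy_number / 2`, where the copy number is the
#' sample's local diploid copy number (for pools, the member-mean).
#' Optionally a small uniform mapping-noise background
#' (`mapping_noise * mean_coverage` expected reads per base, default 0)
#' is added everywhere, which lets deleted segments receive stray reads
#' as mismapping would produce.
#'
#' Soft-clipped read counts are Binomial(depth, clip rate) per position.
#' The clip rate is `background_clip_rate` except within
#' `clip_window_bp` of a deletion breakpoint at which the sample carries
#' at least one junction chromosome *and* at least one chromosome intact
#' across the breakpoint, where it is multiplied by
#' `clip_enrichment`. Junction-only positions (e.g. a homozygous deleted
#' sample) show no enrichment: reads from the junction haplotype cannot
#' be anchored across the >1 kb tandem repeats flanking the breakpoints,
#' so clip signal requires locally mapped intact-haplotype coverage —
#' this reproduces the observation that the clip peak appears in the
#' carrier-containing pool rather than in homozygous cases.
#'
#' @param model A `region_model`.
#' @param spec A `sample_spec`.
#' @param seed Integer seed.
#' @param mapping_noise Expected background depth inside deleted
#'   segments, as a fraction of `mean_coverage` (default 0).
#' @param background_clip_rate Per-read probability of a soft-clip away
#'   from breakpoints.
#' @param clip_enrichment Multiplier on the clip rate near active
#'   breakpoints (default 10).
#' @param clip_window_bp Half-width of the breakpoint clip window (bp).
#' @return An object of class `depth_track`: list with `sample_id`,
#'   integer vectors `depth` and `softclip` over the region, and
#'   `background_mean` (the genome-wide mean depth stand-in, set to
#'   `mean_coverage`).
#' @examples
#' rm <- build_region_model(seed = 1)
#' trk <- simulate_depth(rm, sample_spec("c1", c("Del1", "WT")), seed = 2)
#' mean(trk$depth)
#' @export
simulate_depth <- function(model, spec, seed,
                           mapping_noise = 0,
                           background_clip_rate = 0.01,
                           clip_enrichment = 10,
                           clip_window_bp = 500L) {
  stopifnot(inherits(model, "region_model"), inherits(spec, "sample_spec"))
  if (mapping_noise < 0) stop("mapping_noise must be >= 0")
  set.seed(as.integer(seed))

  lambda <- spec$mean_coverage * expected_copy_profile(model, spec) / 2 +
    mapping_noise * spec$mean_coverage
  depth <- stats::rpois(model$region_length, lambda)

  rate <- rep(background_clip_rate, model$region_length)
  haps <- spec_haplotypes(spec)
  junctions <- unique(unlist(lapply(haps, allele_junctions)))
  for (bp in junctions) {
    pos <- model$breakpoints[[bp]]
    # intact = some chromosome retains sequence across this breakpoint
    intact <- vapply(haps, function(a) !(bp %in% allele_junctions(a)) &&
                       hap_covers(model, a, pos), logical(1))
    if (any(intact)) {
      lo <- max(0L, pos - clip_window_bp) + 1L
      hi <- min(model$region_length, pos + clip_window_bp)
      rate[lo:hi] <- pmin(1, background_clip_rate * clip_enrichment)
    }
  }
  softclip <- stats::rbinom(model$region_length, depth, rate)

  structure(
    list(sample_id = spec$sample_id, depth = as.integer(depth),
         softclip = as.integer(softclip),
         background_mean = spec$mean_coverage),
    class = "depth_track"
  )
}

# does haplotype allele a retain sequence at (0-based) position pos?
hap_covers <- function(model, a, pos) {
  if (a == "Del1") return(!(pos >= model$del1[1L] && pos < model$del1[2L]))
  if (a == "Del2") return(!(pos >= model$del2[1L] && pos < model$del2[2L]))
  TRUE
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("Depth track '%s': %d bp, mean depth %.2f (background %.2f)\n",
              x$sample_id, length(x$depth), mean(x$depth), x$background_mean))
  invisible(x)
}

#' Deterministic pooled site state for explicit member genotypes
#'
#' For each SNP site, counts the haplotype copies surviving deletion
#' (a haplotype contributes a copy unless its deletion removes the site)
#' and the alternate-allele copies among them, and derives the pooled
#' alternate frequency. This is the exact, equimolar-by-construction
#' quantity the count simulator draws from.
#'
#' @param model A `region_model`.
#' @param member_genotypes List of two-allele genotype vectors.
#' @param alt_haplotypes Binary matrix (2 * n_members rows, one column per
#'   SNP site; rows ordered member1-hap1, member1-hap2, member2-hap1, ...)
#'   marking which haplotypes carry the alternate allele at each site.
#' @return data.frame with `pos`, `total_copies`, `alt_copies`,
#'   `alt_freq` (`NaN` where no copies survive).
#' @export
pool_site_frequencies <- function(model, member_genotypes, alt_haplotypes) {
  stopifnot(inherits(model, "region_model"))
  haps <- unlist(member_genotypes)
  n_hap <- length(haps)
  sites <- model$snp_sites$pos
  if (!is.matrix(alt_haplotypes) || nrow(alt_haplotypes) != n_hap ||
      ncol(alt_haplotypes) != length(sites))
    stop("alt_haplotypes must be a ", n_hap, " x ", length(sites), " matrix")
  survives <- vapply(sites, function(p)
    vapply(haps, hap_covers, logical(1), model = model, pos = p),
    logical(n_hap))          # n_hap x n_sites
  total <- as.integer(colSums(survives))
  alt <- as.integer(colSums(alt_haplotypes * survives))
  data.frame(pos = sites, total_copies = total, alt_copies = alt,
             alt_freq = ifelse(total > 0, alt / total, NaN))
}

#' Draw alternate-allele haplotypes from site population frequencies
#'
#' @param model A `region_model`.
#' @param n_haplotypes Number of haplotypes (rows).
#' @param seed Integer seed.
#' @return Binary matrix `n_haplotypes` x `nrow(model$snp_sites)`.
#' @export
draw_alt_haplotypes <- function(model, n_haplotypes, seed) {
  set.seed(as.integer(seed))
  f <- model$snp_sites$alt_freq
  matrix(stats::rbinom(n_haplotypes * length(f), 1L, rep(f, each = n_haplotypes)),
         nrow = n_haplotypes)
}

#' Simulate allele-specific SNP read counts for a pool (or individual)
#'
#' At each SNP site the sequencing depth is Poisson with mean
#' `coverage * (mean member copy number) / 2`; the alternate-read count
#' is Binomial(depth, f'), where f' is the pooled alternate frequency
#' perturbed by the per-read error rate:
#' `f' = f * (1 - error_rate) + (1 - f) * error_rate`.
#' An individual is simply a pool of one member.
#'
#' @param model A `region_model`.
#' @param member_genotypes List of two-allele genotype vectors (>= 1).
#' @param coverage Fold-coverage of the pooled library.
#' @param error_rate Per-read probability of reading the opposite allele.
#' @param seed Integer seed.
#' @param sample_id Sample identifier recorded in the output table.
#' @param alt_haplotypes Optional explicit binary alt-haplotype matrix
#'   (see [pool_site_frequencies()]); by default haplotypes are drawn
#'   from the sites' population frequencies.
#' @return A SNP count table: data.frame `sample_id`, `pos`,
#'   `ref_count`, `alt_count` with one row per SNP site.
#' @export
simulate_pool_snp_counts <- function(model, member_genotypes, coverage,
                                     error_rate = 0, seed,
                                     sample_id = "pool",
                                     alt_haplotypes = NULL) {
  stopifnot(inherits(model, "region_model"))
  if (length(member_genotypes) < 1L) stop("member_genotypes must be non-empty")
  lapply(member_genotypes, check_genotype)
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  set.seed(as.integer(seed))
  n_hap <- 2L * length(member_genotypes)
  if (is.null(alt_haplotypes))
    alt_haplotypes <- matrix(
      stats::rbinom(n_hap * nrow(model$snp_sites), 1L,
                    rep(model$snp_sites$alt_freq, each = n_hap)),
      nrow = n_hap)
  st <- pool_site_frequencies(model, member_genotypes, alt_haplotypes)
  n_members <- length(member_genotypes)
  lambda <- coverage * (st$total_copies / n_members) / 2
  depth <- stats::rpois(nrow(st), lambda)
  f <- ifelse(is.nan(st$alt_freq), 0, st$alt_freq)
  f_err <- f * (1 - error_rate) + (1 - f) * error_rate
  alt <- stats::rbinom(nrow(st), depth, f_err)
  data.frame(sample_id = sample_id, pos = st$pos,
             ref_count = depth - alt, alt_count = alt)
}

#' Simulate one droplet digital PCR assay
#'
#' Droplet occupancy follows the standard ddPCR Poisson model: with
#' `lambda` target copies per droplet, a droplet is positive with
#' probability `1 - exp(-lambda)`. The target load is
#' `mean_copies_per_droplet_ref * copy_number / 2`, where the copy
#' number follows from the genotype and the assay target: a reference
#' assay always sees 2 copies; an assay in the segment unique to the
#' larger deletion sees one copy per non-Del1 haplotype; an assay in the
#' shared (distal) segment sees one copy per wild-type haplotype.
#'
#' @param genotype Two-allele genotype vector.
#' @param assay_target One of `"del1_unique_region"`, `"shared_region"`,
#'   `"reference"`.
#' @param total_droplets Number of droplets generated (default 15000).
#' @param mean_copies_per_droplet_ref Reference-locus load in copies per
#'   droplet (default 1).
#' @param seed Integer seed.
#' @param sample_id,assay_id Identifiers recorded in the output.
#' @param false_positive_rate Probability that an empty droplet still
#'   reads positive (droplet false-positive floor, default 0).
#' @return A droplet assay record: data.frame `sample_id`, `assay_id`,
#'   `assay_target`, `total_droplets`, `positive_droplets`.
#' @examples
#' simulate_ddpcr(c("Del1", "WT"), "del1_unique_region", seed = 1)
#' @export
simulate_ddpcr <- function(genotype, assay_target,
                           total_droplets = 15000L,
                           mean_copies_per_droplet_ref = 1,
                           seed, sample_id = "s1", assay_id = assay_target,
                           false_positive_rate = 0) {
  check_genotype(genotype)
  assay_target <- match.arg(assay_target,
                            c("del1_unique_region", "shared_region", "reference"))
  if (total_droplets <= 0) stop("total_droplets must be positive")
  if (mean_copies_per_droplet_ref < 0) stop("droplet load must be >= 0")
  set.seed(as.integer(seed))
  cn <- assay_copy_number(genotype, assay_target)
  lambda <- mean_copies_per_droplet_ref * cn / 2
  p <- 1 - (1 - false_positive_rate) * exp(-lambda)
  pos <- stats::rbinom(1L, total_droplets, p)
  data.frame(sample_id = sample_id, assay_id = assay_id,
             assay_target = assay_target,
             total_droplets = as.integer(total_droplets),
             positive_droplets = as.integer(pos))
}

#' Genotype-implied copy number at an assay target
#' @keywords internal
assay_copy_number <- function(genotype, assay_target) {
  switch(assay_target,
         reference = 2L,
         del1_unique_region = sum(genotype != "Del1"),
         shared_region = sum(genotype == "WT"))
}

#' Simulate droplet assays for a cohort of genotyped samples
#'
#' Runs [simulate_ddpcr()] for every sample under a reference assay plus
#' the given deletion-targeting assays, with per-assay independent draws.
#'
#' @param genotypes Named list of two-allele genotype vectors (names are
#'   sample ids).
#' @param assays data.frame with columns `assay_id`, `assay_target`
#'   (the default panel is one reference plus one assay in each deletion
#'   segment).
#' @param seed Integer seed.
#' @inheritParams simulate_ddpcr
#' @return data.frame of droplet assay records, one row per sample/assay.
#' @export
simulate_ddpcr_cohort <- function(genotypes,
                                  assays = data.frame(
                                    assay_id = c("REF", "DEL1A", "DEL2A"),
                                    assay_target = c("reference",
                                                     "del1_unique_region",
                                                     "shared_region")),
                                  total_droplets = 15000L,
                                  mean_copies_per_droplet_ref = 1,
                                  seed = 1L,
                                  false_positive_rate = 0) {
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max,
                          length(genotypes) * nrow(assays))
  out <- vector("list", length(genotypes) * nrow(assays))
  k <- 0L
  for (i in seq_along(genotypes)) {
    for (j in seq_len(nrow(assays))) {
      k <- k + 1L
      out[[k]] <- simulate_ddpcr(
        genotypes[[i]], assays$assay_target[j],
        total_droplets = total_droplets,
        mean_copies_per_droplet_ref = mean_copies_per_droplet_ref,
        seed = sub_seeds[k], sample_id = names(genotypes)[i],
        assay_id = assays$assay_id[j],
        false_positive_rate = false_positive_rate)
    }
  }
  do.call(rbind, out)
}

#' Simulate a population of deletion genotypes under Hardy-Weinberg
#'
#' Haplotypes are drawn i.i.d. with the given allele frequencies
#' (random mating, no inbreeding).
#'
#' @param n_individuals Number of individuals.
#' @param del1_freq,del2_freq Population frequencies of the two deletion
#'   alleles; must be in \[0, 1\] and sum to at most 1.
#' @param seed Integer seed.
#' @return data.frame `sample_id`, `allele1`, `allele2`.
#' @export
simulate_population <- function(n_individuals, del1_freq, del2_freq, seed) {
  if (del1_freq < 0 || del1_freq > 1 || del2_freq < 0 || del2_freq > 1)
    stop("allele frequencies must lie in [0, 1]")
  if (del1_freq + del2_freq > 1)
    stop("del1_freq + del2_freq must not exceed 1")
  set.seed(as.integer(seed))
  alleles <- c("Del1", "Del2", "WT")
  p <- c(del1_freq, del2_freq, 1 - del1_freq - del2_freq)
  draw <- matrix(sample(alleles, 2L * n_individuals, replace = TRUE, prob = p),
                 ncol = 2L)
  data.frame(sample_id = sprintf("ind%03d", seq_len(n_individuals)),
             allele1 = draw[, 1L], allele2 = draw[, 2L])
}

#' Simulate the region's nucleotide sequence
#'
#' Random uniform A/C/G/T background with the model's repeat runs
#' overwritten by perfect tandem copies of their motif — enough sequence
#' realism for motif-run scanning around breakpoints; no GC or
#' higher-order composition modeling.
#'
#' @param model A `region_model`.
#' @param seed Integer seed.
#' @return Character scalar of length `model$region_length`.
#' @export
simulate_region_sequence <- function(model, seed) {
  stopifnot(inherits(model, "region_model"))
  set.seed(as.integer(seed))
  bases <- sample(c("A", "C", "G", "T"), model$region_length, replace = TRUE)
  for (i in seq_len(nrow(model$repeat_runs))) {
    run <- model$repeat_runs[i, ]
    tandem <- strsplit(strrep(run$motif, run$copies), "")[[1L]]
    bases[(run$start + 1L):run$end] <- tandem
  }
  paste(bases, collapse = "")
}
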