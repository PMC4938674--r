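test_that("depth signatures match genotype copy numbers", {
  rm <- default_model()
  uq <- (rm$del1[1] + 1):rm$del2[1]        # Del-1-unique segment, 1-based
  sh <- (rm$del2[1] + 1):rm$del2[2]        # shared segment
  out <- (1:10000)                         # proximal flank, diploid

  hom <- simulate_depth(rm, sample_spec("h", c("Del1", "Del1")), seed = 1)
  expect_true(all(hom$depth[c(uq, sh)] == 0))
  se <- sqrt(7 / length(out))
  expect_lt(abs(mean(hom$depth[out]) - 7), 3 * se)

  cmp <- simulate_depth(rm, sample_spec("c", c("Del1", "Del2")), seed = 2)
  expect_true(all(cmp$depth[sh] == 0))
  se_uq <- sqrt(3.5 / length(uq))
  expect_lt(abs(mean(cmp$depth[uq]) - 3.5), 3 * se_uq)
})

test_that("wild-type mean depth converges to the coverage for any coverage", {
  rm <- default_model()
  for (cov in c(1, 7, 56)) {
    trk <- simulate_depth(rm, sample_spec("w", c("WT", "WT"),
                                          mean_coverage = cov), seed = cov)
    se <- sqrt(cov / rm$region_length)
    expect_lt(abs(mean(trk$depth) - cov), 3 * se)
    expect_identical(trk$background_mean, cov)
  }
})

test_that("deleted segments stay at exactly zero without mapping noise, and not with it", {
  rm <- default_model()
  sh <- (rm$del2[1] + 1):rm$del2[2]
  clean <- simulate_depth(rm, sample_spec("h", c("Del1", "Del1")), seed = 3)
  expect_true(all(clean$depth[sh] == 0))
  noisy <- simulate_depth(rm, sample_spec("h", c("Del1", "Del1")), seed = 3,
                          mapping_noise = 0.05)
  expect_gt(sum(noisy$depth[sh]), 0)
})

test_that("fixed seeds give byte-identical tracks and counts", {
  rm <- default_model()
  spec <- sample_spec("c", c("Del1", "WT"))
  expect_identical(simulate_depth(rm, spec, seed = 9),
                   simulate_depth(rm, spec, seed = 9))
  g <- list(c("WT", "WT"), c("Del1", "WT"))
  expect_identical(simulate_pool_snp_counts(rm, g, 56, seed = 9),
                   simulate_pool_snp_counts(rm, g, 56, seed = 9))
  expect_identical(simulate_ddpcr(c("Del1", "WT"), "shared_region", seed = 9),
                   simulate_ddpcr(c("Del1", "WT"), "shared_region", seed = 9))
  expect_identical(simulate_population(50, 0.1, 0.05, seed = 9),
                   simulate_population(50, 0.1, 0.05, seed = 9))
})

test_that("soft-clips are bounded by depth and enriched only at anchored junctions", {
  rm <- default_model()
  near_bp1 <- (rm$breakpoints[["BP1"]] - 499):(rm$breakpoints[["BP1"]] + 500)
  carrier <- simulate_depth(rm, sample_spec("k", c("Del1", "WT")), seed = 4)
  expect_true(all(carrier$softclip <= carrier$depth))
  clip_rate_near <- sum(carrier$softclip[near_bp1]) / sum(carrier$depth[near_bp1])
  far <- 1:20000
  clip_rate_far <- sum(carrier$softclip[far]) / sum(carrier$depth[far])
  expect_gt(clip_rate_near, 5 * clip_rate_far)

  # homozygous deleted: no intact chromosome anchors the junction
  hom <- simulate_depth(rm, sample_spec("h", c("Del1", "Del1")), seed = 5)
  rate_near <- sum(hom$softclip[near_bp1]) / max(1, sum(hom$depth[near_bp1]))
  expect_lt(rate_near, 0.03)
})

test_that("an all-reference pool yields zero alternate reads without error", {
  rm <- default_model(n_snps = 50)
  members <- rep(list(c("WT", "WT")), 21)
  tab <- simulate_pool_snp_counts(rm, members, coverage = 56, error_rate = 0,
                                  seed = 6,
                                  alt_haplotypes = matrix(0L, 42, 50))
  expect_true(all(tab$alt_count == 0))
  expect_true(all(tab$ref_count >= 0))
  expect_error(simulate_pool_snp_counts(rm, list(), 56, seed = 1),
               "non-empty")
})

test_that("pooled alternate fraction converges to the pooled frequency", {
  rm <- default_model(n_snps = 50)
  members <- rep(list(c("WT", "WT")), 10)
  alt <- matrix(rep(c(0L, 1L), each = 10), 20, 50)   # exactly half alt
  tab <- simulate_pool_snp_counts(rm, members, coverage = 2000, seed = 7,
                                  alt_haplotypes = alt)
  frac <- sum(tab$alt_count) / sum(tab$ref_count + tab$alt_count)
  n_reads <- sum(tab$ref_count + tab$alt_count)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_reads))
})

test_that("pooled site frequencies equal brute-force haplotype enumeration", {
  rm <- default_model(n_snps = 40)
  set.seed(11)
  alleles <- c("WT", "Del1", "Del2")
  members <- replicate(8, sample(alleles, 2, replace = TRUE),
                       simplify = FALSE)
  alt <- matrix(rbinom(16 * 40, 1, 0.4), 16, 40)
  got <- pool_site_frequencies(rm, members, alt)

  # oracle: walk every haplotype at every site
  for (s in seq_len(40)) {
    p <- rm$snp_sites$pos[s]
    total <- 0L; altc <- 0L
    h <- 0L
    for (m in members) for (a in m) {
      h <- h + 1L
      deleted <- (a == "Del1" && p >= rm$del1[1] && p < rm$del1[2]) ||
        (a == "Del2" && p >= rm$del2[1] && p < rm$del2[2])
      if (!deleted) {
        total <- total + 1L
        altc <- altc + alt[h, s]
      }
    }
    expect_identical(got$total_copies[s], total)
    expect_identical(got$alt_copies[s], altc)
    if (total > 0) expect_equal(got$alt_freq[s], altc / total)
  }
})

test_that("droplet positives follow Poisson occupancy", {
  # wild type: reference and target assays see the same load
  a_ref <- simulate_ddpcr(c("WT", "WT"), "reference", 100000, 1, seed = 1)
  a_tgt <- simulate_ddpcr(c("WT", "WT"), "shared_region", 100000, 1, seed = 2)
  p2 <- 1 - exp(-1)          # both loci carry two copies at load 1
  se2 <- sqrt(p2 * (1 - p2) / 100000)
  expect_lt(abs(a_ref$positive_droplets / 100000 - p2), 3 * se2)
  expect_lt(abs(a_tgt$positive_droplets / 100000 - p2), 3 * se2)
  p <- 1 - exp(-0.5)
  se <- sqrt(p * (1 - p) / 100000)

  # null-copy cluster: no target molecules, no positives (fp floor 0)
  null <- simulate_ddpcr(c("Del1", "Del1"), "del1_unique_region",
                         15000, 1, seed = 3)
  expect_identical(null$positive_droplets, 0L)

  # hemizygote at load 1: fraction ~ 1 - e^(-1/2)
  hemi <- simulate_ddpcr(c("Del1", "WT"), "del1_unique_region",
                         100000, 1, seed = 4)
  expect_lt(abs(hemi$positive_droplets / 100000 - p), 3 * se)
  expect_error(simulate_ddpcr(c("WT", "WT"), "reference",
                              mean_copies_per_droplet_ref = -1, seed = 1),
               ">= 0")
})

test_that("positive droplet fraction increases with copy number at fixed load", {
  genos <- list(c("Del1", "Del1"), c("Del1", "WT"), c("WT", "WT"))
  pos <- vapply(seq_along(genos), function(i)
    simulate_ddpcr(genos[[i]], "del1_unique_region", 50000, 1,
                   seed = 20 + i)$positive_droplets, integer(1))
  expect_true(all(diff(pos) > 0))
})

test_that("population simulation honours Hardy-Weinberg frequencies", {
  all_wt <- simulate_population(30, 0, 0, seed = 1)
  expect_true(all(all_wt$allele1 == "WT" & all_wt$allele2 == "WT"))
  expect_error(simulate_population(10, 0.8, 0.3, seed = 1), "exceed 1")
  expect_error(simulate_population(10, -0.1, 0, seed = 1), "\\[0, 1\\]")

  q1 <- 0.0479; q2 <- 0.0106
  pop <- simulate_population(1e5, q1, q2, seed = 2)
  lab <- genotype_label(pop$allele1, pop$allele2)
  # exact HWE carrier probability, computed from first principles
  p_wt <- 1 - q1 - q2
  p_carrier <- 2 * q1 * p_wt + 2 * q2 * p_wt
  obs <- mean(lab %in% c("Del1/WT", "Del2/WT"))
  expect_lt(abs(obs - p_carrier), 3 * sqrt(p_carrier * (1 - p_carrier) / 1e5))
})

test_that("the region sequence carries the model's repeat runs", {
  rm <- default_model()
  s <- simulate_region_sequence(rm, seed = 8)
  expect_identical(nchar(s), rm$region_length)
  run <- rm$repeat_runs[1, ]
  expect_identical(substr(s, run$start + 1, run$end),
                   strrep(run$motif, run$copies))
})
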