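#' Genotype count table from genotype calls
#'
#' @param genotypes Character vector of genotype strings (e.g. from
#'   [ddpcr_genotype()]'s `genotype` column), or an already tabulated
#'   named vector/list of counts.
#' @return Named integer vector over the six genotype classes (and
#'   `unresolved` if present).
#' @export
genotype_counts <- function(genotypes) {
  classes <- c("Del1/Del1", "Del1/Del2", "Del2/Del2",
               "Del1/WT", "Del2/WT", "WT/WT", "unresolved")
  if (!is.null(names(genotypes))) {
    counts <- stats::setNames(rep(0L, length(classes)), classes)
    bad <- setdiff(names(genotypes), classes)
    if (length(bad) > 0L)
      stop("unknown genotype classes: ", paste(bad, collapse = ", "))
    counts[names(genotypes)] <- as.integer(unlist(genotypes))
    counts
  } else {
    bad <- setdiff(unique(genotypes), classes)
    if (length(bad) > 0L)
      stop("unknown genotype classes: ", paste(bad, collapse = ", "))
    table(factor(genotypes, levels = classes))
  }
}

#' Allele frequencies by gene counting
#'
#' Each homozygote contributes two copies of its allele, each
#' heterozygote one copy of each; frequencies are allele counts over
#' `2n` chromosomes. Affected genotypes, if present in the cohort, are
#' counted like any other; unresolved calls are excluded from `n`.
#'
#' @param counts Genotype counts (vector accepted by
#'   [genotype_counts()]).
#' @return List `del1_freq`, `del2_freq`, `wt_freq`, `n` (individuals
#'   counted).
#' @examples
#' allele_frequencies(c("Del1/WT" = 9, "Del2/WT" = 2, "WT/WT" = 83))
#' @export
allele_frequencies <- function(counts) {
  k <- genotype_counts(counts)
  n <- sum(k[c("Del1/Del1", "Del1/Del2", "Del2/Del2",
               "Del1/WT", "Del2/WT", "WT/WT")])
  if (n < 1L) stop("no resolved genotypes to count")
  del1 <- 2L * k[["Del1/Del1"]] + k[["Del1/Del2"]] + k[["Del1/WT"]]
  del2 <- 2L * k[["Del2/Del2"]] + k[["Del1/Del2"]] + k[["Del2/WT"]]
  wt <- 2L * k[["WT/WT"]] + k[["Del1/WT"]] + k[["Del2/WT"]]
  list(del1_freq = del1 / (2 * n), del2_freq = del2 / (2 * n),
       wt_freq = wt / (2 * n), n = as.integer(n))
}

#' Carrier fraction
#'
#' Fraction of individuals heterozygous for either deletion allele with
#' a wild-type partner haplotype (`Del1/WT` or `Del2/WT`).
#'
#' @inheritParams allele_frequencies
#' @return Numeric fraction.
#' @export
carrier_fraction <- function(counts) {
  k <- genotype_counts(counts)
  n <- sum(k[c("Del1/Del1", "Del1/Del2", "Del2/Del2",
               "Del1/WT", "Del2/WT", "WT/WT")])
  if (n < 1L) stop("no resolved genotypes")
  (k[["Del1/WT"]] + k[["Del2/WT"]]) / n
}

#' Hardy-Weinberg expectations for a two-deletion recessive locus
#'
#' Trinomial Hardy-Weinberg expansion over alleles (Del-1, Del-2, WT).
#' The expected affected fraction — both haplotypes carrying a deletion
#' — is `(del1_freq + del2_freq)^2`, summing the two homozygous classes
#' and the compound heterozygote.
#'
#' @param del1_freq,del2_freq Deletion allele frequencies (>= 0, sum
#'   <= 1).
#' @return List with `genotype_fractions` (named, sums to 1 exactly),
#'   `carrier_fraction` and `affected_fraction`.
#' @examples
#' hwe_expectations(0.0479, 0.0106)$affected_fraction
#' @export
hwe_expectations <- function(del1_freq, del2_freq) {
  if (del1_freq < 0 || del2_freq < 0)
    stop("allele frequencies must be >= 0")
  if (del1_freq + del2_freq > 1)
    stop("allele frequencies must sum to at most 1")
  q1 <- del1_freq; q2 <- del2_freq; p <- 1 - q1 - q2
  gf <- c("Del1/Del1" = q1^2, "Del1/Del2" = 2 * q1 * q2,
          "Del2/Del2" = q2^2, "Del1/WT" = 2 * q1 * p,
          "Del2/WT" = 2 * q2 * p, "WT/WT" = p^2)
  list(genotype_fractions = gf,
       carrier_fraction = 2 * q1 * p + 2 * q2 * p,
       affected_fraction = (q1 + q2)^2)
}

#' Population summary of deletion genotype calls
#'
#' @inheritParams allele_frequencies
#' @return Object of class `population_summary`: list with
#'   `n_individuals`, `genotype_counts`, `del1_freq`, `del2_freq`,
#'   `wt_freq`, `carrier_fraction`, `hwe_expected_affected_fraction`.
#' @examples
#' population_summary(c("Del1/WT" = 9, "Del2/WT" = 2, "WT/WT" = 83))
#' @export
population_summary <- function(counts) {
  k <- genotype_counts(counts)
  af <- allele_frequencies(k)
  structure(
    list(n_individuals = af$n,
         genotype_counts = k,
         del1_freq = af$del1_freq, del2_freq = af$del2_freq,
         wt_freq = af$wt_freq,
         carrier_fraction = as.numeric(carrier_fraction(k)),
         hwe_expected_affected_fraction =
           hwe_expectations(af$del1_freq, af$del2_freq)$affected_fraction),
    class = "population_summary"
  )
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population summary (n = %d)\n", x$n_individuals))
  k <- x$genotype_counts
  k <- k[k > 0]
  cat("  counts:", paste(sprintf("%s=%d", names(k), k), collapse = "  "), "\n")
  cat(sprintf("  allele frequencies: Del-1 %.2f%%  Del-2 %.2f%%\n",
              100 * x$del1_freq, 100 * x$del2_freq))
  cat(sprintf("  carrier fraction: %.1f%%\n", 100 * x$carrier_fraction))
  cat(sprintf("  HWE expected affected fraction: %.3g\n",
              x$hwe_expected_affected_fraction))
  invisible(x)
}

#' Write a population summary as JSON
#'
#' @param summary A `population_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_summary <- function(summary, path) {
  obj <- unclass(summary)
  obj$genotype_counts <- as.list(obj$genotype_counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Canonical genotype label from two haplotype alleles
#'
#' Orders the alleles (Del1 before Del2 before WT) and joins them with
#' `/`, so `c("WT", "Del1")` and `c("Del1", "WT")` both give
#' `"Del1/WT"`.
#'
#' @param allele1,allele2 Character vectors of haplotype alleles.
#' @return Character vector of genotype labels.
#' @examples
#' genotype_label(c("WT", "Del2"), c("Del1", "Del1"))
#' @export
genotype_label <- function(allele1, allele2) {
  order_of <- c(Del1 = 1L, Del2 = 2L, WT = 3L)
  if (any(!allele1 %in% names(order_of)) || any(!allele2 %in% names(order_of)))
    stop("alleles must be WT, Del1 or Del2")
  first <- ifelse(order_of[allele1] <= order_of[allele2], allele1, allele2)
  second <- ifelse(order_of[allele1] <= order_of[allele2], allele2, allele1)
  paste(first, second, sep = "/")
}
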