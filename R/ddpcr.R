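#' Copy-number state classification ranges
#'
#' One classification vocabulary for both sequencing- and ddPCR-derived
#' copy numbers: two copies in \[1.7, 2.3\], one copy in \[0.7, 1.3\],
#' null below `zero_max`. The published genotyping defined the first two
#' ranges and found no outliers needing a null range; the default
#' `zero_max = 0.3` mirrors the gap below the one-copy range.
#'
#' @param two,one Length-2 inclusive ranges for the 2- and 1-copy
#'   states.
#' @param zero_max Upper (exclusive) bound of the null-copy state.
#' @return List of ranges, for [classify_cn()].
#' @export
cn_state_ranges <- function(two = c(1.7, 2.3), one = c(0.7, 1.3),
                            zero_max = 0.3) {
  stopifnot(length(two) == 2L, length(one) == 2L, zero_max > 0)
  list(two = two, one = one, zero_max = zero_max)
}

#' Classify a copy number into a copy state
#'
#' Total on `[0, Inf)`: values falling in no range are `"ambiguous"`,
#' never an error; `NA` input stays `NA` (undefined measurement).
#' Range boundaries are inclusive.
#'
#' @param copy_number Numeric vector of copy-number estimates (>= 0).
#' @param rules Ranges from [cn_state_ranges()].
#' @return Character vector over `c("0", "1", "2", "ambiguous")` with
#'   `NA` propagated.
#' @examples
#' classify_cn(c(2.05, 0.95, 1.5, 0.05))
#' @export
classify_cn <- function(copy_number, rules = cn_state_ranges()) {
  if (any(copy_number < 0, na.rm = TRUE))
    stop("copy numbers must be >= 0")
  out <- rep(NA_character_, length(copy_number))
  ok <- !is.na(copy_number)
  x <- copy_number[ok]
  res <- rep("ambiguous", length(x))
  res[x < rules$zero_max] <- "0"
  res[x >= rules$one[1L] & x <= rules$one[2L]] <- "1"
  res[x >= rules$two[1L] & x <= rules$two[2L]] <- "2"
  out[ok] <- res
  out
}

#' Poisson occupancy: copies per droplet from droplet counts
#'
#' Inverts the droplet occupancy model: with a fraction `f` of positive
#' droplets, the mean target copies per droplet is `-ln(1 - f)`.
#' A saturated well (every droplet positive) is unquantifiable and is an
#' error — the sample needs re-dilution, extrapolating to infinite
#' concentration would be meaningless.
#'
#' @param positive_droplets,total_droplets Droplet counts (vectorized);
#'   `0 <= positive <= total`, `total > 0`.
#' @return Numeric lambda (copies/droplet).
#' @examples
#' poisson_lambda(round(15000 * (1 - exp(-1))), 15000)
#' @export
poisson_lambda <- function(positive_droplets, total_droplets) {
  if (any(total_droplets <= 0)) stop("total_droplets must be positive")
  if (any(positive_droplets < 0) || any(positive_droplets > total_droplets))
    stop("positive_droplets must lie in [0, total_droplets]")
  if (any(positive_droplets == total_droplets))
    stop("saturated well (all droplets positive): unquantifiable, re-dilute")
  -log(1 - positive_droplets / total_droplets)
}

#' Copy number from target and reference droplet loads
#'
#' @param lambda_target,lambda_ref Copies per droplet at the target and
#'   reference loci (`lambda_ref > 0`).
#' @param reference_copies Copy number of the reference locus
#'   (default 2, a diploid autosomal reference).
#' @return `reference_copies * lambda_target / lambda_ref`.
#' @export
copy_number_ratio <- function(lambda_target, lambda_ref,
                              reference_copies = 2) {
  if (any(lambda_ref <= 0))
    stop("lambda_ref must be positive (no reference signal)")
  if (any(lambda_target < 0)) stop("lambda_target must be >= 0")
  reference_copies * lambda_target / lambda_ref
}

#' Majority consensus over replicate assay states
#'
#' With several assays per targeted region, the region state is the
#' strict-majority state; ties and ambiguous majorities stay
#' `"ambiguous"`.
#'
#' @param states Character vector of per-assay states
#'   (`"0"`,`"1"`,`"2"`,`"ambiguous"`, `NA` treated as ambiguous).
#' @return A single state string.
#' @examples
#' multi_assay_consensus(c("1", "1", "ambiguous"))
#' @export
multi_assay_consensus <- function(states) {
  if (length(states) < 1L) stop("need >= 1 assay state")
  states[is.na(states)] <- "ambiguous"
  numeric_states <- states[states %in% c("0", "1", "2")]
  if (length(numeric_states) == 0L) return("ambiguous")
  tab <- table(numeric_states)
  best <- names(tab)[tab == max(tab)]
  if (length(best) > 1L) return("ambiguous")          # tie
  if (max(tab) * 2L <= length(states)) return("ambiguous")  # no strict majority
  best
}

#' Copy-number estimates from a droplet assay table
#'
#' For each sample, pairs every deletion-targeting assay with the
#' sample's reference assay, computes per-assay lambdas
#' ([poisson_lambda()]), the copy-number ratio and its classified state.
#'
#' @param assays data.frame with columns `sample_id`, `assay_id`,
#'   `assay_target` (`"reference"`, `"del1_unique_region"`,
#'   `"shared_region"`), `total_droplets`, `positive_droplets`.
#' @param rules Ranges from [cn_state_ranges()].
#' @param reference_copies Reference locus copy number (default 2).
#' @return data.frame `sample_id`, `assay_id`, `assay_target`,
#'   `lambda_target`, `lambda_reference`, `copy_number`,
#'   `classified_state`.
#' @export
ddpcr_copy_numbers <- function(assays, rules = cn_state_ranges(),
                               reference_copies = 2) {
  need <- c("sample_id", "assay_id", "assay_target", "total_droplets",
            "positive_droplets")
  stopifnot(all(need %in% names(assays)))
  out <- lapply(split(assays, assays$sample_id), function(a) {
    ref <- a[a$assay_target == "reference", , drop = FALSE]
    if (nrow(ref) == 0L)
      stop("sample ", a$sample_id[1L], " has no reference assay")
    lam_ref <- mean(poisson_lambda(ref$positive_droplets,
                                   ref$total_droplets))
    tg <- a[a$assay_target != "reference", , drop = FALSE]
    lam_t <- poisson_lambda(tg$positive_droplets, tg$total_droplets)
    cn <- copy_number_ratio(lam_t, lam_ref, reference_copies)
    data.frame(sample_id = tg$sample_id, assay_id = tg$assay_id,
               assay_target = tg$assay_target, lambda_target = lam_t,
               lambda_reference = lam_ref, copy_number = cn,
               classified_state = classify_cn(cn, rules))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genotype samples from droplet assays end to end
#'
#' Runs [ddpcr_copy_numbers()], forms per-region consensus states
#' ([multi_assay_consensus()]) for the segment unique to the larger
#' deletion and the shared segment, and maps the state pair to a
#' deletion genotype ([classify_genotype()]). Mean region copy numbers
#' accompany the call.
#'
#' @inheritParams ddpcr_copy_numbers
#' @return data.frame as returned by [classify_genotype()], one row per
#'   sample.
#' @export
ddpcr_genotype <- function(assays, rules = cn_state_ranges(),
                           reference_copies = 2) {
  cns <- ddpcr_copy_numbers(assays, rules, reference_copies)
  out <- lapply(split(cns, cns$sample_id), function(a) {
    uq <- a[a$assay_target == "del1_unique_region", , drop = FALSE]
    sh <- a[a$assay_target == "shared_region", , drop = FALSE]
    if (nrow(uq) == 0L || nrow(sh) == 0L)
      stop("sample ", a$sample_id[1L],
           ": need assays in both targeted regions")
    classify_genotype(
      unique_region_cn = mean(uq$copy_number),
      shared_region_cn = mean(sh$copy_number),
      rules = rules, sample_id = a$sample_id[1L],
      unique_state = multi_assay_consensus(uq$classified_state),
      shared_state = multi_assay_consensus(sh$classified_state))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read droplet assay tables as CSV
#'
#' @param assays Droplet assay data.frame.
#' @param path File path.
#' @return `path` invisibly / the data.frame.
#' @export
write_droplet_csv <- function(assays, path) {
  utils::write.csv(assays, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_droplet_csv
#' @export
read_droplet_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
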