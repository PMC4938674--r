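#' Write per-position depths as a samtools-depth-style TSV
#'
#' Columns: `chrom`, `pos` (1-based, as `samtools depth` prints), then
#' one depth column per sample. Soft-clip counts, when present, go to a
#' companion table via `write_softclip_tsv`.
#'
#' @param tracks Named list of `depth_track` objects of equal length.
#' @param path Output path.
#' @param chrom Chromosome label.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(tracks, path, chrom = "region") {
  stopifnot(length(tracks) >= 1L)
  n <- length(tracks[[1L]]$depth)
  df <- data.frame(chrom = chrom, pos = seq_len(n))
  for (id in names(tracks)) df[[id]] <- tracks[[id]]$depth
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
write_softclip_tsv <- function(tracks, path, chrom = "region") {
  n <- length(tracks[[1L]]$softclip)
  df <- data.frame(chrom = chrom, pos = seq_len(n))
  for (id in names(tracks)) df[[id]] <- tracks[[id]]$softclip
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth TSV back into depth tracks
#'
#' @param path Depth TSV written by [write_depth_tsv()] (or any
#'   chrom/pos/per-sample table with a header).
#' @param background_means Named numeric vector of genome background
#'   mean depths per sample; defaults to each sample's regional mean.
#' @return Named list of `depth_track` objects (soft-clip counts zero
#'   unless supplied via `softclip_path`).
#' @param softclip_path Optional companion soft-clip TSV.
#' @export
read_depth_tsv <- function(path, background_means = NULL,
                           softclip_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  samples <- setdiff(names(df), c("chrom", "pos"))
  clips <- NULL
  if (!is.null(softclip_path))
    clips <- utils::read.delim(softclip_path, check.names = FALSE)
  out <- lapply(samples, function(id) {
    depth <- as.integer(df[[id]])
    bg <- if (!is.null(background_means) && id %in% names(background_means))
      background_means[[id]] else mean(depth)
    structure(
      list(sample_id = id, depth = depth,
           softclip = if (!is.null(clips)) as.integer(clips[[id]])
                      else integer(length(depth)),
           background_mean = bg),
      class = "depth_track")
  })
  stats::setNames(out, samples)
}

#' Write / read SNP allele-count tables (TSV dialect)
#'
#' Long-format table with columns `sample_id`, `pos` (0-based, matching
#' the region model), `ref_count`, `alt_count`.
#'
#' @param table SNP count data.frame.
#' @param path File path.
#' @return `path` invisibly / the data.frame.
#' @export
write_snp_counts_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_counts_tsv
#' @export
read_snp_counts_tsv <- function(path) {
  utils::read.delim(path)
}

#' Read the first sequence of a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` for motif-run
#' scanning of assembly contigs.
#'
#' @param path FASTA path.
#' @return Character scalar.
#' @export
read_fasta_sequence <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  as.character(Biostrings::readDNAStringSet(path)[[1L]])
}
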