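#' Mean depth in fixed-width windows
#'
#' Tiles the region with half-open windows of `window_size` bp (the last
#' window may be shorter) and returns the mean per-position depth in
#' each.
#'
#' @param track A `depth_track` (or bare numeric depth vector).
#' @param window_size Window width in bp (default 1000).
#' @return data.frame `start`, `end`, `mean_depth`.
#' @export
window_mean_depth <- function(track, window_size = 1000L) {
  depth <- if (inherits(track, "depth_track")) track$depth else track
  if (length(depth) == 0L) stop("empty depth track")
  if (window_size < 1L) stop("window_size must be >= 1")
  n <- length(depth)
  window_size <- as.integer(window_size)
  nw <- as.integer(ceiling(n / window_size))
  starts <- (seq_len(nw) - 1L) * window_size
  ends <- pmin(starts + window_size, n)
  means <- vapply(seq_len(nw),
                  function(i) mean(depth[(starts[i] + 1L):ends[i]]),
                  numeric(1))
  data.frame(start = starts, end = ends, mean_depth = means)
}

#' Normalize window depths by the sample's genome background
#'
#' Divides each window mean by the sample's genome-wide average depth,
#' so a diploid window sits at 1.
#'
#' @param window_means Numeric vector of window mean depths.
#' @param background_mean Genome-wide mean depth of the sample; must be
#'   positive.
#' @return Numeric vector of normalized depths.
#' @export
normalize_depth <- function(window_means, background_mean) {
  if (!is.numeric(background_mean) || length(background_mean) != 1L ||
      background_mean <= 0)
    stop("background_mean must be a single positive number")
  window_means / background_mean
}

#' Copy number of a case relative to the control pool
#'
#' `2 * case_normalized / pool_normalized` where the pool has signal;
#' windows where the pool's normalized depth falls below
#' `min_pool_normalized` get `NA` (undefined, not zero): there the pool
#' itself lacks coverage (e.g. unassembled or repetitive sequence) and a
#' ratio would be inflated noise.
#'
#' @param case_normalized,pool_normalized Normalized window depths.
#' @param min_pool_normalized Minimum pool normalized depth required to
#'   form the ratio (default 0.2).
#' @return Numeric vector of copy numbers with `NA` where undefined.
#' @export
copy_number <- function(case_normalized, pool_normalized,
                        min_pool_normalized = 0.2) {
  stopifnot(length(case_normalized) == length(pool_normalized))
  if (any(case_normalized < 0, na.rm = TRUE) ||
      any(pool_normalized < 0, na.rm = TRUE))
    stop("normalized depths must be >= 0")
  ok <- !is.na(pool_normalized) & pool_normalized >= min_pool_normalized
  out <- rep(NA_real_, length(case_normalized))
  out[ok] <- 2 * case_normalized[ok] / pool_normalized[ok]
  out
}

#' Z-score of the pool's normalized depth across windows
#'
#' Standardizes the pool's normalized window depths by their mean and
#' sample standard deviation over all windows, the genome-wide moments
#' in the full-genome setting. Used to confirm pool depth uniformity:
#' a diploid pool should hover near Z = 0.
#'
#' @param pool_normalized Normalized pool depths over all windows
#'   (>= 2 values).
#' @return Numeric vector of Z-scores.
#' @export
pool_zscore <- function(pool_normalized) {
  x <- pool_normalized[!is.na(pool_normalized)]
  if (length(x) < 2L) stop("need >= 2 windows for a Z-score")
  s <- stats::sd(x)
  if (s == 0)
    stop("zero standard deviation across windows: degenerate (constant) input")
  (pool_normalized - mean(x)) / s
}

#' Windowed copy-number table for a case/pool experiment
#'
#' Runs the full windowed-depth computation: per-sample window means,
#' normalization by each sample's genome background mean, case copy
#' numbers relative to the pool, and the pool Z-score.
#'
#' @param tracks Named list of `depth_track` objects (cases and pool).
#' @param pool_id Name of the pool track in `tracks`.
#' @param window_size Window width in bp (default 1000).
#' @param min_pool_normalized Passed to [copy_number()].
#' @return An object of class `window_table`: list with `windows`
#'   (data.frame `start`, `end`), matrices `raw` and `normalized`
#'   (windows x samples), matrix `copy_number` (windows x cases),
#'   vector `pool_z`, and `pool_id`.
#' @examples
#' rm <- build_region_model(seed = 1)
#' trks <- list(
#'   case1 = simulate_depth(rm, sample_spec("case1", c("Del1", "WT")), seed = 2),
#'   pool = simulate_depth(rm, sample_spec("pool", mean_coverage = 56,
#'     pool_members = rep(list(c("WT", "WT")), 21)), seed = 3))
#' wt <- build_window_table(trks, pool_id = "pool")
#' summary(wt$copy_number[, "case1"])
#' @export
build_window_table <- function(tracks, pool_id, window_size = 1000L,
                               min_pool_normalized = 0.2) {
  if (!pool_id %in% names(tracks))
    stop("pool_id '", pool_id, "' not found among tracks")
  wm <- lapply(tracks, window_mean_depth, window_size = window_size)
  windows <- wm[[1L]][, c("start", "end")]
  raw <- vapply(wm, `[[`, numeric(nrow(windows)), "mean_depth")
  bg <- vapply(tracks, `[[`, numeric(1), "background_mean")
  normalized <- sweep(raw, 2L, bg, "/")
  case_ids <- setdiff(names(tracks), pool_id)
  cn <- vapply(case_ids, function(id)
    copy_number(normalized[, id], normalized[, pool_id],
                min_pool_normalized), numeric(nrow(windows)))
  cn <- matrix(cn, nrow = nrow(windows),
               dimnames = list(NULL, case_ids))
  structure(
    list(windows = windows, raw = raw, normalized = normalized,
         copy_number = cn, pool_z = pool_zscore(normalized[, pool_id]),
         pool_id = pool_id, window_size = as.integer(window_size)),
    class = "window_table"
  )
}

#' @export
print.window_table <- function(x, ...) {
  cat(sprintf("Window table: %d windows of %d bp; pool '%s'; cases: %s\n",
              nrow(x$windows), x$window_size, x$pool_id,
              paste(colnames(x$copy_number), collapse = ", ")))
  invisible(x)
}

#' Plot case copy numbers and the pool Z-score along the region
#'
#' @param x A `window_table`.
#' @param samples Case ids to draw (default: all).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.window_table <- function(x, samples = colnames(x$copy_number), ...) {
  mid <- (x$windows$start + x$windows$end) / 2 / 1000
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(NA, xlim = range(mid), ylim = c(0, 2.6),
                 xlab = "position (kb)", ylab = "copy number", ...)
  for (i in seq_along(samples))
    graphics::points(mid, x$copy_number[, samples[i]], pch = 16, cex = 0.4,
                     col = i + 1)
  graphics::legend("bottomleft", legend = samples, col = seq_along(samples) + 1,
                   pch = 16, cex = 0.7, bty = "n")
  graphics::plot(mid, x$pool_z, type = "h", xlab = "position (kb)",
                 ylab = "pool Z-score")
  invisible(x)
}

#' Write a window table as TSV / bedGraph
#'
#' The TSV carries, per window, each sample's raw and normalized depth,
#' each case's copy number and the pool Z-score. `write_bedgraph`
#' exports one sample's normalized depth as a 4-column bedGraph.
#'
#' @param wt A `window_table`.
#' @param path Output path.
#' @param chrom Chromosome label used in the coordinate columns.
#' @return The path, invisibly.
#' @export
write_window_table <- function(wt, path, chrom = "region") {
  df <- data.frame(chrom = chrom, start = wt$windows$start,
                   end = wt$windows$end)
  for (s in colnames(wt$raw)) df[[paste0(s, "_raw")]] <- wt$raw[, s]
  for (s in colnames(wt$normalized))
    df[[paste0(s, "_norm")]] <- wt$normalized[, s]
  for (s in colnames(wt$copy_number))
    df[[paste0(s, "_cn")]] <- wt$copy_number[, s]
  df$pool_z <- wt$pool_z
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_table
#' @param sample Sample id to export.
#' @export
write_bedgraph <- function(wt, sample, path, chrom = "region") {
  df <- data.frame(chrom = chrom, start = wt$windows$start,
                   end = wt$windows$end, value = wt$normalized[, sample])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
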