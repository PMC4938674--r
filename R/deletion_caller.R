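#' Call deletion segments from windowed copy numbers
#'
#' Classifies each window's copy number into a copy state with the same
#' numeric ranges used for ddPCR genotyping (see [classify_cn()]), then
#' merges consecutive windows of the same deletion state (0 or 1) into
#' maximal segments. Runs of ambiguous or undefined (`NA`) windows of
#' length up to `max_gap_windows` are bridged; a window classified as
#' state 2 — or as the other deletion state — always terminates a
#' segment. Segments supported by fewer than `min_windows` same-state
#' windows are dropped.
#'
#' Reported boundaries have window resolution: short-read data cannot
#' resolve these breakpoints to the base, as they sit in long tandem
#' repeats.
#'
#' @param copy_numbers Numeric vector of per-window copy numbers (`NA`
#'   where undefined).
#' @param windows data.frame with `start`, `end` (bp, half-open), sorted
#'   and non-overlapping, one row per copy number.
#' @param state_ranges Classification ranges, see [cn_state_ranges()].
#' @param max_gap_windows Ambiguous/undefined windows bridgeable inside
#'   a segment (default 2).
#' @param min_windows Minimum same-state windows per reported segment
#'   (default 3).
#' @param sample_id Optional id recorded in the output.
#' @return data.frame with one row per call: `sample_id`, `start`,
#'   `end`, `state` (0 or 1), `mean_cn`, `n_windows`.
#' @examples
#' w <- data.frame(start = 0:6 * 1000, end = 1:7 * 1000)
#' call_segments(c(2, 2, 0.1, 0.05, 0.2, 2, 2), w, min_windows = 3)
#' @export
call_segments <- function(copy_numbers, windows,
                          state_ranges = cn_state_ranges(),
                          max_gap_windows = 2L, min_windows = 3L,
                          sample_id = NA_character_) {
  stopifnot(length(copy_numbers) == nrow(windows))
  if (nrow(windows) > 1L) {
    if (is.unsorted(windows$start, strictly = TRUE) ||
        any(windows$start[-1L] < windows$end[-nrow(windows)]))
      stop("windows must be sorted and non-overlapping")
  }
  state <- classify_cn(copy_numbers, state_ranges)

  calls <- list()
  for (s in c("0", "1")) {
    idx <- which(!is.na(state) & state == s)
    if (length(idx) == 0L) next
    # group s-windows: join across gaps of only bridgeable windows
    grp <- cumsum(c(1L, vapply(seq_along(idx)[-1L], function(k) {
      gap <- idx[k] - idx[k - 1L] - 1L
      bridgeable <- gap == 0L ||
        (gap <= max_gap_windows && {
          between <- (idx[k - 1L] + 1L):(idx[k] - 1L)
          all(is.na(state[between]) | state[between] == "ambiguous")
        })
      if (bridgeable) 0L else 1L
    }, integer(1))))
    for (g in unique(grp)) {
      members <- idx[grp == g]
      if (length(members) < min_windows) next
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = sample_id,
        start = windows$start[members[1L]],
        end = windows$end[members[length(members)]],
        state = as.integer(s),
        mean_cn = mean(copy_numbers[members]),
        n_windows = length(members))
    }
  }
  if (length(calls) == 0L)
    return(data.frame(sample_id = character(0), start = integer(0),
                      end = integer(0), state = integer(0),
                      mean_cn = numeric(0), n_windows = integer(0)))
  out <- do.call(rbind, calls)
  out[order(out$start), , drop = FALSE]
}

#' Call deletions for every case in a window table
#'
#' @param wt A `window_table`.
#' @inheritParams call_segments
#' @return data.frame of calls over all case samples.
#' @export
call_deletions <- function(wt, state_ranges = cn_state_ranges(),
                           max_gap_windows = 2L, min_windows = 3L) {
  stopifnot(inherits(wt, "window_table"))
  out <- lapply(colnames(wt$copy_number), function(id)
    call_segments(wt$copy_number[, id], wt$windows, state_ranges,
                  max_gap_windows, min_windows, sample_id = id))
  do.call(rbind, out)
}

#' Write deletion calls as BED6
#'
#' Name column is `sample:state`; score is `round(100 * mean_cn)`.
#'
#' @param calls data.frame from [call_deletions()].
#' @param path Output path.
#' @param chrom Chromosome label.
#' @return `path`, invisibly.
#' @export
write_deletion_bed <- function(calls, path, chrom = "region") {
  bed <- data.frame(chrom = chrom, start = calls$start, end = calls$end,
                    name = paste0(calls$sample_id, ":", calls$state),
                    score = round(100 * calls$mean_cn), strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Soft-clip enrichment scan for breakpoint refinement
#'
#' Slides windows of `window_bp` over the region and tests whether the
#' soft-clipped read count in each window exceeds the background clip
#' rate, using the upper binomial tail on (clips, reads) with Bonferroni
#' control over all windows. Significant windows are grouped into
#' contiguous blocks and each block's best window is reported as a peak.
#' Zero-depth stretches are never significant (no reads, no evidence).
#'
#' @param clip Integer vector of per-position soft-clip counts.
#' @param depth Integer vector of per-position depths (same length;
#'   `clip <= depth` everywhere).
#' @param background_clip_rate Expected clip fraction away from
#'   breakpoints, in (0, 1).
#' @param window_bp Sliding window width (default 500).
#' @param step_bp Slide step (default `window_bp / 5`).
#' @param alpha Family-wise significance level after Bonferroni
#'   (default 0.01).
#' @return List with `windows` (data.frame `start`, `end`, `clips`,
#'   `reads`, `p`, `p_adj`) and `peaks` (data.frame `position`,
#'   `clips`, `reads`, `p_adj`).
#' @export
softclip_enrichment <- function(clip, depth, background_clip_rate = 0.01,
                                window_bp = 500L,
                                step_bp = max(1L, window_bp %/% 5L),
                                alpha = 0.01) {
  stopifnot(length(clip) == length(depth))
  if (any(clip > depth)) stop("clip count exceeds depth at some position")
  if (background_clip_rate <= 0 || background_clip_rate >= 1)
    stop("background_clip_rate must be in (0, 1)")
  n <- length(depth)
  starts <- seq.int(0L, max(0L, n - window_bp), by = step_bp)
  ends <- pmin(starts + window_bp, n)
  cs_clip <- c(0, cumsum(clip))
  cs_depth <- c(0, cumsum(depth))
  clips <- cs_clip[ends + 1L] - cs_clip[starts + 1L]
  reads <- cs_depth[ends + 1L] - cs_depth[starts + 1L]
  p <- stats::pbinom(clips - 1L, reads, background_clip_rate,
                     lower.tail = FALSE)
  p[reads == 0L] <- 1
  p_adj <- pmin(1, p * length(p))
  win <- data.frame(start = starts, end = ends, clips = clips,
                    reads = reads, p = p, p_adj = p_adj)

  sig <- which(p_adj < alpha)
  peaks <- data.frame(position = integer(0), clips = integer(0),
                      reads = integer(0), p_adj = numeric(0))
  if (length(sig) > 0L) {
    block <- cumsum(c(1L, as.integer(diff(sig) > 1L)))
    rows <- vapply(unique(block), function(b) {
      members <- sig[block == b]
      members[which.min(p[members])]
    }, integer(1))
    peaks <- data.frame(position = as.integer((starts[rows] + ends[rows]) %/% 2L),
                        clips = clips[rows], reads = reads[rows],
                        p_adj = p_adj[rows])
  }
  list(windows = win, peaks = peaks)
}

#' Find perfect tandem runs of a motif
#'
#' Scans a sequence left to right for maximal perfect tandem runs of
#' `motif` (whole copies, given strand only; no reverse-complement
#' search) and reports runs spanning at least `min_run_length_bp`.
#'
#' @param sequence Character scalar (e.g. a chromosome or contig).
#' @param motif Non-empty motif string, e.g. `"TGGA"`.
#' @param min_run_length_bp Minimum run length in bp (default 1000,
#'   the scale of the runs flanking the real breakpoints).
#' @return data.frame `start`, `end` (0-based half-open), `copies`.
#' @examples
#' find_motif_runs("TGGATGGATGGA", "TGGA", min_run_length_bp = 8)
#' @export
find_motif_runs <- function(sequence, motif, min_run_length_bp = 1000L) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  stopifnot(length(sequence) == 1L)
  pat <- paste0("(?:", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", motif), ")+")
  m <- gregexpr(pat, sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(0), end = integer(0),
                      copies = integer(0)))
  len <- attr(m, "match.length")
  keep <- len >= min_run_length_bp
  data.frame(start = as.integer(m[keep] - 1L),
             end = as.integer(m[keep] - 1L + len[keep]),
             copies = as.integer(len[keep] / nchar(motif)))
}

#' Annotate breakpoints with clip peaks and flanking repeat runs
#'
#' Combines the soft-clip enrichment peaks from a depth track with
#' motif-run annotation of a region sequence: each clip peak (or each
#' supplied breakpoint position) is reported with the nearest repeat run
#' within `flank_bp`.
#'
#' @param track A `depth_track`.
#' @param sequence Optional region sequence for motif-run scanning.
#' @param motif Repeat motif to scan for (default `"TGGA"`).
#' @param min_run_length_bp Minimum repeat run length (default 1000).
#' @param flank_bp Maximum distance between a peak and its flanking run
#'   (default 2000).
#' @inheritParams softclip_enrichment
#' @return data.frame `position`, `p_adj`, `repeat_start`, `repeat_end`,
#'   `repeat_copies` (`NA` where no run is within `flank_bp`).
#' @export
annotate_breakpoints <- function(track, sequence = NULL, motif = "TGGA",
                                 min_run_length_bp = 1000L,
                                 flank_bp = 2000L,
                                 background_clip_rate = 0.01,
                                 window_bp = 500L, alpha = 0.01) {
  stopifnot(inherits(track, "depth_track"))
  enr <- softclip_enrichment(track$softclip, track$depth,
                             background_clip_rate, window_bp, alpha = alpha)
  peaks <- enr$peaks
  runs <- if (!is.null(sequence))
    find_motif_runs(sequence, motif, min_run_length_bp)
  else data.frame(start = integer(0), end = integer(0), copies = integer(0))
  ann <- lapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks$position[i]
    if (nrow(runs) > 0L) {
      d <- pmax(runs$start - p, p - runs$end, 0L)
      j <- which.min(d)
      if (d[j] <= flank_bp)
        return(data.frame(position = p, p_adj = peaks$p_adj[i],
                          repeat_start = runs$start[j],
                          repeat_end = runs$end[j],
                          repeat_copies = runs$copies[j]))
    }
    data.frame(position = p, p_adj = peaks$p_adj[i],
               repeat_start = NA_integer_, repeat_end = NA_integer_,
               repeat_copies = NA_integer_)
  })
  if (length(ann) == 0L)
    return(data.frame(position = integer(0), p_adj = numeric(0),
                      repeat_start = integer(0), repeat_end = integer(0),
                      repeat_copies = integer(0)))
  do.call(rbind, ann)
}
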