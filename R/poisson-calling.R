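# Per-condition enrichment calling: window counts of the IP library are tested
# against a Poisson expectation taken from the scaled input library; windows
# with p < alpha are merged into peak regions.

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)` (inclusive tail; returns 1 when
#' `k = 0`). Numerically stable down to the smallest representable doubles.
#'
#' @param k Observed count(s), non-negative integers.
#' @param lambda Expected count(s), strictly positive (recycled).
#' @param inclusive If `FALSE`, compute the strict tail `P(X > k)` instead.
#' @return Vector of tail probabilities in (0, 1].
#' @examples
#' poisson_upper_tail(1, 1) # 1 - exp(-1)
#' @export
poisson_upper_tail <- function(k, lambda, inclusive = TRUE) {
  if (any(lambda <= 0)) abort("lambda must be > 0")
  if (any(k < 0) || any(k != floor(k))) abort("k must be a non-negative integer")
  shift <- if (inclusive) 1L else 0L
  ppois(k - shift, lambda, lower.tail = FALSE)
}

#' Expected-count track from a scaled input library
#'
#' The scaled input count of each window is the Poisson expectation for the IP
#' count; windows whose scaled input is exactly zero are set to the average
#' value over all windows (zeros included in the average).
#'
#' @param input_scaled Input window track already scaled to the IP total.
#' @param per_chromosome Impute zeros with per-chromosome means instead of the
#'   genome-wide mean.
#' @return Window track of Poisson expectations (all values > 0).
#' @export
expected_track <- function(input_scaled, per_chromosome = FALSE) {
  if (per_chromosome) {
    means <- input_scaled |>
      group_by(.data$chrom) |>
      summarise(m = mean(.data$count), .groups = "drop")
    mvec <- setNames(means$m, means$chrom)[input_scaled$chrom]
  } else {
    mvec <- rep(mean(input_scaled$count), nrow(input_scaled))
  }
  if (any(mvec <= 0)) abort("mean input count is zero; cannot form expectations")
  input_scaled$count <- ifelse(input_scaled$count == 0, mvec, input_scaled$count)
  input_scaled
}

#' Per-window Poisson enrichment test
#'
#' @param ip_track IP window track (integer counts).
#' @param lambda_track Expectation track from [expected_track()], on the same
#'   grid.
#' @param alpha Significance threshold; a window is significant iff
#'   `p < alpha` (strict).
#' @param inclusive Passed to [poisson_upper_tail()].
#' @return Tibble of per-window calls: `chrom`, `start`, `end`, `ip_count`,
#'   `expected`, `p_value`, `significant`, with the grid width as attribute.
#' @export
call_windows <- function(ip_track, lambda_track, alpha = 1e-6, inclusive = TRUE) {
  stopifnot_same_grid(ip_track, lambda_track)
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  calls <- tibble(
    chrom = ip_track$chrom,
    start = ip_track$start,
    end = ip_track$end,
    ip_count = ip_track$count,
    expected = lambda_track$count,
    p_value = poisson_upper_tail(ip_track$count, lambda_track$count, inclusive)
  )
  calls$significant <- calls$p_value < alpha
  attr(calls, "width") <- track_width(ip_track)
  calls
}

#' Merge significant windows into peak regions
#'
#' Maximal runs of significant windows separated by at most `merge_gap`
#' non-significant windows become one region; the smallest constituent p-value
#' and the number of significant windows are recorded.
#'
#' @param calls Per-window calls from [call_windows()], sorted by position.
#' @param merge_gap Number of tolerated non-significant windows inside a
#'   region.
#' @return Tibble of regions: `chrom`, `start`, `end`, `n_windows`, `min_p`.
#' @export
merge_significant <- function(calls, merge_gap = 0L) {
  ord <- order(match(calls$chrom, unique(calls$chrom)), calls$start)
  if (is.unsorted(ord, strictly = TRUE)) {
    abort("calls must be sorted by chromosome and position")
  }
  width <- attr(calls, "width")
  sig <- calls[calls$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), min_p = numeric()))
  }
  widx <- sig$start %/% width
  new_run <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                 diff(widx) > merge_gap + 1L)
  run_id <- cumsum(new_run)
  sig |>
    mutate(run = run_id) |>
    group_by(.data$run) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      n_windows = n(),
      min_p = min(.data$p_value),
      .groups = "drop"
    ) |>
    select("chrom", "start", "end", "n_windows", "min_p")
}

#' Empirical false discovery rate
#'
#' Ratio of the number of peaks found when comparing two null libraries (input
#' vs input) to the number found in the real IP vs input comparison.
#'
#' @param null_peaks Peak count from the null comparison.
#' @param observed_peaks Peak count from the IP comparison; must be >= 1.
#' @return `null_peaks / observed_peaks`.
#' @export
empirical_fdr <- function(null_peaks, observed_peaks) {
  if (observed_peaks < 1) abort("FDR undefined when no observed peaks")
  null_peaks / observed_peaks
}

#' Call enriched regions for one IP/input library pair
#'
#' The full per-condition pipeline: deduplicate both libraries, extend reads,
#' count on the window grid, scale the input total to the IP total, form the
#' Poisson expectation track (zeros imputed with the genome-wide mean), test
#' every window and merge significant windows into peak regions.
#'
#' @param ip_reads,input_reads Read tibbles (see [read_reads_bed()]).
#' @param genome Genome tibble.
#' @param window Window width in bp.
#' @param extension Read extension in bp.
#' @param alpha Per-window significance threshold (strict `p < alpha`).
#' @param merge_gap Tolerated non-significant windows inside a region.
#' @param ignore_strand Passed to [deduplicate_reads()].
#' @return A `peak_calls` object; `tidy()` returns the peak regions, `glance()`
#'   a one-row summary, `$calls` the per-window table.
#' @export
call_peaks <- function(ip_reads, input_reads, genome, window = 100,
                       extension = 150, alpha = 1e-6, merge_gap = 0L,
                       ignore_strand = FALSE) {
  ip_track <- ip_reads |>
    deduplicate_reads(ignore_strand = ignore_strand) |>
    extend_reads(genome, extension = extension) |>
    count_windows(genome, width = window)
  input_track <- input_reads |>
    deduplicate_reads(ignore_strand = ignore_strand) |>
    extend_reads(genome, extension = extension) |>
    count_windows(genome, width = window)
  lambda <- input_track |>
    scale_to_total(track_total(ip_track)) |>
    expected_track()
  calls <- call_windows(ip_track, lambda, alpha = alpha)
  peaks <- merge_significant(calls, merge_gap = merge_gap)
  structure(
    list(
      calls = calls,
      peaks = peaks,
      params = list(window = window, extension = extension, alpha = alpha,
                    merge_gap = merge_gap),
      totals = list(ip = track_total(ip_track), input_raw = track_total(input_track))
    ),
    class = "peak_calls"
  )
}

#' @export
print.peak_calls <- function(x, ...) {
  cat("<peak_calls>\n")
  cat("  windows tested: ", nrow(x$calls),
      " (width ", x$params$window, " bp)\n", sep = "")
  cat("  significant windows (p < ", format(x$params$alpha), "): ",
      sum(x$calls$significant), "\n", sep = "")
  cat("  peak regions: ", nrow(x$peaks), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.peak_calls <- function(x, ...) {
  x$peaks
}

#' @exportS3Method generics::glance
glance.peak_calls <- function(x, ...) {
  tibble(
    n_windows = nrow(x$calls),
    n_significant = sum(x$calls$significant),
    n_peaks = nrow(x$peaks),
    ip_total = x$totals$ip,
    input_total = x$totals$input_raw,
    alpha = x$params$alpha
  )
}

#' Write peak regions as BED4 (chrom, start, end, min_p)
#'
#' @param peaks Peak region tibble from [merge_significant()] or
#'   `tidy(peak_calls)`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_peaks_bed <- function(peaks, file) {
  out <- peaks[, c("chrom", "start", "end", "min_p")]
  out$min_p <- formatC(out$min_p, format = "e", digits = 3)
  readr::write_tsv(out, file, col_names = FALSE)
  invisible(file)
}

#' Per-gene mark presence
#'
#' A mark is present on a gene iff any peak region overlaps the gene's
#' territory (strand-aware `[TSS - upstream, TES]`) by at least 1 bp.
#'
#' @param genes Gene tibble.
#' @param peaks Peak region tibble.
#' @param genome Genome tibble.
#' @param upstream Promoter extension upstream of the TSS, bp.
#' @return `genes` with a logical `present` column added.
#' @export
gene_presence <- function(genes, peaks, genome, upstream = 500) {
  territory <- gene_territory(genes, genome, upstream = upstream)
  present <- rep(FALSE, nrow(genes))
  if (nrow(peaks) > 0L && nrow(genes) > 0L) {
    hits <- GenomicRanges::findOverlaps(
      intervals_to_granges(territory),
      intervals_to_granges(peaks),
      minoverlap = 1L
    )
    present[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  genes$present <- present
  genes
}
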