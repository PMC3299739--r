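# Two-stage differential detection between the two conditions' IP libraries of
# one mark. Stage 1 discards bins that are background noise in both libraries
# or locally biased in both inputs; stage 2 quantile-normalizes the retained
# bins and labels bins whose pseudocounted fold change reaches tau, merging
# same-direction runs into differential regions.

#' Stage-1 background and bias filter
#'
#' A 200-bp bin is retained iff at least one IP library's count is
#' significantly above that library's genome-wide mean bin count (Poisson
#' upper tail `< stage1_alpha`), and the bin is not flagged as locally biased
#' (both scaled input tracks above `c_bias` times their genome-wide means).
#'
#' @param bins Tibble with columns `count_a`, `count_b` (IP bin counts) and,
#'   when `bias_filter` is used, `input_a`, `input_b` (scaled input bin
#'   counts).
#' @param stage1_alpha Significance level of the background-noise test.
#' @param c_bias Bias multiplier threshold.
#' @param bias_filter Disable to reproduce a reading of the procedure that
#'   uses the IP libraries only.
#' @return `bins` with a logical `retained` column added.
#' @export
stage1_filter <- function(bins, stage1_alpha = 0.01, c_bias = 5,
                          bias_filter = TRUE) {
  lam_a <- mean(bins$count_a)
  lam_b <- mean(bins$count_b)
  if (lam_a <= 0 || lam_b <= 0) abort("an IP library has zero mean bin count")
  noise_ok <- poisson_upper_tail(bins$count_a, lam_a) < stage1_alpha |
    poisson_upper_tail(bins$count_b, lam_b) < stage1_alpha
  if (bias_filter) {
    if (!all(c("input_a", "input_b") %in% names(bins))) {
      abort("bias_filter requires input_a and input_b columns")
    }
    biased <- bins$input_a > c_bias * mean(bins$input_a) &
      bins$input_b > c_bias * mean(bins$input_b)
  } else {
    biased <- FALSE
  }
  bins$retained <- noise_ok & !biased
  bins
}

#' Two-sample quantile normalization
#'
#' Both vectors are mapped rank-wise onto the mean of the two order
#' statistics, making their empirical distributions identical; tied values
#' receive the mean of the reference values over the tied ranks.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A list with components `a` and `b` (the normalized vectors).
#' @examples
#' quantile_normalize(c(1, 2, 3), c(2, 4, 6)) # both become 1.5, 3, 4.5
#' @export
quantile_normalize <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  if (length(a) == 0L) return(list(a = numeric(), b = numeric()))
  ref <- (sort(a) + sort(b)) / 2
  map_one <- function(x) {
    out <- ref[rank(x, ties.method = "first")]
    # ties: average the reference values across the tied ranks
    stats::ave(out, match(x, x), FUN = mean)
  }
  list(a = map_one(a), b = map_one(b))
}

#' Label differential bins by pseudocounted fold change
#'
#' A bin is `higher_in_A` iff `(norm_a + pc) / (norm_b + pc) >= tau`,
#' `higher_in_B` for the reciprocal, otherwise unlabeled (`NA`).
#'
#' @param bins Tibble with `norm_a`, `norm_b` columns (normalized bin values).
#' @param tau Fold-change threshold (> 1).
#' @param pseudocount Stabilizer added to both values.
#' @return `bins` with `direction` (character or `NA`) and `log2_fold`
#'   (signed, A over B) columns added.
#' @export
call_differential_bins <- function(bins, tau = 2, pseudocount = 1) {
  if (tau <= 1) abort("tau must be > 1")
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  ratio <- (bins$norm_a + pseudocount) / (bins$norm_b + pseudocount)
  bins$log2_fold <- log2(ratio)
  bins$direction <- dplyr::case_when(
    ratio >= tau ~ "higher_in_A",
    1 / ratio >= tau ~ "higher_in_B",
    .default = NA_character_
  )
  bins
}

#' Merge labeled bins into directional differential regions
#'
#' Maximal runs of same-direction bins (separated by at most `merge_gap`
#' unlabeled or discarded bins) are merged; bins of opposite direction are
#' never merged.
#'
#' @param bins Tibble from [call_differential_bins()] with `chrom`, `start`,
#'   `end`, `direction`, `log2_fold`, sorted by position, plus attribute or
#'   argument `width` giving the bin width.
#' @param width Bin width in bp.
#' @param merge_gap Tolerated unlabeled bins inside a region.
#' @return Tibble of regions: `chrom`, `start`, `end`, `direction`,
#'   `mean_log2_fold` (mean of constituent bins' signed log2 ratios),
#'   `n_bins`.
#' @export
merge_directional <- function(bins, width, merge_gap = 0L) {
  lab <- bins[!is.na(bins$direction), , drop = FALSE]
  if (nrow(lab) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  direction = character(), mean_log2_fold = numeric(),
                  n_bins = integer()))
  }
  widx <- lab$start %/% width
  n <- nrow(lab)
  new_run <- c(TRUE,
               lab$chrom[-1] != lab$chrom[-n] |
                 diff(widx) > merge_gap + 1L |
                 lab$direction[-1] != lab$direction[-n])
  run_id <- cumsum(new_run)
  lab |>
    mutate(run = run_id) |>
    group_by(.data$run) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      direction = .data$direction[1],
      mean_log2_fold = mean(.data$log2_fold),
      n_bins = n(),
      .groups = "drop"
    ) |>
    select("chrom", "start", "end", "direction", "mean_log2_fold", "n_bins")
}

#' Two-stage differential-region detection between two conditions
#'
#' Counts both conditions' IP and input libraries on a shared bin grid
#' (dedup + extend + count), scales each input to its IP total, applies the
#' stage-1 background/bias filter, quantile-normalizes the retained bins and
#' calls directional differential regions at fold-change threshold `tau`.
#'
#' @param ip_a,input_a,ip_b,input_b Read tibbles for the two conditions.
#' @param genome Genome tibble.
#' @param bin Bin width in bp.
#' @param extension Read extension in bp.
#' @param tau Fold-change threshold.
#' @param pseudocount Stabilizer for fold changes.
#' @param stage1_alpha,c_bias,bias_filter Stage-1 parameters
#'   (see [stage1_filter()]).
#' @param merge_gap Tolerated unlabeled bins inside a region.
#' @return A `chipnorm_fit` object; `tidy()` returns the differential regions,
#'   `glance()` a one-row summary, `$bins` the per-bin table.
#' @export
chipnorm <- function(ip_a, input_a, ip_b, input_b, genome, bin = 200,
                     extension = 150, tau = 2, pseudocount = 1,
                     stage1_alpha = 0.01, c_bias = 5, bias_filter = TRUE,
                     merge_gap = 0L) {
  count_lib <- function(reads) {
    reads |>
      deduplicate_reads() |>
      extend_reads(genome, extension = extension) |>
      count_windows(genome, width = bin)
  }
  t_ip_a <- count_lib(ip_a)
  t_ip_b <- count_lib(ip_b)
  t_in_a <- count_lib(input_a) |> scale_to_total(track_total(t_ip_a))
  t_in_b <- count_lib(input_b) |> scale_to_total(track_total(t_ip_b))
  stopifnot_same_grid(t_ip_a, t_ip_b)

  bins <- tibble(
    chrom = t_ip_a$chrom, start = t_ip_a$start, end = t_ip_a$end,
    count_a = t_ip_a$count, count_b = t_ip_b$count,
    input_a = t_in_a$count, input_b = t_in_b$count
  )
  bins <- stage1_filter(bins, stage1_alpha = stage1_alpha, c_bias = c_bias,
                        bias_filter = bias_filter)
  bins$norm_a <- NA_real_
  bins$norm_b <- NA_real_
  kept <- which(bins$retained)
  if (length(kept) > 0L) {
    qn <- quantile_normalize(bins$count_a[kept], bins$count_b[kept])
    bins$norm_a[kept] <- qn$a
    bins$norm_b[kept] <- qn$b
  }
  bins$direction <- NA_character_
  bins$log2_fold <- NA_real_
  if (length(kept) > 0L) {
    called <- call_differential_bins(bins[kept, ], tau = tau,
                                     pseudocount = pseudocount)
    bins$direction[kept] <- called$direction
    bins$log2_fold[kept] <- called$log2_fold
  }
  regions <- merge_directional(bins, width = bin, merge_gap = merge_gap)
  structure(
    list(
      bins = bins,
      regions = regions,
      params = list(bin = bin, extension = extension, tau = tau,
                    pseudocount = pseudocount, stage1_alpha = stage1_alpha,
                    c_bias = c_bias, bias_filter = bias_filter,
                    merge_gap = merge_gap)
    ),
    class = "chipnorm_fit"
  )
}

#' @export
print.chipnorm_fit <- function(x, ...) {
  cat("<chipnorm_fit>\n")
  cat("  bins: ", nrow(x$bins), " (", x$params$bin, " bp), retained: ",
      sum(x$bins$retained), "\n", sep = "")
  cat("  differential bins: ", sum(!is.na(x$bins$direction)),
      " at tau = ", x$params$tau, "\n", sep = "")
  cat("  regions: ", nrow(x$regions),
      " (higher_in_A: ", sum(x$regions$direction == "higher_in_A"),
      ", higher_in_B: ", sum(x$regions$direction == "higher_in_B"), ")\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chipnorm_fit <- function(x, ...) {
  x$regions
}

#' @exportS3Method generics::glance
glance.chipnorm_fit <- function(x, ...) {
  tibble(
    n_bins = nrow(x$bins),
    n_retained = sum(x$bins$retained),
    n_differential_bins = sum(!is.na(x$bins$direction)),
    n_regions = nrow(x$regions),
    tau = x$params$tau
  )
}

#' Write differential regions as BED9
#'
#' Name carries the direction, score is `round(100 * |mean_log2_fold|)`, and
#' itemRgb follows the browser convention: red for regions higher at
#' condition A, green for regions higher at condition B.
#'
#' @param regions Differential-region tibble from `tidy(chipnorm_fit)`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_differential_bed <- function(regions, file) {
  out <- tibble(
    chrom = regions$chrom,
    start = regions$start,
    end = regions$end,
    name = regions$direction,
    score = round(100 * abs(regions$mean_log2_fold)),
    strand = ".",
    thickStart = regions$start,
    thickEnd = regions$end,
    itemRgb = ifelse(regions$direction == "higher_in_A", "255,0,0", "0,255,0")
  )
  readr::write_tsv(out, file, col_names = FALSE)
  invisible(file)
}
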