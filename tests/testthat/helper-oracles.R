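# Independent oracles and small fixture builders shared across the suite.

# Poisson upper tail P(X >= k) by direct log-space series summation
# (log-sum-exp over terms computed from lgamma); independent of stats::ppois.
oracle_poisson_tail <- function(k, lambda, n_terms = 1500L) {
  i <- k + seq_len(n_terms) - 1L
  lt <- i * log(lambda) - lambda - lgamma(i + 1)
  m <- max(lt)
  exp(m) * sum(exp(lt - m))
}

# Brute-force per-base rasterization: which windows does a fragment touch?
oracle_windows_touched <- function(start, end, width) {
  unique((seq(start, end - 1L)) %/% width)
}

toy_genome <- function(lengths = c(chrT = 30000L)) {
  tibble::tibble(chrom = names(lengths), length = as.integer(lengths))
}

make_reads <- function(chrom, start, end, strand, name = NULL, score = 0) {
  n <- length(start)
  tibble::tibble(
    chrom = rep_len(chrom, n), start = as.integer(start),
    end = as.integer(end),
    name = if (is.null(name)) sprintf("r%03d", seq_len(n)) else name,
    score = rep_len(score, n), strand = rep_len(strand, n)
  )
}

# A window track with prescribed counts, built on the real scaffold.
make_track <- function(genome, width, counts) {
  tr <- count_windows(tibble::tibble(chrom = character(), start = integer(),
                                     end = integer()), genome, width)
  stopifnot(length(counts) == nrow(tr))
  tr$count <- counts
  tr
}

# Fraction of rows of x overlapped (>= 1 bp) by any row of y; both tibbles
# with chrom/start/end in 0-based half-open coordinates.
frac_overlapping <- function(x, y) {
  if (nrow(x) == 0L) return(NA_real_)
  if (nrow(y) == 0L) return(0)
  gx <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
  gy <- GenomicRanges::GRanges(y$chrom, IRanges::IRanges(y$start + 1L, y$end))
  mean(GenomicRanges::countOverlaps(gx, gy) > 0)
}

# Number of rows of x overlapped (>= 1 bp) by any row of y.
n_overlapping <- function(x, y) {
  if (nrow(x) == 0L) return(0L)
  round(frac_overlapping(x, y) * nrow(x))
}

# Planted-category truth for one mark, in the observable category notation.
planted_categories <- function(truth, mark = "K4") {
  state <- if (mark == "K4") truth$k4_state else truth$k27_state
  dplyr::case_when(
    state == "both" ~ paste0(mark, "-", mark),
    state == "a_only" ~ paste0(mark, "-None"),
    state == "b_only" ~ paste0("None-", mark),
    .default = "None-None"
  )
}
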