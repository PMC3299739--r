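# Window tracks are tibbles (chrom, start, end, count) covering every window of
# a fixed-width grid anchored at coordinate 0 of each chromosome; the last
# window of a chromosome may be truncated. Attribute "width" records the grid.

new_window_track <- function(df, width) {
  attr(df, "width") <- as.integer(width)
  class(df) <- unique(c("window_track", class(df)))
  df
}

track_width <- function(track) {
  w <- attr(track, "width")
  if (is.null(w)) abort("not a window track (missing width attribute)")
  w
}

#' Total count of a window track
#'
#' @param track A window track from [count_windows()].
#' @return Sum of all window counts (the library total after counting).
#' @export
track_total <- function(track) {
  sum(track$count)
}

window_scaffold <- function(genome, width) {
  validate_genome(genome)
  width <- as.integer(width)
  if (width < 1L) abort("window width must be >= 1")
  nwin <- as.integer(ceiling(genome$length / width))
  chrom <- rep(genome$chrom, nwin)
  win <- sequence(nwin) - 1L
  start <- win * width
  end <- pmin(start + width, rep(as.integer(genome$length), nwin))
  tibble(chrom = chrom, start = as.integer(start), end = as.integer(end))
}

#' Remove duplicate reads
#'
#' Reads mapping to the same location are counted once to suppress clonal
#' (PCR) amplification. The duplicate key is (chrom, start, strand); set
#' `ignore_strand = TRUE` for the stricter position-only key.
#'
#' @param reads Read tibble from [read_reads_bed()].
#' @param ignore_strand Collapse the two strands onto one key.
#' @return Deduplicated reads, sorted by chrom, start, strand (deterministic).
#' @export
deduplicate_reads <- function(reads, ignore_strand = FALSE) {
  keys <- if (ignore_strand) c("chrom", "start") else c("chrom", "start", "strand")
  reads |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keys)), .keep_all = TRUE) |>
    arrange(.data$chrom, .data$start, .data$strand)
}

#' Extend reads in the 3' direction
#'
#' Each read is extended by `extension` bases beyond its 3' end to approximate
#' the sequenced fragment: a `+` read becomes `[start, end + extension)`, a `-`
#' read `[start - extension, end)`, clipped to the chromosome.
#'
#' @param reads Read tibble.
#' @param genome Genome tibble (for clipping).
#' @param extension Bases added beyond the 3' end.
#' @return A fragment tibble (`chrom`, `start`, `end`, `strand`).
#' @export
extend_reads <- function(reads, genome, extension = 150) {
  validate_genome(genome)
  lookup <- chrom_length_lookup(genome)
  start <- ifelse(reads$strand == "+", reads$start, reads$start - extension)
  end <- ifelse(reads$strand == "+", reads$end + extension, reads$end)
  tibble(
    chrom = reads$chrom,
    start = as.integer(pmax(0, start)),
    end = as.integer(pmin(lookup[reads$chrom], end)),
    strand = reads$strand
  )
}

#' Count fragments on a fixed-width window grid
#'
#' Every window receives +1 for each fragment overlapping it by at least 1 bp
#' (half-open semantics), so a fragment spanning several windows increments
#' each of them.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`), e.g. from
#'   [extend_reads()].
#' @param genome Genome tibble.
#' @param width Window width in bp (100 for enrichment calling, 200 for
#'   differential binning).
#' @return A window track: tibble (`chrom`, `start`, `end`, `count`) covering
#'   the whole genome, with attribute `width`.
#' @export
count_windows <- function(fragments, genome, width = 100) {
  scaffold <- window_scaffold(genome, width)
  width <- as.integer(width)
  nwin_per_chrom <- as.integer(ceiling(genome$length / width))
  offsets <- setNames(c(0L, cumsum(nwin_per_chrom))[seq_len(nrow(genome))],
                      genome$chrom)
  total_windows <- sum(nwin_per_chrom)
  if (nrow(fragments) == 0L) {
    counts <- numeric(total_windows)
  } else {
    validate_intervals(fragments, genome, what = "fragment")
    first <- fragments$start %/% width
    last <- (fragments$end - 1L) %/% width
    nper <- last - first + 1L
    ids <- sequence(nper, from = offsets[fragments$chrom] + first + 1L)
    counts <- as.numeric(tabulate(ids, nbins = total_windows))
  }
  scaffold$count <- counts
  new_window_track(scaffold, width)
}

#' Scale a track to a target library total
#'
#' Multiplies every window count by `target_total / track_total(track)`; used
#' to normalize the input library total to equal the immunoprecipitate's.
#'
#' @param track Window track.
#' @param target_total Desired total (usually the IP library total).
#' @return Scaled track (real-valued counts).
#' @export
scale_to_total <- function(track, target_total) {
  current <- track_total(track)
  if (current <= 0) abort("cannot scale a track with zero total")
  track$count <- track$count * (target_total / current)
  track
}

#' Sum adjacent windows into wider bins
#'
#' Coverage-style aggregation: counts of `factor` adjacent windows are summed.
#' Note this is not identical to counting fragments directly on the wider grid
#' (a fragment straddling an interior boundary of the wide bin is counted once
#' per constituent window here, but once in direct counting); the differential
#' pipeline therefore counts directly at its own bin width.
#'
#' @param track Window track.
#' @param factor Number of adjacent windows per output bin.
#' @return A window track on the `factor`-times-wider grid.
#' @export
rebin_track <- function(track, factor = 2L) {
  width <- track_width(track)
  factor <- as.integer(factor)
  out <- track |>
    mutate(bin = .data$start %/% (width * factor)) |>
    group_by(.data$chrom, .data$bin) |>
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      count = sum(.data$count),
      .groups = "drop"
    ) |>
    arrange(match(.data$chrom, unique(track$chrom)), .data$start) |>
    select("chrom", "start", "end", "count")
  new_window_track(out, width * factor)
}

stopifnot_same_grid <- function(a, b) {
  if (track_width(a) != track_width(b) || nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) || !identical(a$start, b$start)) {
    abort("tracks are not on the same window grid")
  }
  invisible(NULL)
}

#' Write a window track as bedGraph
#'
#' Zero-valued windows are omitted; [read_bedgraph()] reconstructs them from
#' the genome.
#'
#' @param track Window track.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bedgraph <- function(track, file) {
  nz <- track[track$count != 0, c("chrom", "start", "end", "count")]
  readr::write_tsv(nz, file, col_names = FALSE)
  invisible(file)
}

#' Read a bedGraph written by [write_bedgraph()] back into a full track
#'
#' @param file bedGraph path.
#' @param genome Genome tibble.
#' @param width Window width of the original grid.
#' @return Window track with zero windows restored.
#' @export
read_bedgraph <- function(file, genome, width) {
  scaffold <- window_scaffold(genome, width)
  scaffold$count <- 0
  cols <- readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), count = readr::col_double()
  )
  nz <- readr::read_tsv(file, col_names = c("chrom", "start", "end", "count"),
                        col_types = cols, progress = FALSE)
  if (nrow(nz) > 0L) {
    key_all <- paste(scaffold$chrom, scaffold$start)
    idx <- match(paste(nz$chrom, nz$start), key_all)
    if (anyNA(idx)) abort("bedGraph record does not lie on the window grid")
    scaffold$count[idx] <- nz$count
  }
  new_window_track(scaffold, width)
}

#' Average signal around transcription start sites
#'
#' Bins of the track's window width tile `[-flank, +flank)` around each gene's
#' TSS; minus-strand genes are reflected so positive offsets are always
#' downstream (in the direction of transcription). Each bin's value is the
#' track count of the window containing the bin's midpoint; bins falling off
#' the chromosome are dropped from that gene's contribution.
#'
#' @param track Window track.
#' @param genes Gene tibble.
#' @param genome Genome tibble.
#' @param flank Half-width of the profiled region in bp; must be a multiple of
#'   the track's window width.
#' @return A `tss_profile` tibble: `offset` (bp of bin start relative to TSS),
#'   `signal` (mean count), `n_genes` (genes contributing to the bin).
#' @export
tss_profile <- function(track, genes, genome, flank = 10000) {
  if (nrow(genes) == 0L) abort("tss_profile requires at least one gene")
  width <- track_width(track)
  if (flank %% width != 0) abort("flank must be a multiple of the window width")
  nbin <- 2L * (flank %/% width)
  offsets_bp <- (seq_len(nbin) - 1L - nbin %/% 2L) * width
  lookup <- chrom_length_lookup(genome)
  nwin_per_chrom <- as.integer(ceiling(genome$length / width))
  chrom_offsets <- setNames(c(0L, cumsum(nwin_per_chrom))[seq_len(nrow(genome))],
                            genome$chrom)

  sign <- ifelse(genes$strand == "+", 1L, -1L)
  # midpoint of each (gene, bin): TSS + strand-aware offset + half bin
  mid <- outer(genes$tss, rep(1, nbin)) +
    outer(sign, offsets_bp + width / 2)
  chrom_rep <- matrix(rep(genes$chrom, nbin), ncol = nbin)
  ok <- mid >= 0 & mid < matrix(lookup[chrom_rep], ncol = nbin)
  widx <- chrom_offsets[chrom_rep] + floor(mid / width) + 1L
  vals <- matrix(NA_real_, nrow = nrow(genes), ncol = nbin)
  vals[ok] <- track$count[widx[ok]]

  out <- tibble(
    offset = offsets_bp,
    signal = colMeans(vals, na.rm = TRUE),
    n_genes = colSums(!is.na(vals))
  )
  class(out) <- unique(c("tss_profile", class(out)))
  attr(out, "flank") <- flank
  attr(out, "width") <- width
  out
}
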