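# Joins peak and differential calls onto gene models: per-gene mark states and
# their four-way categories, bivalency transitions, expression-quintile
# partition and cross-tabulation, and TSS-relative histograms of differential
# regions.

#' Gene territory for presence assignment
#'
#' Strand-aware interval from `TSS - upstream` to the TES, clipped to the
#' chromosome. H3K4me3 peaks sit at/just downstream of the TSS and H3K27me3
#' covers gene bodies, so one territory serves both marks by default.
#'
#' @param genes Gene tibble.
#' @param genome Genome tibble.
#' @param upstream Upstream extension in bp.
#' @return Tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
gene_territory <- function(genes, genome, upstream = 500) {
  lookup <- chrom_length_lookup(genome)
  start <- ifelse(genes$strand == "+", genes$start - upstream, genes$start)
  end <- ifelse(genes$strand == "+", genes$end, genes$end + upstream)
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = as.integer(pmax(0, start)),
    end = as.integer(pmin(lookup[genes$chrom], end))
  )
}

#' Four-way mark-state category
#'
#' Maps per-condition presence of a mark to the category strings used for the
#' state tables, e.g. `"K4-K4"` (present at both conditions), `"K4-None"`
#' (lost), `"None-K4"` (gained), `"None-None"`.
#'
#' @param present_a,present_b Logical vectors: mark present at condition A/B.
#' @param mark Mark label, e.g. `"K4"` or `"K27"`.
#' @return Character vector of categories.
#' @export
classify_state <- function(present_a, present_b, mark) {
  paste0(
    ifelse(present_a, mark, "None"), "-",
    ifelse(present_b, mark, "None")
  )
}

#' Per-gene mark state table for one mark
#'
#' Calls presence at both conditions over the gene territory, derives the
#' four-way category, and records whether an asymmetric category is supported
#' by an overlapping, direction-consistent differential region (`higher_in_A`
#' for a lost mark, `higher_in_B` for a gained one).
#'
#' @param genes Gene tibble.
#' @param peaks_a,peaks_b Peak-region tibbles for conditions A and B.
#' @param mark Mark label.
#' @param genome Genome tibble.
#' @param diff_regions Optional differential-region tibble
#'   (`tidy(chipnorm_fit)`) used for `diff_supported`.
#' @param upstream Territory upstream extension in bp.
#' @return Tibble `gene_id`, `mark`, `present_a`, `present_b`, `category`,
#'   `diff_supported`.
#' @export
mark_state_table <- function(genes, peaks_a, peaks_b, mark, genome,
                             diff_regions = NULL, upstream = 500) {
  pa <- gene_presence(genes, peaks_a, genome, upstream = upstream)$present
  pb <- gene_presence(genes, peaks_b, genome, upstream = upstream)$present
  states <- tibble(
    gene_id = genes$gene_id,
    mark = mark,
    present_a = pa,
    present_b = pb,
    category = classify_state(pa, pb, mark)
  )
  states$diff_supported <- NA
  if (!is.null(diff_regions)) {
    territory <- gene_territory(genes, genome, upstream = upstream)
    overlap_dir <- function(direction) {
      out <- rep(FALSE, nrow(genes))
      reg <- diff_regions[diff_regions$direction == direction, , drop = FALSE]
      if (nrow(reg) > 0L && nrow(genes) > 0L) {
        hits <- GenomicRanges::findOverlaps(
          intervals_to_granges(territory), intervals_to_granges(reg)
        )
        out[unique(S4Vectors::queryHits(hits))] <- TRUE
      }
      out
    }
    lost <- pa & !pb
    gained <- !pa & pb
    states$diff_supported <- NA
    states$diff_supported[lost] <- overlap_dir("higher_in_A")[lost]
    states$diff_supported[gained] <- overlap_dir("higher_in_B")[gained]
  }
  states
}

#' Bivalency transition classification
#'
#' For genes carrying both marks at condition A (bivalent), classifies the
#' condition-B outcome: `lost_both`, `retained_K27`, `retained_K4`, or
#' `retained_both`.
#'
#' @param k4_present_b,k27_present_b Logical vectors: per-gene presence of
#'   each mark at condition B.
#' @return Character vector of transition categories.
#' @export
classify_bivalent_transition <- function(k4_present_b, k27_present_b) {
  dplyr::case_when(
    !k4_present_b & !k27_present_b ~ "lost_both",
    !k4_present_b & k27_present_b ~ "retained_K27",
    k4_present_b & !k27_present_b ~ "retained_K4",
    .default = "retained_both"
  )
}

#' Bivalency transition table
#'
#' @param k4_states,k27_states State tables from [mark_state_table()] for the
#'   two marks over the same gene set.
#' @return Tibble `gene_id`, `transition`, restricted to genes bivalent at
#'   condition A.
#' @export
bivalency_table <- function(k4_states, k27_states) {
  joined <- inner_join(
    k4_states |> select("gene_id", k4_a = "present_a", k4_b = "present_b"),
    k27_states |> select("gene_id", k27_a = "present_a", k27_b = "present_b"),
    by = "gene_id"
  )
  bivalent <- joined |> filter(.data$k4_a & .data$k27_a)
  tibble(
    gene_id = bivalent$gene_id,
    transition = classify_bivalent_transition(bivalent$k4_b, bivalent$k27_b)
  )
}

#' Read a gene expression table
#'
#' TSV with header columns `gene_id`, `expr_a`, `expr_b` (expression at
#' conditions A and B; non-negative).
#'
#' @param file Path (or literal TSV text).
#' @return Tibble `gene_id`, `expr_a`, `expr_b`.
#' @export
read_expression_table <- function(file) {
  lines <- read_lines_maybe_literal(file)
  tab <- readr::read_tsv(I(paste0(paste(lines, collapse = "\n"), "\n")),
                         col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE)
  if (!all(c("gene_id", "expr_a", "expr_b") %in% names(tab))) {
    abort("expression table must have header gene_id, expr_a, expr_b")
  }
  tab$gene_id <- as.character(tab$gene_id)
  if (!is.numeric(tab$expr_a) || !is.numeric(tab$expr_b)) {
    abort("expression values must be numeric")
  }
  if (any(tab$expr_a < 0) || any(tab$expr_b < 0)) {
    abort("expression values must be non-negative")
  }
  tab[, c("gene_id", "expr_a", "expr_b")]
}

#' Partition genes into expression groups by differential expression
#'
#' Ranks genes by `log2((expr_b + delta) / (expr_a + delta))` (gene_id breaks
#' ties, so the partition is deterministic and order-independent) and assigns
#' contiguous rank blocks to groups `A` (most down-regulated at condition B,
#' i.e. highest differential expression at A) through `E` (most up-regulated
#' at B). Block sizes differ by at most one; earlier groups take the extra
#' gene when the division is uneven.
#'
#' @param expression Tibble from [read_expression_table()].
#' @param n_groups Number of groups (5 gives quintiles A-E).
#' @param delta Pseudocount added to both expressions.
#' @return `expression` with `log_ratio` and `group` columns, sorted by rank.
#' @export
partition_expression_groups <- function(expression, n_groups = 5, delta = 1) {
  n <- nrow(expression)
  if (n < n_groups) abort("fewer records than groups")
  out <- expression |>
    mutate(log_ratio = log2((.data$expr_b + delta) / (.data$expr_a + delta))) |>
    arrange(.data$log_ratio, .data$gene_id)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + (seq_len(n_groups) <= extra)
  out$group <- rep(LETTERS[seq_len(n_groups)], times = sizes)
  out
}

#' Cross-tabulate mark-state categories by expression group
#'
#' @param states State table from [mark_state_table()].
#' @param groups Grouped expression tibble from
#'   [partition_expression_groups()].
#' @param mark Mark label (used to order the category columns).
#' @return Tibble with one row per (group, category): `n` and `proportion`
#'   (of the group's size). Absent combinations appear with zero counts.
#' @export
crosstab_states_by_group <- function(states, groups, mark) {
  missing_ids <- setdiff(states$gene_id, groups$gene_id)
  if (length(missing_ids) > 0L) {
    abort(paste0("gene_ids absent from expression groups: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  categories <- c(paste0(mark, "-", mark), paste0(mark, "-None"),
                  paste0("None-", mark), "None-None")
  joined <- inner_join(states, groups |> select("gene_id", "group"),
                       by = "gene_id")
  tab <- joined |>
    count(.data$group, .data$category) |>
    tidyr::complete(
      group = sort(unique(groups$group)),
      category = categories,
      fill = list(n = 0L)
    )
  sizes <- joined |> count(.data$group, name = "group_size")
  tab |>
    inner_join(sizes, by = "group") |>
    mutate(proportion = .data$n / .data$group_size) |>
    select("group", "category", "n", "group_size", "proportion")
}

#' TSS-relative histogram of differential regions
#'
#' Each region is assigned, by its midpoint, to the nearest gene TSS within
#' `horizon` bp and tallied into a strand-aware bin of width `bin` relative to
#' that TSS. Bin `+1` covers `[TSS, TSS + bin)` downstream (direction of
#' transcription); bin `-1` the first bin upstream; there is no bin 0.
#' Regions with no TSS within the horizon are counted as unassigned, not
#' dropped silently.
#'
#' @param regions Differential-region tibble (`chrom`, `start`, `end`).
#' @param genes Gene tibble.
#' @param bin Bin width in bp.
#' @param horizon Maximum midpoint-to-TSS distance for assignment, bp.
#' @return A `tss_bin_histogram` tibble (`bin`, `n`) with attribute
#'   `unassigned` (count of unassignable regions).
#' @export
tss_bin_histogram <- function(regions, genes, bin = 200, horizon = 10000) {
  if (nrow(regions) == 0L) {
    out <- tibble(bin = integer(), n = integer())
    class(out) <- unique(c("tss_bin_histogram", class(out)))
    attr(out, "unassigned") <- 0L
    return(out)
  }
  mid <- (regions$start + regions$end) %/% 2L
  mid_gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = mid + 1L, width = 1L)
  )
  tss_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$tss + 1L, width = 1L)
  )
  hits <- GenomicRanges::distanceToNearest(mid_gr, tss_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  dist <- S4Vectors::mcols(hits)$distance
  keep <- dist <= horizon
  unassigned <- nrow(regions) - sum(keep)
  offset <- ifelse(genes$strand[sh] == "+",
                   mid[qh] - genes$tss[sh],
                   genes$tss[sh] - mid[qh])
  offset <- offset[keep]
  b0 <- offset %/% bin
  idx <- as.integer(ifelse(offset >= 0, b0 + 1L, b0))
  out <- tibble(bin = idx) |>
    count(.data$bin) |>
    arrange(.data$bin)
  class(out) <- unique(c("tss_bin_histogram", class(out)))
  attr(out, "unassigned") <- as.integer(unassigned)
  attr(out, "bin_width") <- as.integer(bin)
  out
}

#' Count genes passing a fold-change threshold
#'
#' @param folds Positive fold changes (e.g. up-fold `expr_b / expr_a` for
#'   up-regulated genes, down-fold `expr_a / expr_b` for down-regulated ones).
#' @param threshold Inclusive threshold: a record passes iff
#'   `fold >= threshold`.
#' @return Integer count of records passing.
#' @export
fold_change_filter <- function(folds, threshold) {
  if (length(folds) == 0L) return(0L)
  if (any(folds <= 0)) abort("fold values must be positive")
  sum(folds >= threshold)
}
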