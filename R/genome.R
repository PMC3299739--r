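# Coordinate convention: 0-based, half-open [start, end) everywhere inside the
# package (BED convention). GFF3 is 1-based closed and converted at the I/O
# boundary. A genome is a two-column tibble (chrom, length) whose row order is
# the deterministic iteration order.

#' Read a chromosome-sizes table
#'
#' Parses a two-column, whitespace-delimited table of chromosome name and
#' length in bp, preserving input order.
#'
#' @param file Path to a chrom-sizes file, or a literal string containing the
#'   table (anything with an embedded newline or tab is treated as literal
#'   text).
#' @return A tibble with columns `chrom` (character) and `length` (integer bp),
#'   one row per chromosome in input order.
#' @examples
#' read_chrom_sizes("chr1\t30000\nchr2\t20000")
#' @export
read_chrom_sizes <- function(file) {
  lines <- read_lines_maybe_literal(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("empty chromosome sizes input")
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    abort(paste0("malformed chrom sizes line: ", lines[which(bad)[1]]))
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  len_chr <- vapply(parts, `[[`, character(1), 2L)
  len <- suppressWarnings(as.numeric(len_chr))
  if (anyNA(len) || any(len != floor(len))) {
    abort("chromosome lengths must be integers")
  }
  if (any(len < 1)) {
    abort("chromosome lengths must be >= 1")
  }
  if (anyDuplicated(chrom)) {
    abort(paste0("duplicate chromosome name: ", chrom[duplicated(chrom)][1]))
  }
  tibble(chrom = chrom, length = as.integer(len))
}

#' Write a chromosome-sizes table
#'
#' @param genome A genome tibble (`chrom`, `length`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_chrom_sizes <- function(genome, file) {
  validate_genome(genome)
  readr::write_tsv(genome, file, col_names = FALSE)
  invisible(file)
}

validate_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("chrom", "length") %in% names(genome))) {
    abort("genome must be a data frame with columns chrom and length")
  }
  if (anyDuplicated(genome$chrom)) {
    abort("genome chromosome names must be unique")
  }
  if (any(genome$length < 1)) {
    abort("genome lengths must be >= 1")
  }
  invisible(genome)
}

chrom_length_lookup <- function(genome) {
  setNames(as.numeric(genome$length), genome$chrom)
}

#' Read mapped reads from a BED6 file
#'
#' One strand-aware mapped read per line; coordinates are validated against the
#' genome. Reads are assumed to be unique alignments (multi-mappers removed
#' upstream). A strand of `"."` is rejected because strand is required for
#' 3'-extension.
#'
#' @param file Path to a BED6 file, or literal BED text.
#' @param genome Genome tibble from [read_chrom_sizes()].
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `score`, `strand` (`"+"` or `"-"`).
#' @export
read_reads_bed <- function(file, genome) {
  validate_genome(genome)
  lines <- read_lines_maybe_literal(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_reads())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6L)) {
    abort("BED6 requires 6 tab-delimited columns: chrom start end name score strand")
  }
  reads <- tibble(
    chrom = vapply(parts, `[[`, character(1), 1L),
    start = as.integer(vapply(parts, `[[`, character(1), 2L)),
    end = as.integer(vapply(parts, `[[`, character(1), 3L)),
    name = vapply(parts, `[[`, character(1), 4L),
    score = suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 5L))),
    strand = vapply(parts, `[[`, character(1), 6L)
  )
  validate_reads(reads, genome)
  reads
}

empty_reads <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character()
  )
}

validate_reads <- function(reads, genome) {
  validate_intervals(reads, genome, what = "read")
  if (!all(reads$strand %in% c("+", "-"))) {
    abort("read strand must be '+' or '-' (strand is required for extension)")
  }
  invisible(reads)
}

validate_intervals <- function(x, genome, what = "interval") {
  if (anyNA(x$start) || anyNA(x$end)) {
    abort(paste0(what, " coordinates must be numeric"))
  }
  lookup <- chrom_length_lookup(genome)
  unknown <- setdiff(unique(x$chrom), names(lookup))
  if (length(unknown) > 0L) {
    abort(paste0("unknown chromosome: ", unknown[1]))
  }
  if (any(x$start < 0)) {
    abort(paste0(what, " start must be >= 0"))
  }
  if (any(x$start >= x$end)) {
    abort(paste0(what, " must satisfy start < end (0-based half-open)"))
  }
  if (any(x$end > lookup[x$chrom])) {
    abort(paste0(what, " end exceeds chromosome length"))
  }
  invisible(x)
}

#' Write reads (or any BED6-shaped tibble) to a BED6 file
#'
#' Tab-delimited, newline-terminated, no header.
#'
#' @param reads Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_reads_bed <- function(reads, file) {
  readr::write_tsv(
    reads[, c("chrom", "start", "end", "name", "score", "strand")],
    file,
    col_names = FALSE
  )
  invisible(file)
}

#' Read gene models from GFF3
#'
#' Keeps features of one type (default `"gene"`) and derives the strand-aware
#' TSS (5' end) and TES (3' end). GFF3's 1-based closed coordinates are
#' converted to 0-based half-open on read.
#'
#' @param file Path to a GFF3 file.
#' @param genome Genome tibble; gene coordinates are validated against it.
#' @param feature_type GFF3 `type` to keep.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `tes`. `tss`/`tes` are single base positions (0-based); for a
#'   `-` strand gene `tss > tes`.
#' @export
read_genes_gff3 <- function(file, genome, feature_type = "gene") {
  validate_genome(genome)
  gr <- rtracklayer::import(file, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L) {
    return(empty_genes())
  }
  ids <- as.character(gr$ID %||% NA_character_)
  if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
  ids <- sub("^gene:", "", ids)
  if (anyNA(ids) || anyDuplicated(ids)) {
    abort("gene features must carry unique ID attributes")
  }
  genes <- tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  validate_intervals(genes, genome, what = "gene")
  add_tss_tes(genes)
}

empty_genes <- function() {
  tibble(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), tss = integer(), tes = integer()
  )
}

add_tss_tes <- function(genes) {
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  genes$tss <- as.integer(genes$tss)
  genes$tes <- as.integer(genes$tes)
  genes
}

#' Write gene models to GFF3
#'
#' @param genes Gene tibble (see [read_genes_gff3()]).
#' @param file Output path.
#' @param source GFF3 source column.
#' @return `file`, invisibly.
#' @export
write_genes_gff3 <- function(genes, file, source = "chipdyn") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' Length of the intersection of two genomic intervals
#'
#' Half-open semantics: adjacent intervals overlap by 0. Intervals on different
#' chromosomes overlap by 0.
#'
#' @param chrom_a,start_a,end_a First interval (vectors recycle).
#' @param chrom_b,start_b,end_b Second interval.
#' @return Integer vector of overlap lengths in bp.
#' @examples
#' overlap_length("c", 0, 100, "c", 50, 150) # 50
#' @export
overlap_length <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  len <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  as.integer(ifelse(chrom_a == chrom_b, len, 0L))
}

# Accepts a path or literal multi-line text.
read_lines_maybe_literal <- function(file) {
  if (length(file) == 1L && (grepl("[\n\t]", file) || !file.exists(file))) {
    if (!grepl("[\n\t]", file)) {
      abort(paste0("file not found: ", file))
    }
    strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    readr::read_lines(file)
  }
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
}

intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}
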