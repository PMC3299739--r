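# Synthetic two-condition ChIP-seq study with planted truth. The generator
# emulates: a ~uniform input background; IP libraries enriched near the TSS
# (K4-like, first kilobase of the gene) and over gene bodies (K27-like);
# condition-specific gains/losses of enrichment; and an expression table whose
# up/down structure is coupled to the planted mark changes.

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: two 2-Mb chromosomes, 400 genes, K4 state proportions
#' both/none/a_only/b_only = 0.60/0.35/0.025/0.025, K27 = 0.04/0.90/0.05/0.01,
#' 8-fold enrichment, 4-fold planted differential, and a background depth of
#' 0.007 reads/bp (about 2 expected fragments per 100-bp window once 36-bp
#' reads are extended by 150 bp).
#'
#' @param seed Integer seed; mandatory, drives every random draw.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Genes placed uniformly with at least `intergenic_min` bp
#'   between them.
#' @param gene_length_range Uniform range of gene lengths, bp.
#' @param k4_props,k27_props Named proportions over states `both`, `none`,
#'   `a_only`, `b_only`; each must sum to 1.
#' @param enrichment_fold IP rate multiplier inside a planted mark interval.
#' @param differential_fold Planted fold between conditions over a
#'   differential interval: the mark-bearing condition gets
#'   `enrichment_fold`, the other `enrichment_fold / differential_fold`.
#' @param background_rate Read starts per bp per library.
#' @param expr_effect Log2 expression shift for genes gaining/losing a mark
#'   (activating sign for K4, repressive for K27).
#' @param expr_noise_sd Per-condition log2 expression noise.
#' @param read_length Read length, bp.
#' @param dup_rate Fraction of reads duplicated (exercises deduplication).
#' @param n_bias_regions,bias_fold Optional shared bias field: regions whose
#'   rate is multiplied in every library, IP and input alike (exercises the
#'   stage-1 bias filter).
#' @param k4_interval_length Length of the K4-like planted interval
#'   downstream of the TSS, bp.
#' @param intergenic_min Minimum intergenic spacing, bp.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chroms = 2L,
                       chrom_length = 2e6,
                       n_genes = 400L,
                       gene_length_range = c(1000L, 4000L),
                       k4_props = c(both = 0.60, none = 0.35,
                                    a_only = 0.025, b_only = 0.025),
                       k27_props = c(both = 0.04, none = 0.90,
                                     a_only = 0.05, b_only = 0.01),
                       enrichment_fold = 8,
                       differential_fold = 4,
                       background_rate = 0.007,
                       expr_effect = 2,
                       expr_noise_sd = 0.5,
                       read_length = 36L,
                       dup_rate = 0,
                       n_bias_regions = 0L,
                       bias_fold = 5,
                       k4_interval_length = 1000L,
                       intergenic_min = 2000L) {
  if (missing(seed)) abort("seed is mandatory")
  states <- c("both", "none", "a_only", "b_only")
  for (p in list(k4_props, k27_props)) {
    if (!setequal(names(p), states) || abs(sum(p) - 1) > 1e-8) {
      abort("state proportions must be named both/none/a_only/b_only and sum to 1")
    }
  }
  if (background_rate <= 0 || enrichment_fold <= 0 || differential_fold <= 1) {
    abort("rates must be positive and differential_fold > 1")
  }
  structure(
    list(
      seed = as.integer(seed), n_chroms = as.integer(n_chroms),
      chrom_length = chrom_length, n_genes = as.integer(n_genes),
      gene_length_range = as.integer(gene_length_range),
      k4_props = k4_props[states], k27_props = k27_props[states],
      enrichment_fold = enrichment_fold,
      differential_fold = differential_fold,
      background_rate = background_rate,
      expr_effect = expr_effect, expr_noise_sd = expr_noise_sd,
      read_length = as.integer(read_length), dup_rate = dup_rate,
      n_bias_regions = as.integer(n_bias_regions), bias_fold = bias_fold,
      k4_interval_length = as.integer(k4_interval_length),
      intergenic_min = as.integer(intergenic_min)
    ),
    class = "sim_config"
  )
}

#' Simulate a genome and gene annotation
#'
#' Places non-overlapping genes with random strands and at least
#' `intergenic_min` bp spacing, uniformly over each chromosome. Deterministic
#' given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (tibble) and `genes` (gene tibble).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 1L)
  genome <- tibble(
    chrom = paste0("chr", seq_len(config$n_chroms)),
    length = as.integer(rep(config$chrom_length, config$n_chroms))
  )
  n_total <- config$n_genes
  if (n_total == 0L) {
    return(list(genome = genome, genes = empty_genes()))
  }
  per_chrom <- diff(round(seq(0, n_total, length.out = config$n_chroms + 1)))
  genes_list <- vector("list", config$n_chroms)
  gid <- 0L
  for (i in seq_len(config$n_chroms)) {
    n <- per_chrom[i]
    if (n == 0L) next
    L <- genome$length[i]
    lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                   n, replace = TRUE)
    slack <- L - sum(lens) - config$intergenic_min * (n + 1)
    if (slack < 0) {
      abort("cannot place genes at requested density")
    }
    u <- runif(n + 1)
    extra <- floor(slack * u / sum(u))
    gaps <- config$intergenic_min + extra
    starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(lens))[seq_len(n)]
    strands <- sample(c("+", "-"), n, replace = TRUE)
    genes_list[[i]] <- tibble(
      gene_id = sprintf("g%04d", gid + seq_len(n)),
      chrom = genome$chrom[i],
      start = as.integer(starts),
      end = as.integer(starts + lens),
      strand = strands
    )
    gid <- gid + n
  }
  genes <- add_tss_tes(bind_rows(genes_list))
  validate_intervals(genes, genome, what = "gene")
  list(genome = genome, genes = genes)
}

#' Simulate planted mark states and a coupled expression table
#'
#' Draws each gene's K4 and K27 state from the configured proportions and an
#' expression pair whose log2 ratio is shifted by `expr_effect` for mark
#' gains/losses: a K4 gain (state `b_only`) raises condition-B expression, a
#' K4 loss lowers it; K27 applies the opposite (repressive) signs. Baseline
#' log2 expression is Normal(5, 1) with per-condition noise.
#'
#' @param config A [sim_config()].
#' @param genes Gene tibble from [simulate_annotation()].
#' @return List with `truth` (per-gene planted states and intervals) and
#'   `expression` (tibble `gene_id`, `expr_a`, `expr_b`).
#' @export
simulate_states_and_expression <- function(config, genes) {
  set.seed(config$seed + 2L)
  n <- nrow(genes)
  states <- c("both", "none", "a_only", "b_only")
  k4 <- sample(states, n, replace = TRUE, prob = config$k4_props)
  k27 <- sample(states, n, replace = TRUE, prob = config$k27_props)
  k4_len <- pmin(config$k4_interval_length, genes$end - genes$start)
  truth <- tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = genes$start,
    end = genes$end,
    strand = genes$strand,
    tss = genes$tss,
    k4_state = k4,
    k27_state = k27,
    k4_start = as.integer(ifelse(genes$strand == "+", genes$start,
                                 genes$end - k4_len)),
    k4_end = as.integer(ifelse(genes$strand == "+", genes$start + k4_len,
                               genes$end)),
    k27_start = genes$start,
    k27_end = genes$end
  )
  shift <- config$expr_effect *
    ((k4 == "b_only") - (k4 == "a_only") + (k27 == "a_only") - (k27 == "b_only"))
  base <- rnorm(n, mean = 5, sd = 1)
  la <- base + rnorm(n, sd = config$expr_noise_sd)
  lb <- base + shift + rnorm(n, sd = config$expr_noise_sd)
  expression <- tibble(
    gene_id = genes$gene_id,
    expr_a = 2^la,
    expr_b = 2^lb
  )
  list(truth = truth, expression = expression)
}

state_present <- function(state, condition) {
  if (condition == "a") state %in% c("both", "a_only")
  else state %in% c("both", "b_only")
}

#' Planted enriched intervals for one library
#'
#' @param truth Truth tibble from [simulate_states_and_expression()].
#' @param mark `"K4"` or `"K27"`.
#' @param condition `"a"` or `"b"`.
#' @param include_weak Also return the low side of differential genes (where
#'   the IP rate is elevated by `enrichment_fold / differential_fold` only).
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strength` (`"strong"`
#'   for full-fold intervals, `"weak"` for the low side of differential
#'   genes).
#' @export
sim_enriched_intervals <- function(truth, mark, condition,
                                   include_weak = FALSE) {
  state <- if (mark == "K4") truth$k4_state else truth$k27_state
  s_col <- if (mark == "K4") truth$k4_start else truth$k27_start
  e_col <- if (mark == "K4") truth$k4_end else truth$k27_end
  strong <- state_present(state, condition)
  other <- if (condition == "a") "b" else "a"
  weak <- !strong & state_present(state, other)
  keep <- if (include_weak) strong | weak else strong
  tibble(
    gene_id = truth$gene_id[keep],
    chrom = truth$chrom[keep],
    start = s_col[keep],
    end = e_col[keep],
    strength = ifelse(strong[keep], "strong", "weak")
  )
}

#' Planted differential intervals for one mark
#'
#' @param truth Truth tibble.
#' @param mark `"K4"` or `"K27"`.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `direction`
#'   (`higher_in_A` for condition-A-only states).
#' @export
sim_differential_intervals <- function(truth, mark) {
  state <- if (mark == "K4") truth$k4_state else truth$k27_state
  s_col <- if (mark == "K4") truth$k4_start else truth$k27_start
  e_col <- if (mark == "K4") truth$k4_end else truth$k27_end
  keep <- state %in% c("a_only", "b_only")
  tibble(
    gene_id = truth$gene_id[keep],
    chrom = truth$chrom[keep],
    start = s_col[keep],
    end = e_col[keep],
    direction = ifelse(state[keep] == "a_only", "higher_in_A", "higher_in_B")
  )
}

# Poisson-process read placement: background everywhere at `rate`, plus
# per-interval extra rates. Returns a validated, position-sorted read tibble.
sample_library <- function(genome, extra, rate, read_length, prefix,
                           dup_rate = 0) {
  reads_list <- list()
  for (i in seq_len(nrow(genome))) {
    L <- genome$length[i]
    span <- L - read_length + 1
    n_bg <- rpois(1, rate * span)
    starts <- if (n_bg > 0) sample.int(span, n_bg, replace = TRUE) - 1L else integer()
    reads_list[[length(reads_list) + 1L]] <- tibble(
      chrom = genome$chrom[i], start = as.integer(starts)
    )
  }
  if (!is.null(extra) && nrow(extra) > 0L) {
    for (j in seq_len(nrow(extra))) {
      lo <- extra$start[j]
      hi <- min(extra$end[j],
                chrom_length_lookup(genome)[extra$chrom[j]]) - read_length
      if (hi <= lo) next
      n_ex <- rpois(1, extra$rate[j] * (hi - lo))
      if (n_ex == 0) next
      starts <- lo + sample.int(hi - lo, n_ex, replace = TRUE) - 1L
      reads_list[[length(reads_list) + 1L]] <- tibble(
        chrom = extra$chrom[j], start = as.integer(starts)
      )
    }
  }
  reads <- bind_rows(reads_list)
  reads$strand <- sample(c("+", "-"), nrow(reads), replace = TRUE)
  if (dup_rate > 0 && nrow(reads) > 0L) {
    n_dup <- rpois(1, dup_rate * nrow(reads))
    if (n_dup > 0) {
      reads <- bind_rows(reads, reads[sample.int(nrow(reads), n_dup,
                                                 replace = TRUE), ])
    }
  }
  reads <- reads |> arrange(.data$chrom, .data$start, .data$strand)
  tibble(
    chrom = reads$chrom,
    start = reads$start,
    end = reads$start + read_length,
    name = sprintf("%s_%06d", prefix, seq_len(nrow(reads))),
    score = 0,
    strand = reads$strand
  )
}

#' Simulate the six read libraries
#'
#' Reads are placed by a Poisson process: input libraries carry the uniform
#' background rate; each mark's IP library additionally carries
#' `enrichment_fold` times the background inside that condition's planted
#' intervals, and `enrichment_fold / differential_fold` inside intervals whose
#' mark belongs to the other condition only (the planted differential fold).
#' An optional bias field multiplies the rate of every library alike.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param genome,truth From [simulate_annotation()] /
#'   [simulate_states_and_expression()].
#' @return Named list of read tibbles: `ip_k4_a`, `ip_k4_b`, `ip_k27_a`,
#'   `ip_k27_b`, `input_a`, `input_b`.
#' @export
simulate_reads <- function(config, genome, truth) {
  set.seed(config$seed + 3L)
  rate <- config$background_rate
  bias <- NULL
  if (config$n_bias_regions > 0L) {
    idx <- sample.int(nrow(genome), config$n_bias_regions, replace = TRUE)
    pos <- vapply(genome$length[idx] - 2000L, function(m) sample.int(m, 1L),
                  integer(1))
    bias <- tibble(
      chrom = genome$chrom[idx],
      start = as.integer(pos),
      end = as.integer(pos + 2000L),
      rate = rate * (config$bias_fold - 1)
    )
  }
  ip_extra <- function(mark, condition) {
    strong <- sim_enriched_intervals(truth, mark, condition)
    weak_all <- sim_enriched_intervals(truth, mark, condition,
                                       include_weak = TRUE)
    weak <- weak_all[weak_all$strength == "weak", , drop = FALSE]
    out <- bind_rows(
      tibble(chrom = strong$chrom, start = strong$start, end = strong$end,
             rate = rate * max(0, config$enrichment_fold - 1)),
      tibble(chrom = weak$chrom, start = weak$start, end = weak$end,
             rate = rate *
               max(0, config$enrichment_fold / config$differential_fold - 1))
    )
    bind_rows(out, bias)
  }
  libs <- list(
    ip_k4_a = ip_extra("K4", "a"),
    ip_k4_b = ip_extra("K4", "b"),
    ip_k27_a = ip_extra("K27", "a"),
    ip_k27_b = ip_extra("K27", "b"),
    input_a = bias,
    input_b = bias
  )
  out <- vector("list", length(libs))
  names(out) <- names(libs)
  for (nm in names(libs)) {
    out[[nm]] <- sample_library(genome, libs[[nm]], rate, config$read_length,
                                prefix = nm, dup_rate = config$dup_rate)
  }
  out
}

#' Run the whole generator
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `genes`, `truth`, `expression`, `reads` (list
#'   of six read tibbles) and `config`.
#' @export
simulate_chipseq <- function(config) {
  ann <- simulate_annotation(config)
  se <- simulate_states_and_expression(config, ann$genes)
  reads <- simulate_reads(config, ann$genome, se$truth)
  list(genome = ann$genome, genes = ann$genes, truth = se$truth,
       expression = se$expression, reads = reads, config = config)
}

#' Write a simulation to a directory
#'
#' Emits `genome.tsv`, `genes.gff3`, `expression.tsv`, `truth.tsv` and one
#' BED6 file per read library. Byte-identical across runs with the same seed.
#'
#' @param sim Result of [simulate_chipseq()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dir <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_chrom_sizes(sim$genome, file.path(dir, "genome.tsv"))
  write_genes_gff3(sim$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(sim$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  for (nm in names(sim$reads)) {
    write_reads_bed(sim$reads[[nm]], file.path(dir, paste0(nm, ".bed")))
  }
  invisible(dir)
}
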