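# One-call orchestration of the full analysis: per-library window tracks,
# per-condition peak calls, per-mark differential regions, gene-state and
# expression integration, an input-vs-input empirical FDR estimate, and a
# machine-readable manifest that suffices to re-run the pipeline.

default_params <- function() {
  list(
    window = 100L, extend = 150L, alpha = 1e-6, merge_gap = 0L,
    bin = 200L, tau = 2.0, pseudocount = 1, stage1_alpha = 0.01,
    c_bias = 5, bias_filter = TRUE,
    flank = 10000L, n_groups = 5L, delta = 1, upstream = 500L,
    horizon = 10000L
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, materializes every default, and
#' collects all problems (unknown keys, type errors, missing files, invariant
#' violations) into a single error.
#'
#' Schema: top-level keys `genome`, `genes` (paths, required), `expression`
#' (path, optional), `seed` (integer, optional), `reads` (with `input$a`,
#' `input$b`, and `ip$<MARK>$a` / `ip$<MARK>$b` per mark), and `params`
#' (any of window, extend, alpha, merge_gap, bin, tau, pseudocount,
#' stage1_alpha, c_bias, bias_filter, flank, n_groups, delta, upstream,
#' horizon).
#'
#' @param config Path to a YAML config or an equivalent list.
#' @return The fully-resolved config list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  errors <- character()
  known_top <- c("genome", "genes", "expression", "seed", "reads", "params")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown) > 0L) {
    errors <- c(errors, paste0("unknown config key: ", unknown))
  }
  params <- default_params()
  if (!is.null(config$params)) {
    unknown_p <- setdiff(names(config$params), names(params))
    if (length(unknown_p) > 0L) {
      errors <- c(errors, paste0("unknown params key: ", unknown_p))
    }
    for (k in intersect(names(config$params), names(params))) {
      params[[k]] <- config$params[[k]]
    }
  }
  if (!is.null(params$tau) && params$tau <= 1) {
    errors <- c(errors, "tau must be > 1")
  }
  if (params$alpha <= 0 || params$alpha >= 1) {
    errors <- c(errors, "alpha must be in (0, 1)")
  }
  if (params$pseudocount <= 0) {
    errors <- c(errors, "pseudocount must be > 0")
  }
  for (key in c("genome", "genes")) {
    if (is.null(config[[key]])) {
      errors <- c(errors, paste0("missing required key: ", key))
    } else if (!file.exists(config[[key]])) {
      errors <- c(errors, paste0(key, " file not found: ", config[[key]]))
    }
  }
  if (!is.null(config$expression) && !file.exists(config$expression)) {
    errors <- c(errors, paste0("expression file not found: ", config$expression))
  }
  marks <- character()
  if (is.null(config$reads) || is.null(config$reads$input) ||
      is.null(config$reads$ip)) {
    errors <- c(errors, "reads must provide input$a, input$b and ip$<mark>$a/b")
  } else {
    for (cond in c("a", "b")) {
      f <- config$reads$input[[cond]]
      if (is.null(f)) {
        errors <- c(errors, paste0("missing reads$input$", cond))
      } else if (!file.exists(f)) {
        errors <- c(errors, paste0("input reads file not found: ", f))
      }
    }
    marks <- names(config$reads$ip)
    for (m in marks) {
      for (cond in c("a", "b")) {
        f <- config$reads$ip[[m]][[cond]]
        if (is.null(f)) {
          errors <- c(errors, paste0("missing reads$ip$", m, "$", cond))
        } else if (!file.exists(f)) {
          errors <- c(errors, paste0("IP reads file not found: ", f))
        }
      }
    }
  }
  if (length(errors) > 0L) {
    abort(paste0("invalid pipeline config:\n",
                 paste0("  - ", errors, collapse = "\n")))
  }
  structure(
    list(
      genome = config$genome, genes = config$genes,
      expression = config$expression, seed = config$seed %||% 1L,
      reads = config$reads, marks = marks, params = params
    ),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  message(sprintf("[chipdyn] stage %-22s ...", name))
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
  message(sprintf("[chipdyn] stage %-22s done (%.1f s)", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full pipeline
#'
#' Produces, under `outdir`: per-library window tracks (bedGraph), peak BEDs
#' per mark and condition, differential BEDs per mark, the per-gene state
#' table, the bivalency table (when both K4 and K27 are supplied), per-mark
#' crosstabs against expression quintiles, TSS histograms of differential
#' regions, an input-vs-input empirical FDR estimate, and `manifest.json`
#' (all parameters plus input/output checksums). A missing expression table
#' skips the crosstab stage with a warning; earlier outputs are kept.
#'
#' @param config Path to a YAML config or a list (see [validate_config()]).
#' @param outdir Output directory.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- validate_config(config)
  p <- cfg$params
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("tracks", "peaks", "diff")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }

  genome <- stage("load_genome", read_chrom_sizes(cfg$genome))
  genes <- stage("load_genes", read_genes_gff3(cfg$genes, genome))
  read_files <- c(
    setNames(
      unlist(lapply(cfg$marks, function(m) cfg$reads$ip[[m]][c("a", "b")])),
      unlist(lapply(cfg$marks, function(m) paste0("ip_", m, "_", c("a", "b"))))
    ),
    input_a = cfg$reads$input$a, input_b = cfg$reads$input$b
  )
  reads <- stage("load_reads", lapply(read_files, read_reads_bed, genome = genome))

  stage("window_tracks", {
    for (nm in names(reads)) {
      reads[[nm]] |>
        deduplicate_reads() |>
        extend_reads(genome, extension = p$extend) |>
        count_windows(genome, width = p$window) |>
        write_bedgraph(file.path(outdir, "tracks", paste0(nm, ".bedgraph")))
    }
  })

  peak_fits <- stage("call_peaks", {
    fits <- list()
    for (m in cfg$marks) {
      for (cond in c("a", "b")) {
        key <- paste0(m, "_", cond)
        fits[[key]] <- call_peaks(
          reads[[paste0("ip_", key)]], reads[[paste0("input_", cond)]],
          genome,
          window = p$window, extension = p$extend, alpha = p$alpha,
          merge_gap = p$merge_gap
        )
        write_peaks_bed(tidy(fits[[key]]),
                        file.path(outdir, "peaks", paste0(key, ".bed")))
      }
    }
    fits
  })

  diff_fits <- stage("differential", {
    fits <- list()
    for (m in cfg$marks) {
      fits[[m]] <- chipnorm(
        reads[[paste0("ip_", m, "_a")]], reads$input_a,
        reads[[paste0("ip_", m, "_b")]], reads$input_b,
        genome,
        bin = p$bin, extension = p$extend, tau = p$tau,
        pseudocount = p$pseudocount, stage1_alpha = p$stage1_alpha,
        c_bias = p$c_bias, bias_filter = p$bias_filter,
        merge_gap = p$merge_gap
      )
      write_differential_bed(tidy(fits[[m]]),
                             file.path(outdir, "diff", paste0(m, ".bed")))
    }
    fits
  })

  states <- stage("gene_states", {
    st <- lapply(cfg$marks, function(m) {
      mark_state_table(genes, tidy(peak_fits[[paste0(m, "_a")]]),
                       tidy(peak_fits[[paste0(m, "_b")]]), m, genome,
                       diff_regions = tidy(diff_fits[[m]]),
                       upstream = p$upstream)
    })
    names(st) <- cfg$marks
    readr::write_tsv(bind_rows(st), file.path(outdir, "state_table.tsv"))
    st
  })

  if (all(c("K4", "K27") %in% cfg$marks)) {
    stage("bivalency", {
      readr::write_tsv(bivalency_table(states$K4, states$K27),
                       file.path(outdir, "bivalency.tsv"))
    })
  }

  stage("tss_histograms", {
    for (m in cfg$marks) {
      hist <- tss_bin_histogram(tidy(diff_fits[[m]]), genes,
                                bin = p$bin, horizon = p$horizon)
      readr::write_tsv(as_tibble(hist),
                       file.path(outdir, paste0("tss_hist_", m, ".tsv")))
    }
  })

  if (!is.null(cfg$expression)) {
    stage("expression_crosstab", {
      expr <- read_expression_table(cfg$expression)
      groups <- partition_expression_groups(expr, n_groups = p$n_groups,
                                            delta = p$delta)
      readr::write_tsv(groups, file.path(outdir, "expression_groups.tsv"))
      for (m in cfg$marks) {
        st <- states[[m]] |> filter(.data$gene_id %in% groups$gene_id)
        tab <- crosstab_states_by_group(st, groups, m)
        readr::write_tsv(tab, file.path(outdir, paste0("crosstab_", m, ".tsv")))
      }
    })
  } else {
    warn("no expression table supplied; skipping expression integration stages")
  }

  fdr <- stage("empirical_fdr", {
    null_fit <- call_peaks(reads$input_a, reads$input_b, genome,
                           window = p$window, extension = p$extend,
                           alpha = p$alpha, merge_gap = p$merge_gap)
    n_null <- nrow(tidy(null_fit))
    est <- lapply(cfg$marks, function(m) {
      obs <- nrow(tidy(peak_fits[[paste0(m, "_a")]]))
      list(
        mark = m,
        observed_peaks = obs,
        null_peaks = n_null,
        fdr = if (obs >= 1) empirical_fdr(n_null, obs) else NA
      )
    })
    jsonlite::write_json(est, file.path(outdir, "fdr.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    est
  })

  manifest <- stage("manifest", {
    inputs <- c(genome = cfg$genome, genes = cfg$genes,
                expression = cfg$expression, read_files)
    outputs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    outputs <- outputs[basename(outputs) != "manifest.json"]
    man <- list(
      package = "chipdyn",
      version = as.character(utils::packageVersion("chipdyn")),
      seed = cfg$seed,
      params = cfg$params,
      marks = cfg$marks,
      inputs = as.list(tools::md5sum(unlist(inputs))),
      outputs = as.list(tools::md5sum(sort(outputs))),
      fdr = fdr
    )
    jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })
  invisible(manifest)
}
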