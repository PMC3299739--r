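genome10k <- toy_genome(c(c1 = 10000L))

test_that("gene territory is strand-aware and clipped", {
  genes <- chipdyn:::add_tss_tes(tibble::tibble(
    gene_id = c("gp", "gm", "gc"),
    chrom = "c1",
    start = c(1000L, 1000L, 200L),
    end = c(4000L, 4000L, 900L),
    strand = c("+", "-", "+")
  ))
  terr <- gene_territory(genes, genome10k, upstream = 500)
  expect_equal(terr$start, c(500L, 1000L, 0L))
  expect_equal(terr$end, c(4000L, 4500L, 900L))
})

test_that("mark-state categories exhaust the four presence combinations", {
  expect_equal(classify_state(TRUE, TRUE, "K4"), "K4-K4")
  expect_equal(classify_state(TRUE, FALSE, "K27"), "K27-None")
  expect_equal(classify_state(FALSE, TRUE, "K4"), "None-K4")
  expect_equal(classify_state(FALSE, FALSE, "K4"), "None-None")
  combos <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE))
  expect_equal(length(unique(classify_state(combos$a, combos$b, "K4"))), 4L)
})

test_that("bivalency transitions cover the four outcomes and require bivalency at A", {
  expect_equal(classify_bivalent_transition(FALSE, FALSE), "lost_both")
  expect_equal(classify_bivalent_transition(FALSE, TRUE), "retained_K27")
  expect_equal(classify_bivalent_transition(TRUE, FALSE), "retained_K4")
  expect_equal(classify_bivalent_transition(TRUE, TRUE), "retained_both")

  k4 <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       present_a = c(TRUE, TRUE, FALSE),
                       present_b = c(TRUE, FALSE, TRUE))
  k27 <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        present_a = c(TRUE, FALSE, TRUE),
                        present_b = c(FALSE, FALSE, TRUE))
  biv <- bivalency_table(k4, k27)
  expect_equal(biv$gene_id, "g1") # only g1 carries both marks at A
  expect_equal(biv$transition, "retained_K4")
})

test_that("expression quintiles are contiguous rank blocks with deterministic ties", {
  expr <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    expr_a = rep(100, 10),
    expr_b = 100 * 2^c(-3, -2, -1, 0, 1, 2, 3, 4, 5, 6)
  )
  out <- partition_expression_groups(expr, n_groups = 5, delta = 1)
  expect_equal(out$group, rep(LETTERS[1:5], each = 2))
  expect_equal(out$gene_id, sprintf("g%02d", 1:10)) # already in rank order
  expect_true(all(diff(out$log_ratio) >= 0))

  # order invariance
  shuffled <- expr[sample(10), ]
  expect_equal(partition_expression_groups(shuffled, 5, 1), out)

  # all equal: grouping fixed entirely by gene_id
  flat <- expr
  flat$expr_b <- 100
  out_flat <- partition_expression_groups(flat, 5, 1)
  expect_equal(out_flat$gene_id, sort(expr$gene_id))

  # uneven split: sizes differ by at most one
  out7 <- partition_expression_groups(expr[1:7, ], n_groups = 5)
  expect_equal(as.integer(table(out7$group)), c(2L, 2L, 1L, 1L, 1L))

  expect_error(partition_expression_groups(expr[1:3, ], n_groups = 5), "fewer")
})

test_that("an equal five-way partition of 4090 genes yields groups of 818", {
  set.seed(14)
  expr <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:4090),
    expr_a = runif(4090, 1, 100),
    expr_b = runif(4090, 1, 100)
  )
  out <- partition_expression_groups(expr)
  expect_equal(unname(table(out$group)), rep(818L, 5), ignore_attr = TRUE)
})

test_that("the state-by-group crosstab conserves totals and zero-fills", {
  groups <- partition_expression_groups(tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    expr_a = rep(10, 10), expr_b = 2^(1:10)
  ))
  states <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10), mark = "K4",
    present_a = TRUE, present_b = TRUE, category = "K4-K4"
  )
  tab <- crosstab_states_by_group(states, groups, "K4")
  expect_equal(nrow(tab), 20L) # 5 groups x 4 categories, zero-filled
  k4k4 <- tab[tab$category == "K4-K4", ]
  expect_equal(k4k4$n, k4k4$group_size)
  expect_true(all(tab$n[tab$category != "K4-K4"] == 0))
  # row sums reproduce group sizes
  sums <- tapply(tab$n, tab$group, sum)
  expect_equal(unname(sums), unname(tapply(tab$group_size, tab$group, unique)),
               ignore_attr = TRUE)

  bad <- states
  bad$gene_id[1] <- "missing"
  expect_error(crosstab_states_by_group(bad, groups, "K4"), "absent")
})

test_that("TSS bin assignment is strand-aware with no bin zero", {
  genes <- chipdyn:::add_tss_tes(tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "c1",
    start = c(1000L, 3000L), end = c(3000L, 5001L),
    strand = c("+", "-")
  )) # TSS at 1000 (+) and 5000 (-)
  mk_region <- function(mid) {
    tibble::tibble(chrom = "c1", start = mid - 50L, end = mid + 50L)
  }
  h1 <- tss_bin_histogram(mk_region(1250L), genes[1, ])
  expect_equal(h1$bin, 2L) # floor((1250-1000)/200) + 1
  h2 <- tss_bin_histogram(mk_region(4900L), genes[2, ])
  expect_equal(h2$bin, 1L) # 100 bp downstream on the minus strand
  h3 <- tss_bin_histogram(mk_region(999L), genes[1, ])
  expect_equal(h3$bin, -1L) # 1 bp upstream
  expect_true(all(h1$bin != 0) && all(h3$bin != 0))

  # out of horizon: tallied as unassigned
  far <- tibble::tibble(chrom = "c1", start = 9000L, end = 9100L)
  h4 <- tss_bin_histogram(far, genes[1, ], horizon = 1000)
  expect_equal(attr(h4, "unassigned"), 1L)
  expect_equal(nrow(h4), 0L)
})

test_that("mirrored coordinates with flipped strands reproduce the histogram", {
  L <- 100000L
  set.seed(21)
  genes <- chipdyn:::add_tss_tes(tibble::tibble(
    gene_id = sprintf("g%02d", 1:8), chrom = "c1",
    start = as.integer(seq(5000, 82000, length.out = 8)),
    end = as.integer(seq(5000, 82000, length.out = 8)) + 2000L,
    strand = sample(c("+", "-"), 8, replace = TRUE)
  ))
  # offsets off the 200-bp bin boundaries: the half-open mirror x -> L-1-x
  # shifts positions by one, which must not cross a bin edge
  offs <- setdiff(-900:900, seq(-800, 800, by = 200))
  mids <- as.integer(genes$tss + sample(offs, 8, replace = TRUE))
  regions <- tibble::tibble(chrom = "c1", start = mids - 100L, end = mids + 100L)
  h <- tss_bin_histogram(regions, genes)

  # mirror: x -> L - x, strands flipped
  m_genes <- genes
  m_genes$start <- L - genes$end
  m_genes$end <- L - genes$start
  m_genes$strand <- ifelse(genes$strand == "+", "-", "+")
  m_genes <- chipdyn:::add_tss_tes(m_genes)
  m_regions <- tibble::tibble(chrom = "c1", start = L - regions$end,
                              end = L - regions$start)
  m_h <- tss_bin_histogram(m_regions, m_genes)
  expect_equal(as.data.frame(m_h), as.data.frame(h))
})

test_that("fold-change filtering counts inclusive threshold passes", {
  surg <- c(90148, 635, 309, 304, 113, 99, 74, 16)
  sdrg <- c(14116, 2788, 70, 55, 53, 25, 0.4)
  expect_equal(fold_change_filter(surg, 15), 8L)
  expect_equal(fold_change_filter(sdrg, 24), 6L)
  expect_equal(fold_change_filter(numeric(), 10), 0L)
  expect_equal(fold_change_filter(c(15, 14.999), 15), 1L) # inclusive
  expect_error(fold_change_filter(c(2, -1), 10), "positive")
})

test_that("the bundled qPCR table reproduces its printed filter counts", {
  path <- system.file("extdata", "qpcr_senescence_expression.tsv",
                      package = "chipdyn")
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  up <- tab[tab$class == "SURG", ]
  down <- tab[tab$class == "SDRG", ]
  expect_equal(fold_change_filter(up$expr_b / up$expr_a, 15), 8L)
  expect_equal(fold_change_filter(down$expr_a / down$expr_b, 24), 6L)
  expect_equal(max(up$expr_b / up$expr_a), 90148)
})

test_that("expression tables require the documented header and non-negative values", {
  tab <- read_expression_table("gene_id\texpr_a\texpr_b\ng1\t1\t2\ng2\t3\t0")
  expect_equal(nrow(tab), 2L)
  expect_error(read_expression_table("gene\ta\tb\ng1\t1\t2"), "header")
})
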