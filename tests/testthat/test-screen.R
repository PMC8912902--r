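toy_table <- function() {
  data.frame(gene = LETTERS[1:5],
             base_mean = c(600, 600, 600, 600, 100),
             log2fc = c(0.05, 0.05, 0.5, 0.05, 0.05),
             padj = c(0.8, 0.01, 0.8, 0.8, 0.8),
             dispersion = c(0.0225, 0.0225, 0.0225, 0.0625, 0.0225),
             stringsAsFactors = FALSE)
}

test_that("dispersion converts to the CV-like percentage", {
  tab <- compute_cv_from_dispersion(
    data.frame(gene = c("a", "b", "c"), base_mean = 1, log2fc = 0, padj = 1,
               dispersion = c(0.0225, 0, 0.04)))
  expect_equal(tab$cv_from_disp, c(15, 0, 20))
  expect_error(compute_cv_from_dispersion(
    data.frame(dispersion = -0.1)), class = "refstab_validation_error")
  # missing dispersion propagates
  na_tab <- compute_cv_from_dispersion(
    data.frame(gene = "a", dispersion = NA_real_))
  expect_true(is.na(na_tab$cv_from_disp))
})

test_that("the four candidate filters act conjunctively with stated boundaries", {
  tab <- compute_cv_from_dispersion(toy_table())
  # B fails padj, C fails lfc, D fails cv (25%), E fails base_mean
  kept <- filter_reference_candidates(tab)
  expect_equal(kept$gene, "A")

  # boundary semantics: lfc and cv inclusive, base_mean >= , padj strict >
  edge <- compute_cv_from_dispersion(data.frame(
    gene = c("lfc_hi", "cv_lo", "cv_hi", "bm_eq", "padj_eq"),
    base_mean = c(600, 600, 600, 500, 600),
    log2fc = c(0.1, 0, 0, 0, 0),
    padj = c(0.8, 0.8, 0.8, 0.8, 0.05),
    dispersion = c(0.0225, 0.01, 0.04, 0.0225, 0.0225)))
  kept2 <- filter_reference_candidates(edge)
  expect_setequal(kept2$gene, c("lfc_hi", "cv_lo", "cv_hi", "bm_eq"))

  # missing padj is excluded
  na_padj <- compute_cv_from_dispersion(data.frame(
    gene = "x", base_mean = 600, log2fc = 0, padj = NA_real_,
    dispersion = 0.0225))
  expect_warning(out <- filter_reference_candidates(na_padj), "no genes")
  expect_equal(nrow(out), 0L)

  # idempotence
  expect_equal(filter_reference_candidates(kept)$gene, kept$gene)
})

test_that("filtering a large synthetic table matches a brute-force row scan", {
  set.seed(91)
  n <- 1000
  tab <- compute_cv_from_dispersion(data.frame(
    gene = sprintf("gene%04d", 1:n),
    base_mean = exp(runif(n, log(10), log(1e5))),
    log2fc = rnorm(n, 0, 0.5),
    padj = ifelse(runif(n) < 0.05, NA, runif(n)),
    dispersion = runif(n, 0, 0.09)))
  got <- filter_reference_candidates(tab)$gene
  want <- character()
  for (i in seq_len(n)) {            # exhaustive scan, one row at a time
    row <- tab[i, ]
    if (is.na(row$padj)) next
    if (!(row$padj > 0.05)) next
    if (row$log2fc < -0.1 || row$log2fc > 0.1) next
    if (row$cv_from_disp < 10 || row$cv_from_disp > 20) next
    if (row$base_mean < 500) next
    want <- c(want, row$gene)
  }
  expect_identical(got, want)
})

test_that("panel selection honours the quartile allocation and seeding", {
  set.seed(5)
  pool <- compute_cv_from_dispersion(data.frame(
    gene = sprintf("g%02d", 1:40),
    base_mean = sort(runif(40, 500, 5e4)),
    log2fc = 0, padj = 0.9,
    dispersion = runif(40, 0.01, 0.04)))
  panel <- select_panel(pool, seed = 7)
  expect_equal(nrow(panel), 10L)
  expect_equal(as.integer(table(panel$quartile)[paste0("Q", 1:4)]),
               c(3L, 3L, 3L, 1L))
  # panel spans the base_mean range: Q1 genes all below Q4 genes
  expect_lt(max(panel$base_mean[panel$quartile == "Q1"]),
            min(panel$base_mean[panel$quartile == "Q4"]))
  # seeded reproducibility, bit for bit
  expect_identical(panel, select_panel(pool, seed = 7))
  expect_false(identical(panel$gene, select_panel(pool, seed = 8)$gene))
  # deterministic strategy is seed-free and repeatable
  det <- select_panel(pool, strategy = "lowest_cv")
  expect_identical(det, select_panel(pool, strategy = "lowest_cv", seed = 99))
  # selected genes always come from the pool
  expect_true(all(panel$gene %in% pool$gene))
  # undersized quartile raises a selection error naming the quartile
  small <- pool[1:10, ]
  expect_error(select_panel(small, allocation = c(3, 3, 3, 1)),
               "Q3", class = "refstab_selection_error")
})

test_that("target selection splits by direction with strict cuts", {
  tab <- data.frame(
    gene = sprintf("t%02d", 1:12),
    base_mean = 1000,
    log2fc = c(0.7, 0.9, 1.5, 2.0, -0.7, -0.9, -1.5, -2.0, 0.6, -0.6, 3, -3),
    padj = c(rep(0.01, 10), 0.04, 0.06),
    dispersion = 0.02)
  sel <- select_targets(tab, seed = 2)
  expect_length(sel$up, 3L)
  expect_length(sel$down, 3L)
  # boundary: lfc 0.6 / -0.6 exactly are excluded (strict)
  expect_false("t09" %in% sel$up_pool)
  expect_false("t10" %in% sel$down_pool)
  # padj 0.04 passes (t11, lfc 3), padj 0.06 fails (t12)
  expect_true("t11" %in% sel$up_pool)
  expect_false("t12" %in% sel$down_pool)
  expect_identical(sel, select_targets(tab, seed = 2))
  expect_error(select_targets(tab[tab$log2fc > 0, ], n_per_direction = 3),
               class = "refstab_selection_error")
})

test_that("targets drawn from a simulated table are planted DE genes", {
  genes <- sprintf("g%03d", 1:60)
  theta <- matrix(0, 60, 2, dimnames = list(genes, c("WT", "KO")))
  theta[1:8, "KO"] <- c(2, 2, 1.5, 1.5, -2, -2, -1.5, -1.5)
  cfg <- count_sim_config(mean_expr = setNames(rep(2000, 60), genes),
                          dispersion = 0.01, log2_effects = theta,
                          n_per_group = c(WT = 6L, KO = 6L), seed = 14)
  sim <- simulate_counts(cfg)
  res <- deseq_like_results(sim$counts, sim$groups,
                            true_dispersion = sim$truth$alpha)
  sel <- select_targets(res$results, seed = 3)
  expect_true(all(c(sel$up, sel$down) %in% sim$truth$de_genes))
})

test_that("results tables round-trip through the DESeq2-style reader", {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  write.csv(data.frame(gene = c("a", "b"), baseMean = c(100, 200),
                       log2FoldChange = c(0, 1), padj = c(0.9, 0.01),
                       dispersion = c(0.02, 0.03)),
            tf, row.names = FALSE)
  tab <- read_deseq_results(tf)
  expect_equal(tab$base_mean, c(100, 200))
  expect_equal(tab$log2fc, c(0, 1))
  tf2 <- tempfile(fileext = ".csv")
  on.exit(unlink(tf2), add = TRUE)
  write.csv(data.frame(gene = c("a", "b"), baseMean = 1), tf2,
            row.names = FALSE)
  expect_error(read_deseq_results(tf2), class = "refstab_format_error")
})
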