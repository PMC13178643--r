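test_that("qc_filter applies the four rules in order on the toy matrix", {
  cm <- qc_toy()
  out <- qc_filter(cm, min_genes = 10)
  expect_equal(out$nucleus_meta$nucleus_id, sprintf("c%02d", 1:9))
  expect_equal(out$gene_ids, sprintf("g%02d", 1:35))
  rep <- attr(out, "qc_report")
  expect_equal(rep$removed[rep$rule == "min_genes"], 1)       # c10
  expect_equal(rep$removed[rep$rule == "min_cells"], 15)      # g36..g49 + mt
  expect_equal(rep$removed[rep$rule == "gene_percentile"], 1) # c11
  expect_equal(rep$removed[rep$rule == "max_mito"], 1)        # c12
})

test_that("qc boundaries are inclusive exactly as stated", {
  # 250 genes; one nucleus expressing 199 genes (removed), one with 200 (kept)
  n_genes <- 250
  m <- matrix(1L, n_genes, 6)      # background nuclei expressing everything
  m[, 5] <- c(rep(1L, 199), rep(0L, 51))
  m[, 6] <- c(rep(1L, 200), rep(0L, 50))
  meta <- data.frame(nucleus_id = paste0("c", 1:6), sex = rep(c("F", "M"), 3))
  cm <- count_matrix(m, paste0("g", 1:n_genes), meta)
  out <- qc_filter(cm, min_genes = 200, gene_percentile = 1)
  expect_false("c5" %in% out$nucleus_meta$nucleus_id)
  expect_true("c6" %in% out$nucleus_meta$nucleus_id)
  # gene in 2 cells removed, in 3 retained
  m2 <- matrix(0L, 10, 6)
  m2[1:8, ] <- 1L
  m2[9, 1:2] <- 1L
  m2[10, 1:3] <- 1L
  cm2 <- count_matrix(m2, paste0("g", 1:10),
                      data.frame(nucleus_id = paste0("c", 1:6),
                                 sex = rep(c("F", "M"), 3)))
  out2 <- qc_filter(cm2, min_genes = 1, gene_percentile = 1)
  expect_false("g9" %in% out2$gene_ids)
  expect_true("g10" %in% out2$gene_ids)
})

test_that("normalisation matches the log1p/target-sum arithmetic", {
  m <- matrix(c(2, 1998, 0, 500, 500, 0), nrow = 3)
  cm <- count_matrix(m, c("a", "b", "c"),
                     data.frame(nucleus_id = c("n1", "n2"), sex = c("F", "M")))
  norm <- normalize_log1p(cm, target_sum = 1e6)
  expect_equal(norm$values["a", "n1"], log1p(1000), tolerance = 1e-12)
  expect_equal(norm$values["c", "n1"], 0)
  # back-transformed column sums hit the target
  expect_equal(colSums(expm1(norm$values)), c(n1 = 1e6, n2 = 1e6),
               tolerance = 1e-9)
  # cell total equal to target -> identity log1p(count)
  big <- count_matrix(matrix(c(4, 1e6 - 4), 2), c("a", "b"),
                      data.frame(nucleus_id = "n1", sex = "F"))
  expect_equal(normalize_log1p(big)$values["a", 1], log1p(4))
  zero <- count_matrix(matrix(c(1, 0), 1), c("a"),
                       data.frame(nucleus_id = c("n1", "n2"),
                                  sex = c("F", "M")))
  expect_error(normalize_log1p(zero), "zero total")
})

test_that("projection classification follows the marker co-expression rules", {
  # columns: core-like, shell-like, triple-positive, all-negative, calb-only
  vals <- rbind(Calb1   = c(1, 1, 1, 0, 1),
                Sox6    = c(1, 0, 1, 0, 0),
                Aldh1a1 = c(0, 1, 1, 0, 0))
  norm <- structure(list(values = vals, gene_ids = rownames(vals),
                         nucleus_meta = data.frame(
                           nucleus_id = paste0("n", 1:5),
                           sex = c("F", "M", "F", "M", "F"))),
                    class = "normalized_matrix")
  lab <- classify_projection(norm)
  expect_equal(as.character(lab),
               c("core", "shell", "ambiguous", "unassigned", "unassigned"))
  # invariant to monotone positive rescaling (only zero/nonzero matters)
  norm2 <- norm
  norm2$values <- norm$values * 17.3
  expect_identical(classify_projection(norm2), lab)
  norm3 <- norm
  norm3$gene_ids <- c("Calb1", "Sox6", "Other")
  rownames(norm3$values) <- norm3$gene_ids
  expect_error(classify_projection(norm3), "Aldh1a1")
})

test_that("per-gene Wilcoxon matches enumeration and fold-change arithmetic", {
  vals <- rbind(sep = c(1, 2, 3, 4, 5, 6),       # complete separation
                same = c(5, 6, 7, 5, 6, 7))      # identical multisets
  labs <- rep(c("A", "B"), each = 3)
  tab <- rank_genes_wilcoxon(vals, labs, group1 = "A")
  oracle <- mw_exact_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tab$statistic[1], oracle$u)
  # normal approximation vs exact: same extreme-separation call
  expect_lt(abs(tab$p_value[1] - oracle$p_two), 0.07)
  expect_equal(tab$p_value[2], 1)
  expect_equal(tab$log2fc[2], 0)
  expect_false(tab$significant[2])
  # expm1-scale mean ratio of 2 -> log2fc of 1
  g1 <- log1p(c(4, 4, 4)); g2 <- log1p(c(2, 2, 2))
  tab2 <- rank_genes_wilcoxon(matrix(c(g1, g2), nrow = 1),
                              labs, group1 = "A")
  expect_equal(tab2$log2fc, 1, tolerance = 1e-6)
  # DEGTable invariants: padj >= p, significance definition
  set.seed(1)
  vals3 <- matrix(rnorm(50 * 12), 50)
  tab3 <- rank_genes_wilcoxon(vals3, rep(c("A", "B"), each = 6))
  expect_true(all(tab3$padj >= tab3$p_value - 1e-12))
  expect_equal(tab3$significant,
               abs(tab3$log2fc) > 0.5 & tab3$padj < 0.025)
})

test_that("bootstrap DEG counting is balanced, deterministic and seed-sensitive", {
  cm <- simulate_counts(count_sim_params(n_nuclei = 25, n_genes = 150,
                                         seed = 21))
  norm <- normalize_log1p(cm)
  core <- subset_norm(norm, norm$nucleus_meta$projection_truth == "core")
  d1 <- bootstrap_deg_counts(core, n_boot = 4, n_per_sex = 10, seed = 5)
  d2 <- bootstrap_deg_counts(core, n_boot = 4, n_per_sex = 10, seed = 5)
  expect_identical(d1$counts, d2$counts)
  expect_length(d1$counts, 4)
  expect_true(all(d1$counts >= 0))
  d3 <- bootstrap_deg_counts(core, n_boot = 1, n_per_sex = 10, seed = 6)
  expect_length(d3$counts, 1)
  only_f <- subset_norm(core, core$nucleus_meta$sex == "F")
  expect_error(bootstrap_deg_counts(only_f, n_boot = 2, n_per_sex = 5,
                                    seed = 1), "both sexes")
})

test_that("compare_regions follows the U convention and tiny-case enumeration", {
  same <- list(counts = c(1, 2, 3, 4, 5))
  class(same) <- "deg_count_distribution"
  r <- compare_regions(same, same)
  expect_gte(r$p_value, 0.9)
  hi <- structure(list(counts = 101:150), class = "deg_count_distribution")
  lo <- structure(list(counts = 1:50), class = "deg_count_distribution")
  expect_equal(compare_regions(hi, lo)$statistic, 2500)  # n1 * n2
  tiny <- compare_regions(structure(list(counts = c(1, 2)),
                                    class = "deg_count_distribution"),
                          structure(list(counts = c(3, 4)),
                                    class = "deg_count_distribution"))
  oracle <- mw_exact_oracle(c(1, 2), c(3, 4))
  expect_equal(tiny$statistic, oracle$u)
  expect_equal(tiny$p_value, oracle$p_two, tolerance = 1e-12)
})

test_that("label permutation makes the region comparison conservative", {
  # with sex labels permuted the bootstrap DEG distributions are
  # exchangeable; the comparison p-value must not be anti-conservative.
  # (DEG counts are heavily tied near zero, so the p-value distribution is
  # discrete and stochastically larger than uniform; we check the one-sided
  # Kolmogorov-Smirnov bound rather than two-sided uniformity.)
  cm <- simulate_counts(count_sim_params(n_nuclei = 20, n_genes = 100,
                                         baseline_mean = 8, seed = 33))
  norm <- normalize_log1p(cm)
  set.seed(77)
  pvals <- vapply(1:60, function(i) {
    perm <- sample(norm$nucleus_meta$sex)
    core <- subset_norm(norm, norm$nucleus_meta$projection_truth == "core")
    shell <- subset_norm(norm, norm$nucleus_meta$projection_truth == "shell")
    perm_core <- perm[norm$nucleus_meta$projection_truth == "core"]
    perm_shell <- perm[norm$nucleus_meta$projection_truth == "shell"]
    d1 <- bootstrap_deg_counts(core, sex_labels = perm_core, n_boot = 5,
                               n_per_sex = 10, seed = i)
    d2 <- bootstrap_deg_counts(shell, sex_labels = perm_shell, n_boot = 5,
                               n_per_sex = 10, seed = i + 1000)
    compare_regions(d1, d2)$p_value
  }, numeric(1))
  ecdf_p <- ecdf(pvals)
  grid <- seq(0.01, 0.99, by = 0.01)
  dplus <- max(ecdf_p(grid) - grid)
  # one-sided KS band at alpha = 0.01 for n = 60
  expect_lt(dplus, sqrt(-log(0.01) / (2 * 60)))
})

test_that("gene_sex_comparison gates between t and rank tests", {
  set.seed(4)
  f <- rnorm(30, 5); m <- rnorm(30, 5)
  labels <- c(rep("F", 30), rep("M", 30))
  r <- gene_sex_comparison(c(f, m), labels)
  expect_equal(r$test, "t")
  skewed <- c(exp(rnorm(30, 0, 1.5)), exp(rnorm(30, 0.5, 1.5)))
  r2 <- gene_sex_comparison(skewed, labels)
  expect_equal(r2$test, "mann_whitney")
  r3 <- gene_sex_comparison(rep(1, 60), labels)
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)
  expect_error(gene_sex_comparison(1:4, c("F", "F", "M", "M")), ">= 3")
})

test_that("DEG tables serialise to TSV", {
  vals <- matrix(rnorm(20 * 8), 20)
  tab <- rank_genes_wilcoxon(vals, rep(c("A", "B"), each = 4))
  path <- file.path(tempdir(), "deg.tsv")
  write_deg_table(tab, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 20)
  expect_equal(back$p_value, tab$p_value, tolerance = 1e-9)
  unlink(path)
})
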