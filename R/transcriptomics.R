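#' Quality-control filter for single-nucleus counts
#'
#' Applies, in order: (1) nuclei retained if they express at least
#' `min_genes` genes; (2) genes retained if expressed (count > 0) in at least
#' `min_cells` nuclei; (3) nuclei exceeding the `gene_percentile` percentile
#' of total genes expressed removed (percentile computed after the first
#' filter, per sample when a `sample` column is present, with
#' linear-interpolation quantiles); (4) nuclei with mitochondrial expression
#' above `max_mito` of total counts removed.
#'
#' @param cm a [count_matrix()].
#' @param mito_gene_set character vector of mitochondrial gene ids; defaults
#'   to `grep("^mt-", gene_ids, ignore.case = TRUE)`.
#' @param min_genes minimum genes expressed per nucleus (default 200).
#' @param min_cells minimum nuclei expressing a gene (default 3).
#' @param gene_percentile upper percentile for the genes-per-nucleus cap
#'   (default 0.98).
#' @param max_mito maximum mitochondrial count fraction (default 0.05).
#' @return filtered [count_matrix()] with an attached `qc_report` attribute:
#'   a data.frame of per-rule removals.
#' @export
qc_filter <- function(cm, mito_gene_set = NULL, min_genes = 200, min_cells = 3,
                      gene_percentile = 0.98, max_mito = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  if (ncol(counts) == 0 || nrow(counts) == 0) stop("empty count matrix")
  if (is.null(mito_gene_set))
    mito_gene_set <- cm$gene_ids[grepl("^mt-", cm$gene_ids, ignore.case = TRUE)]

  report <- list()
  keep_cells <- rep(TRUE, ncol(counts))
  keep_genes <- rep(TRUE, nrow(counts))
  genes_per_cell <- Matrix::colSums(counts > 0)

  # rule 1: minimum genes per nucleus
  r1 <- genes_per_cell >= min_genes
  report$min_genes <- sum(!r1)
  keep_cells <- keep_cells & r1
  if (!any(keep_cells)) stop("all nuclei removed by the min-genes rule")

  # rule 2: gene expressed in enough retained nuclei
  cells_per_gene <- Matrix::rowSums(counts[, keep_cells, drop = FALSE] > 0)
  r2 <- cells_per_gene >= min_cells
  report$min_cells <- sum(!r2)
  keep_genes <- keep_genes & r2
  if (!any(keep_genes)) stop("all genes removed by the min-cells rule")

  # rule 3: upper percentile of genes expressed, per sample; the percentile
  # is computed over the nuclei surviving rule 1, on the raw gene totals
  gpc <- genes_per_cell
  samp <- if ("sample" %in% names(cm$nucleus_meta)) cm$nucleus_meta$sample
          else rep("all", ncol(counts))
  r3 <- rep(TRUE, ncol(counts))
  for (s in unique(samp)) {
    idx <- samp == s & keep_cells
    if (!any(idx)) next
    cap <- stats::quantile(gpc[idx], gene_percentile, type = 7, names = FALSE)
    r3[idx] <- gpc[idx] <= cap
  }
  report$gene_percentile <- sum(keep_cells & !r3)
  keep_cells <- keep_cells & r3
  if (!any(keep_cells)) stop("all nuclei removed by the percentile rule")

  # rule 4: mitochondrial fraction
  mito_idx <- cm$gene_ids %in% mito_gene_set
  total <- Matrix::colSums(counts)
  mito_frac <- if (any(mito_idx))
    Matrix::colSums(counts[mito_idx, , drop = FALSE]) / pmax(total, 1)
  else rep(0, ncol(counts))
  r4 <- mito_frac <= max_mito
  report$max_mito <- sum(keep_cells & !r4)
  keep_cells <- keep_cells & r4
  if (!any(keep_cells)) stop("all nuclei removed by the mito rule")

  out <- count_matrix(counts[keep_genes, keep_cells, drop = FALSE],
                      cm$gene_ids[keep_genes],
                      cm$nucleus_meta[keep_cells, , drop = FALSE])
  attr(out, "qc_report") <- data.frame(rule = names(report),
                                       removed = unlist(report, use.names = FALSE))
  out
}

#' Library-size normalisation with log1p transform
#'
#' Each nucleus is scaled to `target_sum` total counts and log-transformed:
#' `value = log(1 + count / total * target_sum)`.
#'
#' @param cm a (filtered) [count_matrix()]; every nucleus must have a positive
#'   total.
#' @param target_sum target counts per nucleus (default 1e6).
#' @return object of class `normalized_matrix`: `values` (genes x nuclei,
#'   dense), `gene_ids`, `nucleus_meta`, `target_sum`.
#' @export
normalize_log1p <- function(cm, target_sum = 1e6) {
  stopifnot(inherits(cm, "count_matrix"))
  total <- Matrix::colSums(cm$counts)
  if (any(total <= 0)) stop("nucleus with zero total counts")
  vals <- log1p(sweep(as.matrix(cm$counts), 2, total, `/`) * target_sum)
  structure(list(values = vals, gene_ids = cm$gene_ids,
                 nucleus_meta = cm$nucleus_meta, target_sum = target_sum),
            class = "normalized_matrix")
}

#' Classify nuclei by projection target from marker co-expression
#'
#' Core-projecting dopamine neurons co-express Calb1 and Sox6; shell-projecting
#' neurons co-express Calb1 and Aldh1a1. "Expressed" means normalised value
#' strictly above `threshold` (default 0, i.e. any count). Nuclei satisfying
#' both definitions are labelled `ambiguous`; nuclei satisfying neither are
#' `unassigned`.
#'
#' @param norm a [normalize_log1p()] result.
#' @param markers named character vector with entries `calb1`, `sox6`,
#'   `aldh1a1` giving the gene ids to use.
#' @param threshold expression cutoff on the normalised scale.
#' @return factor of length n-nuclei with levels
#'   `core, shell, ambiguous, unassigned`.
#' @export
classify_projection <- function(norm,
                                markers = c(calb1 = "Calb1", sox6 = "Sox6",
                                            aldh1a1 = "Aldh1a1"),
                                threshold = 0) {
  stopifnot(inherits(norm, "normalized_matrix"))
  missing <- setdiff(unname(markers), norm$gene_ids)
  if (length(missing))
    stop("marker gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  expr <- norm$values[match(markers, norm$gene_ids), , drop = FALSE] > threshold
  rownames(expr) <- names(markers)
  core <- expr["calb1", ] & expr["sox6", ]
  shell <- expr["calb1", ] & expr["aldh1a1", ]
  lab <- rep("unassigned", ncol(norm$values))
  lab[core & !shell] <- "core"
  lab[shell & !core] <- "shell"
  lab[core & shell] <- "ambiguous"
  factor(lab, levels = c("core", "shell", "ambiguous", "unassigned"))
}

# Row-wise two-sided tie-corrected Wilcoxon rank-sum (normal approximation,
# no continuity correction — matrix-scale convention). Returns a 2 x n_genes
# matrix with rows (U for group 1, p).
.wilcox_rows <- function(mat, g1_idx, g2_idx) {
  n1 <- length(g1_idx); n2 <- length(g2_idx)
  n <- n1 + n2
  sub <- mat[, c(g1_idx, g2_idx), drop = FALSE]
  mu <- n1 * n2 / 2
  apply(sub, 1, function(v) {
    r <- rank(v)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    tie_tab <- tabulate(match(r, unique(r)))
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    p <- if (sigma2 <= 0) 1 else
      min(1, 2 * stats::pnorm(-abs(u - mu) / sqrt(sigma2)))
    c(u, p)
  })
}

#' Per-gene Wilcoxon rank-sum differential expression
#'
#' Two-sided tie-corrected normal-approximation rank-sum test per gene between
#' two groups of nuclei on normalised log1p values. The log2 fold change is
#' computed on back-transformed (expm1) group means with a pseudo-count:
#' `log2((mean(expm1(g1)) + eps) / (mean(expm1(g2)) + eps))`. P-values are
#' Benjamini-Hochberg adjusted across genes; a gene is significant when
#' `|log2fc| > lfc_threshold` and `padj < alpha`.
#'
#' @param norm a [normalize_log1p()] result (or any genes x samples matrix via
#'   `values`).
#' @param group_labels vector of two distinct labels, one per nucleus.
#' @param group1 label treated as the numerator group; default the first
#'   distinct label.
#' @param lfc_threshold absolute log2 fold-change cutoff (default 0.5).
#' @param alpha adjusted-p cutoff (default 0.025: 0.05 Bonferroni-corrected
#'   for two regions).
#' @param eps pseudo-count on back-transformed means.
#' @return data.frame of class `deg_table`: `gene`, `statistic` (U for
#'   group1), `p_value`, `padj`, `log2fc`, `significant`.
#' @export
rank_genes_wilcoxon <- function(norm, group_labels, group1 = NULL,
                                lfc_threshold = 0.5, alpha = 0.025,
                                eps = 1e-9) {
  vals <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  gene_ids <- if (inherits(norm, "normalized_matrix")) norm$gene_ids
              else rownames(vals)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(vals)))
  labs <- unique(group_labels)
  if (length(labs) != 2) stop("exactly two groups required")
  if (is.null(group1)) group1 <- labs[1]
  g1 <- which(group_labels == group1)
  g2 <- which(group_labels != group1)
  if (length(g1) < 2 || length(g2) < 2) stop("each group needs >= 2 nuclei")

  up <- .wilcox_rows(vals, g1, g2)
  u <- up[1, ]; p <- up[2, ]
  # back-transformed means are clamped at zero: log1p-normalised input is
  # non-negative, but arbitrary matrices passed directly may not be
  m1 <- pmax(rowMeans(expm1(vals[, g1, drop = FALSE])), 0)
  m2 <- pmax(rowMeans(expm1(vals[, g2, drop = FALSE])), 0)
  lfc <- log2((m1 + eps) / (m2 + eps))
  padj <- benjamini_hochberg(p)
  out <- data.frame(gene = gene_ids, statistic = u, p_value = p, padj = padj,
                    log2fc = lfc,
                    significant = abs(lfc) > lfc_threshold & padj < alpha,
                    row.names = NULL)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Balanced-bootstrap DEG counting
#'
#' The number of sex-differential genes in a population depends on its size;
#' to compare populations fairly, each bootstrap iteration draws `n_per_sex`
#' nuclei with replacement from each sex, runs the per-gene Wilcoxon test and
#' counts genes passing both the fold-change and adjusted-p thresholds. The
#' RNG stream is deterministic given `seed`.
#'
#' @param norm a [normalize_log1p()] result restricted to one population
#'   (e.g. core-projecting nuclei).
#' @param sex_labels per-nucleus labels in `{F, M}`; defaults to
#'   `norm$nucleus_meta$sex`.
#' @param n_boot bootstrap iterations (default 50).
#' @param n_per_sex nuclei drawn per sex per iteration (default 30).
#' @param lfc_threshold,alpha significance thresholds (defaults 0.5, 0.025).
#' @param seed integer RNG seed.
#' @param keep_genes also record, per iteration, which genes were significant.
#' @return object of class `deg_count_distribution`: integer vector `counts`
#'   of length `n_boot`; when `keep_genes` is TRUE an attribute
#'   `gene_hits` (genes x iterations logical matrix).
#' @export
bootstrap_deg_counts <- function(norm, sex_labels = norm$nucleus_meta$sex,
                                 n_boot = 50, n_per_sex = 30,
                                 lfc_threshold = 0.5, alpha = 0.025,
                                 seed = 1L, keep_genes = FALSE) {
  stopifnot(n_boot >= 1, n_per_sex >= 2)
  f_idx <- which(sex_labels == "F")
  m_idx <- which(sex_labels == "M")
  if (length(f_idx) == 0 || length(m_idx) == 0)
    stop("both sexes must be present in the population")
  vals <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  gene_ids <- if (inherits(norm, "normalized_matrix")) norm$gene_ids
              else rownames(vals)

  counts <- integer(n_boot)
  hits <- if (keep_genes) matrix(FALSE, nrow(vals), n_boot,
                                 dimnames = list(gene_ids, NULL))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      fs <- sample(f_idx, n_per_sex, replace = TRUE)
      ms <- sample(m_idx, n_per_sex, replace = TRUE)
      sub <- vals[, c(fs, ms), drop = FALSE]
      labs <- rep(c("F", "M"), each = n_per_sex)
      tab <- rank_genes_wilcoxon(sub, labs, group1 = "F",
                                 lfc_threshold = lfc_threshold, alpha = alpha)
      counts[b] <- sum(tab$significant)
      if (keep_genes) hits[, b] <- tab$significant
    }
  })
  structure(list(counts = counts), class = "deg_count_distribution",
            gene_hits = hits)
}

#' Compare DEG-count distributions between two populations
#'
#' Two-sided Mann-Whitney U test on the bootstrap DEG counts of two
#' projection populations. `U` is reported for the first population under the
#' larger-is-bigger convention, so complete separation with the first
#' population higher gives `U = n1 * n2`.
#'
#' @param dist1,dist2 [bootstrap_deg_counts()] results (or bare numeric
#'   vectors).
#' @return a `rank_test` result (see [mann_whitney_u()]).
#' @export
compare_regions <- function(dist1, dist2) {
  x <- if (inherits(dist1, "deg_count_distribution")) dist1$counts else dist1
  y <- if (inherits(dist2, "deg_count_distribution")) dist2$counts else dist2
  if (length(x) == 0 || length(y) == 0) stop("empty distribution")
  mann_whitney_u(x, y, "two.sided", continuity = FALSE)
}

#' Sex comparison of one gene's expression
#'
#' Assumption-gated two-sample test: when both groups pass a Shapiro-Wilk
#' normality check (p > 0.05) and the variance ratio is below `var_ratio_max`,
#' an unpaired equal-variance t test is used; otherwise a Mann-Whitney test.
#'
#' @param values per-nucleus expression of one gene.
#' @param sex_labels labels in `{F, M}`, one per value; >= 3 per sex.
#' @param var_ratio_max maximum admissible variance ratio (default 4).
#' @return list: `test` (`"t"` or `"mann_whitney"`), `statistic`, `p_value`,
#'   `degenerate` flag.
#' @export
gene_sex_comparison <- function(values, sex_labels, var_ratio_max = 4) {
  f <- values[sex_labels == "F"]
  m <- values[sex_labels == "M"]
  if (length(f) < 3 || length(m) < 3) stop("need >= 3 nuclei per sex")
  if (stats::var(c(f, m)) == 0)
    return(list(test = "degenerate", statistic = NA_real_, p_value = 1,
                degenerate = TRUE))
  normal_ok <- function(v) {
    if (stats::var(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > 0.05
  }
  vr <- {
    vf <- stats::var(f); vm <- stats::var(m)
    if (vf == 0 || vm == 0) Inf else max(vf, vm) / min(vf, vm)
  }
  if (normal_ok(f) && normal_ok(m) && vr < var_ratio_max) {
    tt <- stats::t.test(f, m, var.equal = TRUE)
    list(test = "t", statistic = unname(tt$statistic),
         p_value = tt$p.value, degenerate = FALSE)
  } else {
    mw <- mann_whitney_u(f, m)
    list(test = "mann_whitney", statistic = mw$statistic,
         p_value = mw$p_value, degenerate = FALSE)
  }
}

#' Write a DEG table as TSV
#' @param tab a `deg_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
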