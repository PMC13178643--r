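#' Single-nucleus count simulation parameters
#'
#' Negative-binomial gene x nucleus counts with projection-class marker
#' structure and optional planted sex-differential genes. Nuclei come in four
#' groups (sex F/M x projection core/shell). Counts for gene g in nucleus j
#' are NB with mean `mu_gj = baseline_mean_g * marker_factor * sex_factor *
#' libsize_j` and dispersion `dispersion` (variance `mu + dispersion * mu^2`).
#'
#' Marker structure follows the projection mapping of midbrain dopamine
#' neurons: core-projecting nuclei co-express Calb1 and Sox6; shell-projecting
#' nuclei co-express Calb1 and Aldh1a1; the off-class marker is silenced.
#'
#' @param n_nuclei nuclei per (sex x projection) group; scalar or named vector
#'   with names `F_core`, `M_core`, `F_shell`, `M_shell`.
#' @param n_genes total gene count (markers included).
#' @param baseline_mean per-gene NB mean; scalar (recycled) or length
#'   `n_genes`.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param marker_design list with `genes = c(calb1=, sox6=, aldh1a1=)` gene
#'   indices and `on_mean` / `off_mean` expression means per class.
#' @param sex_effect data.frame with columns `gene` (index), `lfc` (log2 fold
#'   change, female over male) and `projection` (`"core"`, `"shell"` or
#'   `"both"`); may have zero rows.
#' @param libsize_spread sd of the log-normal library-size multiplier
#'   (mean 1 on the log scale 0).
#' @param mito_genes integer indices treated as mitochondrial (named
#'   `mt-...`).
#' @param seed integer RNG seed.
#' @return object of class `count_sim_params`.
#' @export
count_sim_params <- function(n_nuclei = 50, n_genes = 2000, baseline_mean = 5,
                             dispersion = 0.2,
                             marker_design = list(genes = c(calb1 = 1, sox6 = 2,
                                                            aldh1a1 = 3),
                                                  on_mean = 50, off_mean = 0),
                             sex_effect = data.frame(gene = integer(),
                                                     lfc = numeric(),
                                                     projection = character()),
                             libsize_spread = 0.3,
                             mito_genes = integer(), seed = 1L) {
  if (length(n_nuclei) == 1) {
    n_nuclei <- stats::setNames(rep(as.integer(n_nuclei), 4),
                                c("F_core", "M_core", "F_shell", "M_shell"))
  }
  stopifnot(all(c("F_core", "M_core", "F_shell", "M_shell") %in% names(n_nuclei)))
  if (any(n_nuclei < 1)) stop("each group needs >= 1 nucleus")
  if (length(baseline_mean) == 1) baseline_mean <- rep(baseline_mean, n_genes)
  if (length(baseline_mean) != n_genes) stop("baseline_mean length mismatch")
  if (any(baseline_mean < 0)) stop("baseline_mean must be >= 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (any(marker_design$genes > n_genes) || any(marker_design$genes < 1))
    stop("marker_design references a gene index outside 1..n_genes")
  if (nrow(sex_effect) && (any(sex_effect$gene > n_genes) || any(sex_effect$gene < 1)))
    stop("sex_effect references a gene index outside 1..n_genes")
  if (any(mito_genes > n_genes)) stop("mito gene index outside 1..n_genes")
  structure(list(n_nuclei = n_nuclei, n_genes = as.integer(n_genes),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 marker_design = marker_design, sex_effect = sex_effect,
                 libsize_spread = libsize_spread,
                 mito_genes = as.integer(mito_genes), seed = as.integer(seed)),
            class = "count_sim_params")
}

#' Simulate a single-nucleus count matrix
#'
#' @param params a [count_sim_params()] object.
#' @return object of class `count_matrix`: `counts` (sparse dgCMatrix,
#'   genes x nuclei), `gene_ids`, `nucleus_meta` (data.frame: `nucleus_id`,
#'   `sex`, `sample`, `projection_truth`). Deterministic given `params$seed`.
#' @export
simulate_counts <- function(params) {
  stopifnot(inherits(params, "count_sim_params"))
  with_seed(params$seed, {
    grp <- params$n_nuclei
    sex <- rep(c("F", "M", "F", "M"), grp)
    proj <- rep(c("core", "core", "shell", "shell"), grp)
    n_cells <- sum(grp)
    n_genes <- params$n_genes

    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    md <- params$marker_design
    gene_ids[md$genes["calb1"]] <- "Calb1"
    gene_ids[md$genes["sox6"]] <- "Sox6"
    gene_ids[md$genes["aldh1a1"]] <- "Aldh1a1"
    if (length(params$mito_genes))
      gene_ids[params$mito_genes] <- sprintf("mt-gene%03d",
                                             seq_along(params$mito_genes))

    # per-cell library-size multipliers, log-normal centred at 1
    libsize <- exp(stats::rnorm(n_cells, 0, params$libsize_spread))

    # gene x cell mean matrix
    mu <- matrix(params$baseline_mean, nrow = n_genes, ncol = n_cells)
    is_core <- proj == "core"
    mu[md$genes["calb1"], ] <- md$on_mean
    mu[md$genes["sox6"], ] <- ifelse(is_core, md$on_mean, md$off_mean)
    mu[md$genes["aldh1a1"], ] <- ifelse(is_core, md$off_mean, md$on_mean)
    se <- params$sex_effect
    if (nrow(se)) {
      for (k in seq_len(nrow(se))) {
        affected <- sex == "F" &
          (se$projection[k] == "both" | proj == se$projection[k])
        mu[se$gene[k], affected] <- mu[se$gene[k], affected] * 2^se$lfc[k]
      }
    }
    mu <- sweep(mu, 2, libsize, `*`)

    counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                    size = 1 / params$dispersion),
                     nrow = n_genes)
    meta <- data.frame(
      nucleus_id = sprintf("nuc%05d", seq_len(n_cells)),
      sex = sex,
      sample = paste0("sample_", sex),
      projection_truth = proj,
      stringsAsFactors = FALSE)
    count_matrix(Matrix::Matrix(counts, sparse = TRUE), gene_ids, meta)
  })
}

#' Construct a count-matrix container
#'
#' @param counts genes x nuclei matrix of non-negative integers (dense or
#'   sparse).
#' @param gene_ids character vector, length `nrow(counts)`.
#' @param nucleus_meta data.frame with one row per nucleus; must contain a
#'   `sex` column with values in `{F, M}` (other columns are free-form).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids, nucleus_meta) {
  if (nrow(counts) != length(gene_ids)) stop("gene_ids length mismatch")
  if (ncol(counts) != nrow(nucleus_meta)) stop("nucleus_meta row mismatch")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!"sex" %in% names(nucleus_meta)) stop("nucleus_meta must have a sex column")
  rownames(counts) <- gene_ids
  colnames(counts) <- nucleus_meta$nucleus_id
  structure(list(counts = counts, gene_ids = gene_ids,
                 nucleus_meta = nucleus_meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d nuclei (%d F / %d M)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$nucleus_meta$sex == "F"), sum(x$nucleus_meta$sex == "M")))
  invisible(x)
}

#' Write / read counts as a MatrixMarket triplet plus metadata TSV
#'
#' Files written under `dir`: `matrix.mtx` (genes x nuclei), `genes.tsv`,
#' `barcodes.tsv`, `metadata.tsv` (nucleus_id, sex, sample, truth labels).
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; `read_counts_mtx` returns a [count_matrix()].
#' @export
write_counts_mtx <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(cm$counts, "dMatrix"), "TsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(cm$nucleus_meta$nucleus_id, file.path(dir, "barcodes.tsv"))
  utils::write.table(cm$nucleus_meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  count_matrix(methods::as(m, "CsparseMatrix"), genes, meta)
}
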