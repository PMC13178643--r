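# Independent oracles used across the suite. These deliberately avoid the
# code paths they are checking.

# Fine-step forward-Euler integrator for the pulsed-release / MM-clearance
# model; the package integrator is RK4 at 1 kHz, this is Euler at `dt`.
euler_mm_oracle <- function(times, pulses, dap, vmax, km, dt = 1e-4) {
  t_end <- max(times)
  n_steps <- ceiling(t_end / dt)
  pulse_steps <- round(pulses / dt)
  c_now <- 0
  out <- numeric(length(times))
  out_i <- 1
  sample_steps <- round(times / dt)
  for (step in 0:n_steps) {
    if (any(pulse_steps == step)) c_now <- c_now + dap * sum(pulse_steps == step)
    while (out_i <= length(times) && sample_steps[out_i] == step) {
      out[out_i] <- c_now
      out_i <- out_i + 1
    }
    c_now <- c_now - dt * vmax * c_now / (km + c_now)
    if (c_now < 0) c_now <- 0
  }
  out
}

# Exhaustive-enumeration Mann-Whitney oracle for tie-free samples:
# enumerates all C(n1+n2, n1) assignments of the pooled ranks.
mw_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled_ranks <- rank(c(x, y))
  u_obs <- sum(pooled_ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  all_ranks <- seq_len(n1 + n2)
  u_all <- apply(combos, 2, function(idx) sum(all_ranks[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(u = u_obs, p_two = min(1, 2 * min(p_le, p_ge)),
       p_greater = p_ge, p_less = p_le)
}

# Direct step-up BH formula on sorted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# 12-nucleus x 50-gene toy matrix with hand-computable QC outcomes under
# min_genes = 10 (the 200-gene rule scaled to the toy's dimensions;
# arithmetic unchanged), min_cells = 3, percentile 0.98, mito 5%:
#  - c10 expresses 5 genes -> min-genes rule.
#  - genes g31..g35 sit in exactly 3 retained nuclei -> retained (boundary);
#    g36..g37 in exactly 2 -> removed; g38..g47 only in c11 -> removed;
#    g48..g49 in none -> removed; mt-nd1 only in c12 -> removed.
#  - raw genes-per-nucleus over the 11 rule-1 survivors are
#    {35,35,35,32,32,30,30,30,30,40,31}; the 98th percentile (type 7)
#    is 35 + 0.8*(40-35) = 39, so only c11 (40) is removed.
#  - c12 puts 10 of its 100 counts on mt-nd1 (10% > 5%) -> mito rule.
# Expected survivors: nuclei c1..c9 and genes g1..g35.
qc_toy <- function() {
  n_genes <- 50; n_cells <- 12
  m <- matrix(0L, n_genes, n_cells)
  m[1:30, 1:9] <- 1L          # core block
  m[31:35, 1:3] <- 1L         # min-cells boundary pass (3 nuclei)
  m[36:37, 4:5] <- 1L         # min-cells boundary fail (2 nuclei)
  m[1:5, 10] <- 1L            # c10: too few genes
  m[c(1:30, 38:47), 11] <- 1L # c11: 40 genes, percentile outlier
  m[1:30, 12] <- 3L           # c12: 90 counts on ordinary genes ...
  m[50, 12] <- 10L            # ... plus 10 on the mito gene = 10%
  gene_ids <- c(sprintf("g%02d", 1:49), "mt-nd1")
  meta <- data.frame(nucleus_id = sprintf("c%02d", 1:12),
                     sex = rep(c("F", "M"), 6),
                     sample = "s1", stringsAsFactors = FALSE)
  count_matrix(m, gene_ids, meta)
}

# Small convenience: restrict a normalized matrix to a nucleus subset.
subset_norm <- function(norm, idx) {
  norm$values <- norm$values[, idx, drop = FALSE]
  norm$nucleus_meta <- norm$nucleus_meta[idx, , drop = FALSE]
  norm
}
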