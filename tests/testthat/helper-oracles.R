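# Independent oracles and small fixture builders used across the suite.

# Loop-based log10/pseudocount/Z/back-transform, written independently of the
# vectorized implementation (population standard deviation).
oracle_zscore <- function(mat, pseudocount = 0.01) {
  out <- mat * 0
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col[col == 0] <- pseudocount
    lg <- log10(col)
    mu <- mean(lg)
    s <- sqrt(sum((lg - mu)^2) / length(lg))
    z <- if (s > 0) (lg - mu) / s else rep(0, length(lg))
    out[, j] <- 10^z
  }
  out
}

# Explained-variance ratios via eigendecomposition of the sample covariance.
oracle_pca_ratios <- function(mat, k) {
  ev <- eigen(stats::cov(mat), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  (ev / sum(ev))[seq_len(k)]
}

# Exact two-sided Mann-Whitney p by enumerating index subsets and counting
# pairwise wins directly (no ranks), independent of the implementation.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  u_all <- utils::combn(n, n1, FUN = u_of)
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# Write a small rearrangement TSV; `rows` is a data frame of columns to emit.
write_airr_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

airr_rows <- function(v_call, j_call, cdr3_aa,
                      v_support = 1e-10, j_support = 1e-10,
                      productive = "T", vj_in_frame = "T", stop_codon = "F") {
  data.frame(v_call = v_call, j_call = j_call, cdr3_aa = cdr3_aa,
             v_support = v_support, j_support = j_support,
             productive = productive, vj_in_frame = vj_in_frame,
             stop_codon = stop_codon, stringsAsFactors = FALSE)
}

make_repertoire <- function(donor_id, v, j, cdr3, cohort = NA_character_) {
  structure(list(donor_id = donor_id, cohort = cohort,
                 clonotypes = data.frame(v_gene = v, j_gene = j, cdr3_aa = cdr3,
                                         stringsAsFactors = FALSE)),
            class = "repertoire")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# One standard synthetic run: fingerprint + intra/inter PC distance summary.
run_study_fingerprint <- function(seed, delta, ...) {
  specs <- default_study_specs(delta = delta, ...)
  study <- generate_study(specs$cohort_a, specs$cohort_b, seed = seed)
  fp <- fingerprint(study$counts, subsample = subsample_spec(seed = seed),
                    cluster = cluster_spec(seed = seed))
  list(study = study, fp = fp)
}

separation_ratio <- function(groups) {
  median(groups$inter) / median(c(groups$intra_A, groups$intra_B))
}
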