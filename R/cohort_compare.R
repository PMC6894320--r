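#' Per-donor centroids in principal-component space
#'
#' Each donor's replicate cloud is reduced to its centroid: the arithmetic mean
#' of the donor's replicate coordinates over the first `components` components.
#'
#' @param embedding Matrix from [project_embedding()] with a `"row_donors"`
#'   attribute (one donor id per row).
#' @param components Component columns used (default PC1+2).
#' @return Numeric matrix, one row per donor.
#' @export
donor_centroids <- function(embedding, components = 1:2) {
  donors <- attr(embedding, "row_donors")
  if (is.null(donors)) stop("embedding lacks a 'row_donors' attribute")
  components <- components[components <= ncol(embedding)]
  x <- embedding[, components, drop = FALSE]
  ids <- unique(donors)
  cent <- t(vapply(ids, function(d) colMeans(x[donors == d, , drop = FALSE]),
                   numeric(ncol(x))))
  rownames(cent) <- ids
  cent
}

make_distance_records <- function(value_fun, donor_ids, cohorts, metric) {
  missing <- donor_ids[!donor_ids %in% names(cohorts) | is.na(cohorts[donor_ids])]
  if (length(missing) > 0L) {
    stop("donor(s) missing a cohort label: ", paste(missing, collapse = ", "))
  }
  if (length(donor_ids) < 2L) stop("need at least 2 donors for pairwise distances")
  labels <- sort(unique(cohorts[donor_ids]))
  pairs <- utils::combn(donor_ids, 2L)
  recs <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    ca <- cohorts[[a]]; cb <- cohorts[[b]]
    group <- if (ca == cb) paste0("intra_", ca) else "inter"
    data.frame(donor_a = a, donor_b = b, group = group, metric = metric,
               value = value_fun(a, b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  attr(out, "cohort_labels") <- labels
  out
}

#' Pairwise donor distances in PC space
#'
#' One record per unordered donor pair: the Euclidean distance between the two
#' donors' replicate centroids in PC1+2 (or the requested components), labelled
#' `intra_<cohort>` when both donors share a cohort and `inter` otherwise.
#'
#' @param embedding Matrix from [project_embedding()].
#' @param cohorts Named character vector mapping donor id to cohort label.
#' @param components Component columns used for the distance.
#' @return Data frame of distance records: `donor_a`, `donor_b`, `group`,
#'   `metric`, `value`.
#' @export
pc_pairwise_distances <- function(embedding, cohorts, components = 1:2) {
  cent <- donor_centroids(embedding, components)
  make_distance_records(
    function(a, b) sqrt(sum((cent[a, ] - cent[b, ])^2)),
    rownames(cent), cohorts, metric = "pc_euclidean"
  )
}

#' RDI specification
#' @param depth Bootstrap subsample size per donor per iteration.
#' @param n_boot Number of bootstrap iterations averaged.
#' @param seed Base RNG seed.
#' @return An object of class `rdi_spec`.
#' @export
rdi_spec <- function(depth = 100000L, n_boot = 100L, seed = 1L) {
  stopifnot(depth >= 1, n_boot >= 1)
  structure(list(depth = as.integer(depth), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "rdi_spec")
}

#' Repertoire Dissimilarity Index between two count vectors
#'
#' Bootstrap gene-usage distance: in each of `n_boot` iterations both donors
#' are subsampled with replacement to `depth`, converted to frequency vectors,
#' and the Euclidean norm of their difference is taken; the RDI is the mean
#' over iterations. This is the plain frequency-vector core of the index, with
#' no baseline subtraction or unit calibration. The pair is put in a canonical
#' order before drawing, so `compute_rdi(a, b)` equals `compute_rdi(b, a)`
#' bit-for-bit.
#'
#' @param counts_a,counts_b Nonnegative count vectors over a shared feature
#'   space, each with positive sum.
#' @param spec An [rdi_spec()].
#' @param pair_id Optional label mixed into the seed so different donor pairs
#'   use independent bootstrap streams.
#' @return Nonnegative scalar.
#' @export
compute_rdi <- function(counts_a, counts_b, spec = rdi_spec(), pair_id = "") {
  if (length(counts_a) != length(counts_b)) {
    stop("count vectors must share one feature space")
  }
  if (sum(counts_a) <= 0 || sum(counts_b) <= 0) {
    stop("RDI requires both count vectors to have positive sums")
  }
  # canonical order => exact symmetry in the bootstrap draws
  key_a <- paste(counts_a, collapse = ",")
  key_b <- paste(counts_b, collapse = ",")
  if (key_a > key_b) {
    tmp <- counts_a; counts_a <- counts_b; counts_b <- tmp
  }
  with_seed(derive_seed(spec$seed, paste0("rdi|", pair_id)), {
    fa <- stats::rmultinom(spec$n_boot, spec$depth, counts_a) / spec$depth
    fb <- stats::rmultinom(spec$n_boot, spec$depth, counts_b) / spec$depth
    mean(sqrt(colSums((fa - fb)^2)))
  })
}

#' Pairwise donor RDI distances
#'
#' @param counts Donors-by-pairs count matrix.
#' @param cohorts Named character vector mapping donor id to cohort label.
#' @param spec An [rdi_spec()].
#' @return Data frame of distance records (`metric = "rdi"`).
#' @export
rdi_pairwise_distances <- function(counts, cohorts, spec = rdi_spec()) {
  make_distance_records(
    function(a, b) {
      pid <- paste(sort(c(a, b)), collapse = "|")
      compute_rdi(counts[a, ], counts[b, ], spec, pair_id = pid)
    },
    rownames(counts), cohorts, metric = "rdi"
  )
}

#' Split distance records into intra- and inter-cohort value lists
#'
#' @param records Data frame of distance records sharing one metric.
#' @return Named list of numeric vectors: one per intra-cohort group (in
#'   lexicographic cohort order) plus `inter`; sizes sum to `nrow(records)`.
#' @export
split_intra_inter <- function(records) {
  if (nrow(records) > 0L && length(unique(records$metric)) > 1L) {
    stop("distance records mix metrics: ",
         paste(unique(records$metric), collapse = ", "))
  }
  intra_groups <- sort(unique(records$group[records$group != "inter"]))
  out <- lapply(intra_groups, function(g) records$value[records$group == g])
  names(out) <- intra_groups
  out$inter <- records$value[records$group == "inter"]
  out
}

#' Two-sided Mann-Whitney rank test
#'
#' Computes the Mann-Whitney U statistic with mid-ranks for ties. The p-value
#' is exact — full enumeration of all `choose(n1 + n2, n1)` assignments of the
#' pooled observed values to the first group — whenever that count is at most
#' `max_enumeration`; the two-sided p is `min(1, 2 * min(P(U <= u), P(U >= u)))`
#' over the enumerated null. Larger samples use the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y Nonempty numeric vectors.
#' @param max_enumeration Largest combination count enumerated exactly.
#' @return List of class `mw_test`: `u_statistic` (U for `x`), `p_two_sided`,
#'   `n1`, `n2`, `method` (`"exact"` or `"normal-approximation"`).
#' @examples
#' mann_whitney_two_sided(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1
#' @export
mann_whitney_two_sided <- function(x, y, max_enumeration = 1e6) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n_comb <- choose(n1 + n2, n1)

  if (n_comb <= max_enumeration) {
    rank_sums <- utils::combn(n1 + n2, n1, FUN = function(idx) sum(r[idx]))
    u_all <- rank_sums - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_le <- mean(u_all <= u_obs + eps)
    p_ge <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    cc <- sign(u_obs - mu) * 0.5
    z <- (u_obs - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(u_statistic = u_obs, p_two_sided = p, n1 = n1, n2 = n2,
                 method = method),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank test (%s): U = %g, n = %d vs %d, two-sided p = %.4g\n",
              x$method, x$u_statistic, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

#' Intra- versus inter-cohort rank tests for one distance metric
#'
#' Mirrors the standard cohort comparison: each intra-cohort distance
#' distribution is tested against the inter-cohort distances with a two-sided
#' Mann-Whitney rank test.
#'
#' @param records Data frame of distance records (one metric).
#' @return Data frame with one row per intra-cohort group: `group`, `metric`,
#'   `n_intra`, `n_inter`, `u_statistic`, `p_two_sided`, `method`.
#' @export
intra_inter_tests <- function(records) {
  groups <- split_intra_inter(records)
  inter <- groups$inter
  if (length(inter) == 0L) stop("no inter-cohort pairs; need two cohorts")
  intra_names <- setdiff(names(groups), "inter")
  rows <- lapply(intra_names, function(g) {
    t <- mann_whitney_two_sided(groups[[g]], inter)
    data.frame(group = g, metric = records$metric[[1L]],
               n_intra = t$n1, n_inter = t$n2, u_statistic = t$u_statistic,
               p_two_sided = t$p_two_sided, method = t$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write distance records as TSV
#' @param records Distance record data frame.
#' @param path Output path.
#' @export
write_distance_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
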