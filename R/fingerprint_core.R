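#' Subsampling specification
#'
#' Replicates are multinomial redraws of a donor's V-J counts at a fixed depth,
#' simulating repeated resequencing at uniform coverage. Defaults follow the
#' standard protocol: depth 1e5 and 10 replicates per donor.
#'
#' @param depth Draw size per replicate (>= 1).
#' @param n_replicates Number of replicates per donor (>= 1).
#' @param seed Base RNG seed; each donor gets an independent stream derived
#'   from this seed and the donor id.
#' @return An object of class `subsample_spec`.
#' @export
subsample_spec <- function(depth = 100000L, n_replicates = 10L, seed = 1L) {
  stopifnot(depth >= 1, n_replicates >= 1)
  structure(list(depth = as.integer(depth), n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "subsample_spec")
}

#' Draw subsampled replicates for one donor
#'
#' Each replicate is an independent multinomial draw of size `spec$depth` with
#' cell probabilities proportional to `counts`, so every replicate row sums
#' exactly to the depth.
#'
#' @param counts Nonnegative count vector (not all zero) over the feature space.
#' @param spec A [subsample_spec()].
#' @param donor_id Label used for the donor-specific seed stream and row names.
#' @return Integer matrix with `spec$n_replicates` rows and one column per
#'   feature; row names are `"<donor_id>|<replicate>"`.
#' @export
subsample_replicates <- function(counts, spec = subsample_spec(), donor_id = "donor") {
  if (all(counts == 0)) {
    stop("cannot subsample donor '", donor_id, "': all V-J counts are zero")
  }
  reps <- with_seed(derive_seed(spec$seed, donor_id), {
    t(stats::rmultinom(spec$n_replicates, size = spec$depth, prob = counts))
  })
  dimnames(reps) <- list(paste0(donor_id, "|", seq_len(spec$n_replicates)),
                         names(counts))
  reps
}

#' Build the joint replicate matrix for a study
#'
#' Stacks the subsampled replicates of every donor into one matrix; this is the
#' input to [zscore_normalize()] and PCA.
#'
#' @param counts Donors-by-pairs matrix from [vj_count_table()].
#' @param spec A [subsample_spec()].
#' @return Integer matrix (`donors * n_replicates` rows) with a `"row_donors"`
#'   attribute giving each row's donor id.
#' @export
build_replicate_matrix <- function(counts, spec = subsample_spec()) {
  blocks <- lapply(rownames(counts), function(d) {
    subsample_replicates(counts[d, ], spec, donor_id = d)
  })
  m <- do.call(rbind, blocks)
  attr(m, "row_donors") <- rep(rownames(counts), each = spec$n_replicates)
  attr(m, "depth") <- spec$depth
  m
}

#' Normalization specification
#'
#' @param pseudocount Value replacing zero counts before the log10 transform.
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(pseudocount = 0.01) {
  stopifnot(pseudocount > 0)
  structure(list(pseudocount = pseudocount, log_base = 10), class = "normalization_spec")
}

#' Log10 / Z-score / back-transform normalization
#'
#' Per feature column: zeros are replaced by the pseudocount, counts are log10
#' transformed, converted to a Z score across rows (subtracting the column mean
#' and dividing by the population standard deviation, i.e. divisor `n`), and
#' transformed back out of log space as `10^Z`. Columns with zero variance in
#' log space get Z = 0 everywhere (back-transformed value 1). The transform
#' de-emphasizes features with very low or no counts while keeping all values
#' strictly positive.
#'
#' @param mat Numeric matrix, >= 2 rows (replicates) by features.
#' @param spec A [normalization_spec()].
#' @return Numeric matrix of the same shape; attributes of `mat` (row donors,
#'   dimnames) are preserved.
#' @export
zscore_normalize <- function(mat, spec = normalization_spec()) {
  if (!is.matrix(mat) || nrow(mat) < 2L) {
    stop("normalization requires a matrix with at least 2 rows")
  }
  x <- mat
  x[x == 0] <- spec$pseudocount
  logs <- log10(x)
  mu <- colMeans(logs)
  centered <- sweep(logs, 2L, mu)
  sd_pop <- sqrt(colMeans(centered^2))
  z <- sweep(centered, 2L, ifelse(sd_pop > 0, sd_pop, 1), `/`)
  z[, sd_pop == 0] <- 0
  out <- 10^z
  dimnames(out) <- dimnames(mat)
  attr(out, "row_donors") <- attr(mat, "row_donors")
  out
}

#' Fit a principal component analysis model
#'
#' Columns are mean-centered (no further scaling: the Z-score normalization has
#' already put features on a common scale) and decomposed into orthonormal
#' components ordered by decreasing explained variance. If the matrix has zero
#' total variance the model is degenerate: all explained-variance ratios are
#' reported as 0 and a warning is emitted.
#'
#' @param mat Normalized matrix from [zscore_normalize()].
#' @param n_components Number of components to keep,
#'   `<= min(nrow - 1, ncol)`.
#' @return An object of class `pca_model`: `loadings` (components x features),
#'   `explained_variance_ratio`, `center` (column means), `feature_names`.
#' @export
fit_pca <- function(mat, n_components = 2L) {
  stopifnot(is.matrix(mat))
  kmax <- min(nrow(mat) - 1L, ncol(mat))
  if (n_components > kmax) {
    stop("n_components (", n_components, ") exceeds min(rows - 1, features) = ", kmax)
  }
  fit <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  total_var <- sum(fit$sdev^2)
  if (total_var <= .Machine$double.eps * ncol(mat)) {
    warning("matrix has zero total variance; PCA model is degenerate")
    ratios <- rep(0, n_components)
  } else {
    ratios <- (fit$sdev^2 / total_var)[seq_len(n_components)]
  }
  loadings <- t(fit$rotation[, seq_len(n_components), drop = FALSE])
  rownames(loadings) <- paste0("PC", seq_len(n_components))
  structure(
    list(loadings = loadings,
         explained_variance_ratio = ratios,
         center = fit$center,
         feature_names = colnames(mat) %||% as.character(seq_len(ncol(mat)))),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  pct <- sprintf("%.1f%%", 100 * x$explained_variance_ratio)
  cat("PCA model:", nrow(x$loadings), "components over",
      length(x$feature_names), "features\n  variance explained:",
      paste(pct, collapse = ", "), "\n")
  invisible(x)
}

#' Project a matrix into a fitted PCA model's component space
#'
#' Coordinates are `(values - stored column means) %*% t(loadings)`; projecting
#' the training matrix reproduces its component scores.
#'
#' @param model A `pca_model`.
#' @param mat Matrix with columns matching the model's features.
#' @return An embedding: numeric matrix (rows x components) with the
#'   `"row_donors"` attribute propagated from `mat`.
#' @export
project_embedding <- function(model, mat) {
  stopifnot(inherits(model, "pca_model"), is.matrix(mat))
  feats <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
  if (!identical(feats, model$feature_names)) {
    bad <- union(setdiff(feats, model$feature_names),
                 setdiff(model$feature_names, feats))
    stop("feature mismatch between matrix and model: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  coords <- sweep(mat, 2L, model$center) %*% t(model$loadings)
  attr(coords, "row_donors") <- attr(mat, "row_donors")
  attr(coords, "explained_variance_ratio") <- model$explained_variance_ratio
  coords
}

#' Per-feature loading weights for selected components
#'
#' Returns each requested component's loadings keyed by V-J pair name, together
#' with the rank of each feature by absolute weight. Sign convention: each
#' component's largest-|weight| entry is made positive (the sign of a principal
#' axis is otherwise arbitrary).
#'
#' @param model A `pca_model`.
#' @param components Integer indices of components to report.
#' @return Data frame with `feature` plus, per component, `PC<k>` and
#'   `PC<k>_rank` columns (rank 1 = largest absolute weight).
#' @export
feature_weights <- function(model, components = 1:2) {
  stopifnot(inherits(model, "pca_model"))
  if (any(components < 1L | components > nrow(model$loadings))) {
    stop("invalid component index; model has ", nrow(model$loadings), " components")
  }
  out <- data.frame(feature = model$feature_names, stringsAsFactors = FALSE)
  for (k in components) {
    w <- model$loadings[k, ]
    top <- which.max(abs(w))
    if (w[top] < 0) w <- -w
    out[[paste0("PC", k)]] <- unname(w)
    out[[paste0("PC", k, "_rank")]] <- rank(-abs(w), ties.method = "first")
  }
  out
}

#' K-means clustering specification
#' @param k Number of clusters (default 2, matching a two-cohort comparison).
#' @param seed RNG seed for the k-means restarts.
#' @param n_init Number of random restarts; the best by within-cluster sum of
#'   squares is kept.
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(k = 2L, seed = 1L, n_init = 10L) {
  stopifnot(k >= 1, n_init >= 1)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 n_init = as.integer(n_init)),
            class = "cluster_spec")
}

#' Cluster embedded replicates with K-means
#'
#' Runs standard K-means on the first `components` of the embedding (default
#' PC1+2) with `n_init` seeded restarts. Cluster labels are renumbered
#' deterministically by the lexicographic order of the cluster centroids, so a
#' given seed always yields the same assignment.
#'
#' @param embedding Matrix from [project_embedding()].
#' @param spec A [cluster_spec()].
#' @param components Column indices used for clustering.
#' @return Integer vector of cluster labels in `1..k`, one per row, with a
#'   `"centers"` attribute (k x components, in label order).
#' @export
kmeans_cluster <- function(embedding, spec = cluster_spec(), components = 1:2) {
  components <- components[components <= ncol(embedding)]
  x <- embedding[, components, drop = FALSE]
  if (nrow(x) < spec$k) {
    stop("cannot form ", spec$k, " clusters from ", nrow(x), " rows")
  }
  fit <- with_seed(spec$seed, {
    stats::kmeans(x, centers = spec$k, nstart = spec$n_init, iter.max = 100L)
  })
  ord <- do.call(order, as.data.frame(fit$centers))
  relabel <- integer(spec$k)
  relabel[ord] <- seq_len(spec$k)
  labels <- relabel[fit$cluster]
  names(labels) <- rownames(embedding)
  attr(labels, "centers") <- fit$centers[ord, , drop = FALSE]
  labels
}

#' Run the full fingerprinting pipeline on a count table
#'
#' Convenience wrapper: subsample replicates, normalize, fit PCA, project, and
#' cluster. This is the core "repertoire fingerprint": each replicate's
#' position in the low-dimensional principal-component space of normalized V-J
#' pair usage.
#'
#' @param counts Donors-by-pairs matrix from [vj_count_table()] or
#'   [generate_study()].
#' @param subsample A [subsample_spec()].
#' @param normalization A [normalization_spec()].
#' @param n_components Number of principal components retained.
#' @param cluster A [cluster_spec()].
#' @return List with `replicates`, `normalized`, `model`, `embedding`,
#'   `weights`, `clusters`, of class `fingerprint`.
#' @export
fingerprint <- function(counts, subsample = subsample_spec(),
                        normalization = normalization_spec(),
                        n_components = 2L, cluster = cluster_spec()) {
  reps <- build_replicate_matrix(counts, subsample)
  norm <- zscore_normalize(reps, normalization)
  model <- fit_pca(norm, n_components)
  emb <- project_embedding(model, norm)
  structure(
    list(replicates = reps, normalized = norm, model = model, embedding = emb,
         weights = feature_weights(model, seq_len(min(2L, n_components))),
         clusters = kmeans_cluster(emb, cluster)),
    class = "fingerprint"
  )
}

#' Persist / restore a PCA model as a versioned JSON document
#' @param model A `pca_model`.
#' @param path JSON file path.
#' @export
write_pca_model <- function(model, path) {
  doc <- list(
    format = "repfingerprint/pca_model", version = 1L,
    feature_names = model$feature_names,
    center = unname(model$center),
    loadings = lapply(seq_len(nrow(model$loadings)),
                      function(i) unname(model$loadings[i, ])),
    explained_variance_ratio = model$explained_variance_ratio
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "repfingerprint/pca_model")) {
    stop("not a PCA model document: ", path)
  }
  loadings <- if (is.matrix(doc$loadings)) doc$loadings else
    do.call(rbind, lapply(doc$loadings, unlist))
  colnames(loadings) <- doc$feature_names
  rownames(loadings) <- paste0("PC", seq_len(nrow(loadings)))
  center <- doc$center
  names(center) <- doc$feature_names
  structure(list(loadings = loadings,
                 explained_variance_ratio = doc$explained_variance_ratio,
                 center = center, feature_names = doc$feature_names),
            class = "pca_model")
}
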