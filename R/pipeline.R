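#' Run configuration
#'
#' One flat configuration object driving the pipeline commands. All nested
#' specifications are derived from it, and it is persisted verbatim (as
#' `provenance.json`) next to every command's outputs so any run can be
#' reproduced bit-for-bit.
#'
#' @param input_dir Directory holding per-donor rearrangement TSVs and a
#'   `manifest.tsv` with columns `donor_id`, `cohort`, `file`.
#' @param out_dir Output directory (created if needed).
#' @param feature_space_mode `"union"`, `"intersection"` or `"from_file"`.
#' @param feature_space_file Pair-list file used when mode is `"from_file"`.
#' @param depth,n_replicates Subsampling depth and replicate count per donor.
#' @param pseudocount Normalization pseudocount.
#' @param n_components Principal components retained.
#' @param k,n_init K-means clusters and restarts.
#' @param rdi_depth,rdi_n_boot RDI bootstrap depth and iteration count.
#' @param noise_sigma,normalize_alt Alternate-feature noise level and
#'   histogram-normalization switch.
#' @param seed Global seed.
#' @param max_evalue Quality-filter E-value threshold.
#' @return A list of class `fp_config`.
#' @export
fp_config <- function(input_dir = NULL, out_dir = "fp_out",
                      feature_space_mode = "union", feature_space_file = NULL,
                      depth = 100000L, n_replicates = 10L, pseudocount = 0.01,
                      n_components = 2L, k = 2L, n_init = 10L,
                      rdi_depth = 100000L, rdi_n_boot = 100L,
                      noise_sigma = 0.05, normalize_alt = TRUE,
                      seed = 1L, max_evalue = 1e-6) {
  structure(as.list(environment()), class = "fp_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys match the arguments of [fp_config()].
#' @param overrides Named list of values taking precedence over the file.
#' @return An `fp_config`.
#' @export
read_fp_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, overrides[!vapply(overrides, is.null, logical(1))])
  do.call(fp_config, vals[names(vals) %in% names(formals(fp_config))])
}

write_provenance <- function(config, out_dir, command) {
  rec <- list(command = command,
              package_version = as.character(utils::packageVersion("repfingerprint")),
              config = unclass(config))
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Load repertoires listed in a study manifest
#'
#' Reads `manifest.tsv` from `config$input_dir`, ingests each donor's
#' rearrangement table, applies the quality filters and collapses to unique
#' V3J clonotypes.
#'
#' @param config An [fp_config()].
#' @return List of `repertoire` objects.
#' @export
load_study_repertoires <- function(config) {
  if (is.null(config$input_dir)) stop("config$input_dir is not set")
  manifest_path <- file.path(config$input_dir, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- utils::read.delim(manifest_path, sep = "\t", header = TRUE,
                                colClasses = "character")
  listed <- file.path(config$input_dir, manifest$file)
  missing <- !file.exists(listed)
  if (any(missing)) {
    stop("manifest lists missing input file(s) for donor(s): ",
         paste(manifest$donor_id[missing], collapse = ", "))
  }
  present <- list.files(config$input_dir, pattern = "\\.tsv$")
  extra <- setdiff(present, c(basename(listed), "manifest.tsv"))
  if (length(extra) > 0L) {
    stop("input donor file(s) not listed in the manifest: ",
         paste(extra, collapse = ", "))
  }
  fspec <- filter_spec(max_evalue = config$max_evalue)
  lapply(seq_len(nrow(manifest)), function(i) {
    recs <- read_rearrangement_table(listed[[i]], manifest$donor_id[[i]])
    kept <- apply_quality_filters(recs, fspec)
    message(sprintf("%s: %d records parsed, %d kept after filters",
                    manifest$donor_id[[i]], nrow(recs), nrow(kept)))
    extract_v3j_clonotypes(kept, donor_id = manifest$donor_id[[i]],
                           cohort = manifest$cohort[[i]])
  })
}

study_feature_space <- function(config, repertoires) {
  if (config$feature_space_mode == "from_file") {
    if (is.null(config$feature_space_file)) stop("feature_space_file is not set")
    build_feature_space(config$feature_space_file, mode = "from_file")
  } else {
    build_feature_space(repertoires, mode = config$feature_space_mode)
  }
}

#' Pipeline command: simulate a synthetic study
#'
#' Writes per-donor AIRR tables, a manifest and a parameter record for the
#' standard two-cohort study into `config$out_dir`.
#'
#' @param config An [fp_config()].
#' @param delta,n_effect,n_a,n_b,clonotypes_per_donor Study-shape arguments
#'   passed to [default_study_specs()].
#' @return The `synthetic_study`, invisibly.
#' @export
run_simulate <- function(config, delta = 1, n_effect = 20L, n_a = 3L, n_b = 5L,
                         clonotypes_per_donor = 20000L) {
  if (delta < 0) stop("effect size delta must be nonnegative")
  specs <- default_study_specs(delta = delta, n_effect = n_effect,
                               n_a = n_a, n_b = n_b,
                               clonotypes_per_donor = clonotypes_per_donor)
  study <- generate_study(specs$cohort_a, specs$cohort_b, seed = config$seed,
                          emit = "airr_tsv", dir = config$out_dir)
  write_provenance(config, config$out_dir, "simulate")
  invisible(study)
}

#' Pipeline command: fingerprint a study
#'
#' Ingests the study's rearrangement tables, builds the V-J count table,
#' runs subsampling, normalization, PCA and K-means, and writes
#' `counts.tsv`, `embedding.tsv`, `model.json`, `weights.tsv`, `clusters.tsv`
#' and `provenance.json` into `config$out_dir`.
#'
#' @param config An [fp_config()].
#' @return List with `counts`, `cohorts`, the fitted `fingerprint`, invisibly.
#' @export
run_fingerprint <- function(config) {
  reps <- load_study_repertoires(config)
  if (length(reps) < 2L) stop("fingerprinting requires at least 2 donors")
  space <- study_feature_space(config, reps)
  counts <- vj_count_table(reps, space)
  fp <- fingerprint(counts,
                    subsample = subsample_spec(config$depth, config$n_replicates,
                                               config$seed),
                    normalization = normalization_spec(config$pseudocount),
                    n_components = config$n_components,
                    cluster = cluster_spec(config$k, config$seed, config$n_init))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(counts, file.path(config$out_dir, "counts.tsv"))
  write_embedding(fp$embedding, file.path(config$out_dir, "embedding.tsv"))
  write_pca_model(fp$model, file.path(config$out_dir, "model.json"))
  utils::write.table(fp$weights, file.path(config$out_dir, "weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(row = names(fp$clusters), donor_id = attr(fp$embedding, "row_donors"),
               cluster = as.integer(fp$clusters)),
    file.path(config$out_dir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(config, config$out_dir, "fingerprint")
  invisible(list(counts = counts, cohorts = attr(counts, "cohorts"), fingerprint = fp))
}

#' Pipeline command: intra/inter cohort comparison
#'
#' Computes donor-pair distances under both metrics (Euclidean distance
#' between replicate centroids in PC1+2, and the bootstrap RDI), splits them
#' into intra- and inter-cohort groups, runs the two-sided Mann-Whitney rank
#' tests, and writes `distances.tsv`, `tests.json` and a comparison boxplot.
#'
#' @param config An [fp_config()].
#' @return List with `distances` (data frame) and `tests` (data frame),
#'   invisibly.
#' @export
run_compare <- function(config) {
  fpres <- run_fingerprint(config)
  cohorts <- fpres$cohorts
  if (length(unique(cohorts)) < 2L) {
    stop("comparison requires two cohorts; found only: ",
         paste(unique(cohorts), collapse = ", "))
  }
  pc_rec <- pc_pairwise_distances(fpres$fingerprint$embedding, cohorts)
  rdi_rec <- rdi_pairwise_distances(fpres$counts, cohorts,
                                    rdi_spec(config$rdi_depth, config$rdi_n_boot,
                                             config$seed))
  distances <- rbind(pc_rec, rdi_rec)
  tests <- rbind(intra_inter_tests(pc_rec), intra_inter_tests(rdi_rec))
  write_distance_records(distances, file.path(config$out_dir, "distances.tsv"))
  jsonlite::write_json(tests, file.path(config$out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  p <- plot_distance_boxes(distances)
  ggplot2::ggsave(file.path(config$out_dir, "comparison.pdf"), p,
                  width = 7, height = 4)
  invisible(list(distances = distances, tests = tests))
}

#' Pipeline command: alternate-feature fingerprint
#'
#' Runs the control analysis: CDRH3 length/charge/composition feature vectors
#' with Gaussian-noise replicates through the same normalize/PCA/K-means path,
#' writing `alt_embedding.tsv` and `alt_clusters.tsv`.
#'
#' @param config An [fp_config()].
#' @return List with the alt-feature `embedding` and `clusters`, invisibly.
#' @export
run_altfeatures <- function(config) {
  reps <- load_study_repertoires(config)
  spec <- alt_feature_spec(noise_sigma = config$noise_sigma,
                           n_replicates = config$n_replicates,
                           seed = config$seed, normalize = config$normalize_alt)
  mat <- build_alt_replicate_matrix(reps, spec)
  norm <- zscore_normalize(mat, normalization_spec(config$pseudocount))
  model <- fit_pca(norm, config$n_components)
  emb <- project_embedding(model, norm)
  clusters <- kmeans_cluster(emb, cluster_spec(config$k, config$seed, config$n_init))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_embedding(emb, file.path(config$out_dir, "alt_embedding.tsv"))
  utils::write.table(
    data.frame(row = names(clusters), donor_id = attr(emb, "row_donors"),
               cluster = as.integer(clusters)),
    file.path(config$out_dir, "alt_clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(config, config$out_dir, "altfeatures")
  invisible(list(embedding = emb, clusters = clusters, model = model))
}

#' Write an embedding as TSV (row label, donor, one column per component)
#' @param embedding Matrix from [project_embedding()].
#' @param path Output path.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(row = rownames(embedding),
                   donor_id = attr(embedding, "row_donors"),
                   as.data.frame(unclass(embedding)[, , drop = FALSE]))
  names(df)[-(1:2)] <- paste0("PC", seq_len(ncol(embedding)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
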