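#' Alternate-feature specification
#'
#' Control feature set describing a repertoire by its CDRH3 loops instead of
#' V-J gene usage: a length histogram over bins 4..30, a net-charge histogram
#' over bins -6..+6, and the mean amino-acid composition. Replicates are
#' simulated by multiplicative Gaussian noise (default 5% per bin) rather than
#' subsampling.
#'
#' @param length_bins Integer bin centers for CDRH3 length.
#' @param charge_bins Integer bin centers for CDRH3 net charge.
#' @param noise_sigma Fractional standard deviation of the per-bin noise.
#' @param n_replicates Noise replicates per donor.
#' @param seed Base RNG seed.
#' @param normalize If `TRUE` (default) histograms are converted to fractions
#'   of the repertoire size, so donors of different depths are comparable.
#' @return An object of class `alt_feature_spec`.
#' @export
alt_feature_spec <- function(length_bins = 4:30, charge_bins = -6:6,
                             noise_sigma = 0.05, n_replicates = 10L,
                             seed = 1L, normalize = TRUE) {
  stopifnot(all(diff(length_bins) == 1L), all(diff(charge_bins) == 1L),
            noise_sigma >= 0, n_replicates >= 1)
  structure(list(length_bins = length_bins, charge_bins = charge_bins,
                 noise_sigma = noise_sigma, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), normalize = normalize),
            class = "alt_feature_spec")
}

#' Net charge of a CDRH3 amino-acid sequence
#'
#' Integer charge model: arginine and lysine count +1, aspartate and glutamate
#' count -1, histidine counts 0, all other residues 0.
#'
#' @param cdr3_aa Character vector of nonempty sequences over the 20 standard
#'   amino acids.
#' @return Integer vector of net charges.
#' @examples
#' cdrh3_net_charge("CAKDRW")  # +1
#' @export
cdrh3_net_charge <- function(cdr3_aa) {
  if (length(cdr3_aa) == 0L) return(integer(0))
  if (any(is.na(cdr3_aa) | !nzchar(cdr3_aa))) stop("empty CDR3 sequence")
  bad <- grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), cdr3_aa)
  if (any(bad)) {
    stop("non-standard amino-acid letter in CDR3: ",
         paste(utils::head(cdr3_aa[bad], 5L), collapse = ", "))
  }
  count_of <- function(letters) {
    pattern <- paste0("[", letters, "]")
    nchar(cdr3_aa) - nchar(gsub(pattern, "", cdr3_aa))
  }
  as.integer(count_of("RK") - count_of("DE"))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' CDRH3 length and net-charge histograms for a repertoire
#'
#' Each unique clonotype contributes one count to each histogram. Values
#' outside the bin ranges are clamped to the nearest edge bin (preserving
#' histogram totals); the number of clamped clonotypes is reported in the
#' `"n_clamped"` attribute.
#'
#' @param repertoire A `repertoire` (may be empty: all-zero histograms).
#' @param spec An [alt_feature_spec()].
#' @return List with `length` (named `len_*` counts) and `charge` (named
#'   `chg_*` counts), plus the `"n_clamped"` attribute.
#' @export
length_charge_histograms <- function(repertoire, spec = alt_feature_spec()) {
  cdr3 <- repertoire$clonotypes$cdr3_aa
  lens <- nchar(cdr3)
  chgs <- if (length(cdr3) > 0L) cdrh3_net_charge(cdr3) else integer(0)
  lb <- spec$length_bins; cb <- spec$charge_bins
  n_clamped <- sum(lens < min(lb) | lens > max(lb)) +
    sum(chgs < min(cb) | chgs > max(cb))
  lh <- table(factor(clamp(lens, min(lb), max(lb)), levels = lb))
  ch <- table(factor(clamp(chgs, min(cb), max(cb)), levels = cb))
  out <- list(length = stats::setNames(as.numeric(lh), paste0("len_", lb)),
              charge = stats::setNames(as.numeric(ch), paste0("chg_", cb)))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Mean amino-acid composition of a repertoire's CDRH3 loops
#'
#' Each clonotype's CDRH3 is converted to its amino-acid frequency vector (a
#' point on the 20-simplex); the repertoire composition is the unweighted mean
#' over clonotypes, so long loops do not dominate short ones.
#'
#' @param repertoire A nonempty `repertoire`.
#' @return Named numeric vector of 20 frequencies summing to 1 (`aa_A`..`aa_Y`).
#' @export
mean_aa_composition <- function(repertoire) {
  cdr3 <- repertoire$clonotypes$cdr3_aa
  if (length(cdr3) == 0L) stop("amino-acid composition of an empty repertoire is undefined")
  chars <- strsplit(cdr3, "", fixed = TRUE)
  lens <- lengths(chars)
  groups <- rep(seq_along(cdr3), lens)
  tab <- table(groups, factor(unlist(chars), levels = AA_STANDARD))
  freqs <- sweep(unclass(tab), 1L, lens, `/`)
  stats::setNames(colMeans(freqs), paste0("aa_", AA_STANDARD))
}

#' Assemble a donor's alternate feature vector
#'
#' Concatenates the length histogram, charge histogram and mean amino-acid
#' composition into one named vector (27 + 13 + 20 = 60 features by default).
#' With `spec$normalize = TRUE` the histograms are fractions of the repertoire
#' size; the mode is recorded in the `"normalized"` attribute.
#'
#' @param repertoire A nonempty `repertoire`.
#' @param spec An [alt_feature_spec()].
#' @return Named numeric feature vector.
#' @export
alt_feature_vector <- function(repertoire, spec = alt_feature_spec()) {
  hists <- length_charge_histograms(repertoire, spec)
  n <- nrow(repertoire$clonotypes)
  if (n == 0L) stop("alternate features of an empty repertoire are undefined")
  lh <- hists$length; ch <- hists$charge
  if (spec$normalize) {
    lh <- lh / n; ch <- ch / n
  }
  out <- c(lh, ch, mean_aa_composition(repertoire))
  attr(out, "normalized") <- spec$normalize
  out
}

#' Gaussian-noise replicates of a feature vector
#'
#' Each replicate entry is `value * (1 + eps)` with `eps ~ N(0, noise_sigma)`
#' drawn independently per bin; negative results are clipped to 0 and zero
#' entries stay exactly 0 (the noise is multiplicative).
#'
#' @param vec Named numeric feature vector.
#' @param spec An [alt_feature_spec()].
#' @param donor_id Label for the seed stream and row names.
#' @return Numeric matrix (`n_replicates` x features).
#' @export
gaussian_noise_replicates <- function(vec, spec = alt_feature_spec(),
                                      donor_id = "donor") {
  stopifnot(all(is.finite(vec)))
  p <- length(vec)
  reps <- with_seed(derive_seed(spec$seed, paste0("altnoise|", donor_id)), {
    eps <- matrix(stats::rnorm(spec$n_replicates * p, sd = spec$noise_sigma),
                  nrow = spec$n_replicates)
    pmax(matrix(vec, nrow = spec$n_replicates, ncol = p, byrow = TRUE) * (1 + eps), 0)
  })
  dimnames(reps) <- list(paste0(donor_id, "|", seq_len(spec$n_replicates)),
                         names(vec))
  reps
}

#' Joint alternate-feature replicate matrix for several repertoires
#'
#' Drop-in replacement for [build_replicate_matrix()] on the CDRH3 control
#' features: the result feeds [zscore_normalize()] and [fit_pca()] unchanged.
#'
#' @param repertoires List of nonempty `repertoire` objects.
#' @param spec An [alt_feature_spec()].
#' @return Numeric matrix with a `"row_donors"` attribute.
#' @export
build_alt_replicate_matrix <- function(repertoires, spec = alt_feature_spec()) {
  ids <- vapply(repertoires, function(r) r$donor_id, character(1))
  blocks <- lapply(repertoires, function(r) {
    gaussian_noise_replicates(alt_feature_vector(r, spec), spec, donor_id = r$donor_id)
  })
  m <- do.call(rbind, blocks)
  attr(m, "row_donors") <- rep(ids, each = spec$n_replicates)
  m
}
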