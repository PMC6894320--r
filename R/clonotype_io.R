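#' Default AIRR Rearrangement column mapping
#'
#' Maps the internal record fields onto AIRR Rearrangement TSV column names.
#' `cdr3_aa` lists fallbacks tried in order (`cdr3_aa`, then `junction_aa`).
#' Override individual entries via the `columns` argument of
#' [read_rearrangement_table()].
#'
#' @return Named list of column names.
#' @export
airr_default_columns <- function() {
  list(
    v_call = "v_call",
    j_call = "j_call",
    cdr3_aa = c("cdr3_aa", "junction_aa"),
    v_evalue = "v_support",
    j_evalue = "j_support",
    productive = "productive",
    in_frame = "vj_in_frame",
    has_stop_codon = "stop_codon"
  )
}

# AIRR encodes logicals as T/F/TRUE/FALSE (any case); empty and NA are unknown.
parse_airr_logical <- function(x) {
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[up %in% c("T", "TRUE", "1")] <- TRUE
  out[up %in% c("F", "FALSE", "0")] <- FALSE
  out
}

#' Read an AIRR Rearrangement table into clonotype records
#'
#' Parses one donor's annotated rearrangements from a tab-separated AIRR
#' Rearrangement file. No filtering or allele stripping is applied at this
#' stage; raw gene calls are preserved. Optional quality columns (alignment
#' E-values, productive/in-frame/stop-codon flags) that are absent from the
#' file are filled with `NA`, which downstream filters treat as passing, and a
#' message names each missing column.
#'
#' @param path Path to a tab-separated rearrangement file with a header row.
#' @param donor_id Donor label attached to every record.
#' @param columns Named list overriding entries of [airr_default_columns()].
#' @return A `data.frame` of clonotype records with columns `donor_id`,
#'   `v_call`, `j_call`, `cdr3_aa`, `v_evalue`, `j_evalue`, `in_frame`,
#'   `productive`, `has_stop_codon`.
#' @export
read_rearrangement_table <- function(path, donor_id, columns = list()) {
  if (!file.exists(path)) {
    stop("rearrangement file not found: ", path)
  }
  cols <- utils::modifyList(airr_default_columns(), columns)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))

  pick <- function(cands) {
    hit <- cands[cands %in% names(tab)]
    if (length(hit) == 0L) NA_character_ else hit[[1L]]
  }
  required <- c("v_call", "j_call", "cdr3_aa")
  for (field in required) {
    if (is.na(pick(cols[[field]]))) {
      stop("required column missing from ", path, ": expected one of '",
           paste(cols[[field]], collapse = "', '"), "' for field ", field)
    }
  }

  n <- nrow(tab)
  get_col <- function(field, parser = identity, default = NA) {
    name <- pick(cols[[field]])
    if (is.na(name)) {
      message("column for '", field, "' absent in ", basename(path),
              "; records treated as passing that criterion")
      return(rep(default, n))
    }
    parser(tab[[name]])
  }

  data.frame(
    donor_id = rep(donor_id, n),
    v_call = as.character(tab[[pick(cols$v_call)]]),
    j_call = as.character(tab[[pick(cols$j_call)]]),
    cdr3_aa = as.character(tab[[pick(cols$cdr3_aa)]]),
    v_evalue = get_col("v_evalue", function(x) suppressWarnings(as.numeric(x))),
    j_evalue = get_col("j_evalue", function(x) suppressWarnings(as.numeric(x))),
    in_frame = get_col("in_frame", parse_airr_logical),
    productive = get_col("productive", parse_airr_logical),
    has_stop_codon = get_col("has_stop_codon", parse_airr_logical),
    stringsAsFactors = FALSE
  )
}

#' Quality-filter specification
#'
#' The five record-level filters applied before clonotype collapsing: germline
#' alignment E-values below a threshold for both V and J, an in-frame junction,
#' a productive rearrangement, no stop codons, and a defined CDR3 sequence.
#'
#' @param max_evalue Strict upper bound on both V and J alignment E-values.
#' @param require_in_frame,require_productive,reject_stop_codons,require_cdr3
#'   Logical switches enabling the individual criteria.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(max_evalue = 1e-6, require_in_frame = TRUE,
                        require_productive = TRUE, reject_stop_codons = TRUE,
                        require_cdr3 = TRUE) {
  stopifnot(is.numeric(max_evalue), max_evalue > 0)
  structure(
    list(max_evalue = max_evalue, require_in_frame = require_in_frame,
         require_productive = require_productive,
         reject_stop_codons = reject_stop_codons, require_cdr3 = require_cdr3),
    class = "filter_spec"
  )
}

#' Apply record-level quality filters
#'
#' Retains exactly the records passing every enabled criterion. Records with
#' `NA` in an optional flag or E-value column pass that criterion (permissive
#' default for heterogeneous AIRR dialects). Per-criterion rejection counts are
#' attached as the `"rejections"` attribute; a record failing several criteria
#' is counted once per criterion it fails.
#'
#' @param records Data frame from [read_rearrangement_table()].
#' @param spec A [filter_spec()].
#' @return Filtered data frame of records, with a `"rejections"` attribute.
#' @export
apply_quality_filters <- function(records, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  pass_na <- function(x) ifelse(is.na(x), TRUE, x)

  keep_ev <- pass_na(records$v_evalue < spec$max_evalue) &
    pass_na(records$j_evalue < spec$max_evalue)
  keep_frame <- if (spec$require_in_frame) pass_na(records$in_frame) else TRUE
  keep_prod <- if (spec$require_productive) pass_na(records$productive) else TRUE
  keep_stop <- if (spec$reject_stop_codons) pass_na(!records$has_stop_codon) else TRUE
  has_cdr3 <- !is.na(records$cdr3_aa) & nzchar(records$cdr3_aa)
  keep_cdr3 <- if (spec$require_cdr3) has_cdr3 else TRUE

  keep <- keep_ev & rep(keep_frame, length.out = nrow(records)) &
    rep(keep_prod, length.out = nrow(records)) &
    rep(keep_stop, length.out = nrow(records)) &
    rep(keep_cdr3, length.out = nrow(records))

  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- c(
    evalue = sum(!keep_ev),
    in_frame = if (spec$require_in_frame) sum(!keep_frame) else 0L,
    productive = if (spec$require_productive) sum(!keep_prod) else 0L,
    stop_codon = if (spec$reject_stop_codons) sum(!keep_stop) else 0L,
    cdr3 = if (spec$require_cdr3) sum(!keep_cdr3) else 0L
  )
  out
}

#' Strip the allele suffix from a germline gene call
#'
#' Collapses a gene call to the gene level: multi-assignment calls
#' (comma-separated) resolve to the first listed call, and anything from the
#' first `*` on (the allele designation) is removed, together with surrounding
#' whitespace.
#'
#' @param gene_call Character vector of gene calls, e.g. `"IGHV1-2*02"`.
#' @return Character vector of allele-stripped gene names.
#' @examples
#' strip_allele("IGHV1-2*02")                     # "IGHV1-2"
#' strip_allele("IGHV3-30*18,IGHV3-30-5*01")      # "IGHV3-30"
#' @export
strip_allele <- function(gene_call) {
  if (length(gene_call) == 0L) return(character(0))
  if (any(is.na(gene_call) | !nzchar(trimws(gene_call)))) {
    stop("empty gene call cannot be allele-stripped")
  }
  first <- vapply(strsplit(gene_call, ",", fixed = TRUE), `[[`, character(1), 1L)
  trimws(vapply(strsplit(first, "*", fixed = TRUE), `[[`, character(1), 1L))
}

#' Collapse filtered records to a repertoire of unique V3J clonotypes
#'
#' A V3J clonotype is the triple (allele-stripped V gene, allele-stripped J
#' gene, CDRH3 amino-acid sequence); CDR3 equality is exact string match after
#' upper-casing. Duplicate triples collapse to one clonotype, so the repertoire
#' counts unique clonotypes, not reads.
#'
#' @param records Filtered record data frame ([apply_quality_filters()]).
#' @param donor_id Donor label; defaults to the records' donor.
#' @param cohort Optional cohort label.
#' @return An object of class `repertoire`: a list with `donor_id`, `cohort`
#'   and `clonotypes` (a data frame with columns `v_gene`, `j_gene`, `cdr3_aa`).
#' @export
extract_v3j_clonotypes <- function(records, donor_id = NULL, cohort = NA_character_) {
  donor_id <- donor_id %||%
    (if (nrow(records) > 0L) records$donor_id[[1L]] else NA_character_)
  if (nrow(records) == 0L) {
    clono <- data.frame(v_gene = character(0), j_gene = character(0),
                        cdr3_aa = character(0), stringsAsFactors = FALSE)
  } else {
    clono <- data.frame(
      v_gene = strip_allele(records$v_call),
      j_gene = strip_allele(records$j_call),
      cdr3_aa = toupper(records$cdr3_aa),
      stringsAsFactors = FALSE
    )
    clono <- unique(clono)
    rownames(clono) <- NULL
  }
  structure(list(donor_id = donor_id, cohort = cohort, clonotypes = clono),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat("V3J repertoire for donor", x$donor_id,
      if (!is.na(x$cohort)) paste0("(cohort ", x$cohort, ")") else "",
      "\n  unique clonotypes:", nrow(x$clonotypes), "\n")
  invisible(x)
}

vj_pair_names <- function(v_gene, j_gene) paste(v_gene, j_gene, sep = "_")

#' Build a V-J pair feature space
#'
#' The feature space is the ordered list of V-J gene-pair names
#' (`"Vgene_Jgene"`) over which count vectors are tabulated. It can be read
#' from a file (one pair name per line, order preserved) or derived from the
#' pairs observed in a set of repertoires, as either their union or
#' intersection (both sorted lexicographically for determinism).
#'
#' @param x A list of `repertoire` objects, or (for `mode = "from_file"`) a
#'   file path.
#' @param mode One of `"union"`, `"intersection"`, `"from_file"`.
#' @return Character vector of pair names with class `feature_space`.
#' @export
build_feature_space <- function(x, mode = c("union", "intersection", "from_file")) {
  mode <- match.arg(mode)
  if (mode == "from_file") {
    stopifnot(is.character(x), length(x) == 1L)
    pairs <- readLines(x, warn = FALSE)
    pairs <- trimws(pairs)
    pairs <- pairs[nzchar(pairs)]
    if (anyDuplicated(pairs)) stop("duplicate pair names in ", x)
  } else {
    stopifnot(is.list(x), length(x) >= 1L)
    per_donor <- lapply(x, function(rep) {
      unique(vj_pair_names(rep$clonotypes$v_gene, rep$clonotypes$j_gene))
    })
    pairs <- if (mode == "union") {
      sort(unique(unlist(per_donor)))
    } else {
      sort(Reduce(intersect, per_donor))
    }
  }
  if (length(pairs) == 0L) stop("resulting feature space is empty")
  structure(pairs, class = "feature_space")
}

#' Write a feature space to a file, one pair name per line
#' @param space A `feature_space`.
#' @param path Output file path.
#' @export
write_feature_space <- function(space, path) {
  writeLines(as.character(space), path)
  invisible(path)
}

#' Count unique clonotypes per V-J pair
#'
#' Tabulates a repertoire over a feature space: entry *i* is the number of
#' unique V3J clonotypes whose pair name equals the *i*-th feature. Clonotypes
#' whose pair is outside the space are dropped (not lumped into an "other"
#' bin); their number is reported in the `"excluded"` attribute.
#'
#' @param repertoire A `repertoire`.
#' @param space A `feature_space`.
#' @return Named integer vector of clonotype counts, one per pair, with an
#'   `"excluded"` attribute.
#' @export
count_vj_pairs <- function(repertoire, space) {
  stopifnot(inherits(repertoire, "repertoire"), length(space) >= 1L)
  pairs <- vj_pair_names(repertoire$clonotypes$v_gene, repertoire$clonotypes$j_gene)
  counts <- table(factor(pairs, levels = as.character(space)))
  out <- as.integer(counts)
  names(out) <- as.character(space)
  attr(out, "excluded") <- sum(!pairs %in% as.character(space))
  out
}

#' Tabulate several repertoires into a donors-by-pairs count table
#'
#' @param repertoires List of `repertoire` objects with distinct donor ids.
#' @param space A `feature_space`.
#' @return Integer matrix (donors in rows, V-J pairs in columns) of unique
#'   clonotype counts, with a `"cohorts"` attribute carrying any cohort labels.
#' @export
vj_count_table <- function(repertoires, space) {
  ids <- vapply(repertoires, function(r) r$donor_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate donor ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  counts <- t(vapply(repertoires, function(r) as.vector(count_vj_pairs(r, space)),
                     integer(length(space))))
  dimnames(counts) <- list(ids, as.character(space))
  cohorts <- vapply(repertoires, function(r) r$cohort %||% NA_character_, character(1))
  names(cohorts) <- ids
  attr(counts, "cohorts") <- cohorts
  counts
}

#' Write / read a count table as TSV (first column `donor_id`)
#' @param counts Matrix from [vj_count_table()].
#' @param path File path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(donor_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$donor_id
  storage.mode(m) <- "integer"
  m
}
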