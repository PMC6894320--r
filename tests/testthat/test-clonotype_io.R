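test_that("rearrangement tables parse row-for-row with raw gene calls preserved", {
  path <- write_airr_fixture(airr_rows(
    v_call = c("IGHV1-2*02", "IGHV3-23*01"),
    j_call = c("IGHJ4*02", "IGHJ6*01"),
    cdr3_aa = c("CARWGGDYW", "CAKYSSGWFDPW")))
  recs <- read_rearrangement_table(path, donor_id = "D1")
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$v_call[1], "IGHV1-2*02")  # no stripping at parse time
  expect_equal(recs$donor_id, c("D1", "D1"))
  expect_equal(recs$v_evalue, c(1e-10, 1e-10))
})

test_that("a table without any CDR3 column is a format error naming the field", {
  rows <- airr_rows("IGHV1-2*02", "IGHJ4*02", "CARW")
  rows$cdr3_aa <- NULL
  path <- write_airr_fixture(rows)
  expect_error(read_rearrangement_table(path, "D1"), "cdr3_aa")
  expect_error(read_rearrangement_table(tempfile(), "D1"), "not found")
})

test_that("junction_aa is accepted as a CDR3 fallback and missing flags default to passing", {
  rows <- data.frame(v_call = "IGHV1-2*02", j_call = "IGHJ4*02",
                     junction_aa = "CARW", stringsAsFactors = FALSE)
  path <- write_airr_fixture(rows)
  expect_message(recs <- read_rearrangement_table(path, "D1"), "productive")
  expect_true(is.na(recs$productive))
  kept <- apply_quality_filters(recs)
  expect_equal(nrow(kept), 1L)  # NA flags pass permissively
})

test_that("quality filters enforce each criterion and report rejection counts", {
  recs <- rbind(
    data.frame(donor_id = "D", v_call = "V1", j_call = "J1", cdr3_aa = "CARW",
               v_evalue = 1e-5, j_evalue = 1e-10, in_frame = TRUE,
               productive = TRUE, has_stop_codon = FALSE),    # E-value too big
    data.frame(donor_id = "D", v_call = "V1", j_call = "J1", cdr3_aa = "CA*W",
               v_evalue = 1e-10, j_evalue = 1e-10, in_frame = TRUE,
               productive = TRUE, has_stop_codon = TRUE),     # stop codon
    data.frame(donor_id = "D", v_call = "V1", j_call = "J1", cdr3_aa = NA,
               v_evalue = 1e-10, j_evalue = 1e-10, in_frame = TRUE,
               productive = TRUE, has_stop_codon = FALSE),    # no CDR3
    data.frame(donor_id = "D", v_call = "V1", j_call = "J1", cdr3_aa = "CARW",
               v_evalue = 1e-10, j_evalue = 1e-10, in_frame = FALSE,
               productive = FALSE, has_stop_codon = FALSE),   # frame+productive
    data.frame(donor_id = "D", v_call = "V1", j_call = "J1", cdr3_aa = "CAKY",
               v_evalue = 1e-7, j_evalue = 1e-8, in_frame = TRUE,
               productive = TRUE, has_stop_codon = FALSE)     # passes all five
  )
  kept <- apply_quality_filters(recs)
  expect_equal(kept$cdr3_aa, "CAKY")
  rej <- attr(kept, "rejections")
  expect_equal(unname(rej[c("evalue", "stop_codon", "cdr3")]), c(1L, 1L, 1L))
  expect_equal(unname(rej["in_frame"]), 1L)
  # idempotence
  again <- apply_quality_filters(kept)
  expect_equal(again, kept, ignore_attr = TRUE)
  # E-value bound is strict: exactly 1e-6 fails
  recs$v_evalue[5] <- 1e-6
  expect_equal(nrow(apply_quality_filters(recs)), 0L)
})

test_that("allele stripping takes the first call and drops the allele suffix", {
  expect_equal(strip_allele("IGHV1-2*02"), "IGHV1-2")
  expect_equal(strip_allele("IGHJ4"), "IGHJ4")
  expect_equal(strip_allele("IGHV3-30*18,IGHV3-30-5*01"), "IGHV3-30")
  expect_equal(strip_allele(" IGHV1-2 *02"), "IGHV1-2")
  expect_error(strip_allele(""), "empty")
})

test_that("V3J clonotype extraction dedupes after stripping and upper-cases CDR3", {
  recs <- data.frame(
    donor_id = "D1",
    v_call = c("IGHV1-2*02", "IGHV1-2*04", "IGHV1-2*02", "IGHV1-2*02"),
    j_call = c("IGHJ4*01", "IGHJ4*02", "IGHJ4*01", "IGHJ6*01"),
    cdr3_aa = c("CARW", "carw", "CAKY", "CAKY"),
    v_evalue = 1e-10, j_evalue = 1e-10, in_frame = TRUE, productive = TRUE,
    has_stop_codon = FALSE, stringsAsFactors = FALSE)
  rep <- extract_v3j_clonotypes(recs)
  expect_s3_class(rep, "repertoire")
  expect_equal(nrow(rep$clonotypes), 3L)
  expect_true(all(rep$clonotypes$cdr3_aa == toupper(rep$clonotypes$cdr3_aa)))
  # order invariance
  rep2 <- extract_v3j_clonotypes(recs[sample(nrow(recs)), ])
  o <- function(df) df[do.call(order, df), ]
  expect_equal(o(rep2$clonotypes), o(rep$clonotypes), ignore_attr = TRUE)
  # empty input
  expect_equal(nrow(extract_v3j_clonotypes(recs[0, ])$clonotypes), 0L)
})

test_that("V-J pair counting tallies clonotypes over the space and reports exclusions", {
  rep <- make_repertoire("D1",
                         v = c("IGHV1-2", "IGHV1-2", "IGHV1-2"),
                         j = c("IGHJ4", "IGHJ4", "IGHJ6"),
                         cdr3 = c("CARW", "CAKY", "CAKY"))
  space <- structure(c("IGHV1-2_IGHJ4", "IGHV1-2_IGHJ6"), class = "feature_space")
  cnt <- count_vj_pairs(rep, space)
  expect_equal(as.vector(cnt), c(2L, 1L))
  expect_equal(attr(cnt, "excluded"), 0L)
  narrow <- structure("IGHV1-2_IGHJ6", class = "feature_space")
  cnt2 <- count_vj_pairs(rep, narrow)
  expect_equal(as.vector(cnt2), 1L)
  expect_equal(attr(cnt2, "excluded"), 2L)
  empty <- make_repertoire("D2", character(0), character(0), character(0))
  expect_equal(as.vector(count_vj_pairs(empty, space)), c(0L, 0L))
  # conservation: counts + excluded = repertoire size
  expect_equal(sum(cnt2) + attr(cnt2, "excluded"), nrow(rep$clonotypes))
})

test_that("feature spaces build from union, intersection, or file order", {
  r1 <- make_repertoire("D1", "A", "B", "X")
  r2 <- make_repertoire("D2", c("A", "C"), c("B", "D"), c("X", "Y"))
  expect_equal(as.character(build_feature_space(list(r1, r2), "union")),
               c("A_B", "C_D"))
  expect_equal(as.character(build_feature_space(list(r1, r2), "intersection")),
               "A_B")
  f <- tempfile()
  writeLines(c("C_D", "A_B"), f)
  expect_equal(as.character(build_feature_space(f, "from_file")), c("C_D", "A_B"))
  empty <- make_repertoire("D3", character(0), character(0), character(0))
  expect_error(build_feature_space(list(empty), "union"), "empty")
})

test_that("count tables round-trip through TSV", {
  r1 <- make_repertoire("D1", "A", "B", "X", cohort = "H")
  r2 <- make_repertoire("D2", c("A", "C"), c("B", "D"), c("X", "Y"), cohort = "V")
  space <- build_feature_space(list(r1, r2), "union")
  tab <- vj_count_table(list(r1, r2), space)
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(attr(tab, "cohorts"), c(D1 = "H", D2 = "V"))
  path <- tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  back <- read_count_table(path)
  expect_equal(back, tab, ignore_attr = TRUE)
  expect_error(vj_count_table(list(r1, r1), space), "duplicate")
})
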