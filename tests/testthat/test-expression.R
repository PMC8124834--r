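# Expression ingestion, quantile normalization, group means, gene panel,
# GEO series-matrix parsing.

write_toy_files <- function(x, annot,
                            dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "matrix.tsv"); ap <- file.path(dir, "annot.tsv")
  write_expression_matrix(x, mp)
  write_sample_annotation(annot, ap)
  list(matrix = mp, annot = ap)
}

test_that("matrix reading validates annotation coverage and numeric cells", {
  annot <- toy_annotation(reps = 3L)
  x <- toy_matrix(paste0("miR-t", 1:4), annot)
  fp <- write_toy_files(x, annot)
  got <- read_expression_matrix(fp$matrix, fp$annot)
  expect_equal(dim(got$matrix), c(4L, 12L))
  expect_equal(got$annotation$sample_id, colnames(got$matrix))
  # annotation missing one sample -> error
  fp2 <- write_toy_files(x, annot[-1L, ])
  expect_error(read_expression_matrix(fp2$matrix, fp2$annot),
               "without annotation")
  # non-numeric cell -> error
  bad <- file.path(withr::local_tempdir(), "bad.tsv")
  writeLines(c("feature_id\tE_C_1\tE_C_2", "miR-t1\t1.0\toops",
               "miR-t2\t2.0\t3.0"), bad)
  expect_error(read_expression_matrix(bad, fp$annot), "non-numeric")
  expect_error(read_expression_matrix("/nope.tsv", fp$annot), "no such file")
})

test_that("write/read round-trip reproduces a simulated matrix at stated precision", {
  ds <- simulate_dataset(simulation_config(n_mirnas = 30L, n_genes = 10L,
                                           n_planted_down = 4L,
                                           n_planted_down_geromirs = 2L,
                                           n_planted_up = 2L,
                                           n_planted_up_genes = 2L,
                                           seed = 11L))
  fp <- write_toy_files(ds$mirna_matrix, ds$mirna_annotation)
  got <- read_expression_matrix(fp$matrix, fp$annot)
  expect_equal(got$matrix, signif(ds$mirna_matrix, 10), tolerance = 1e-12)
  expect_equal(as.data.frame(got$annotation),
               as.data.frame(ds$mirna_annotation))
})

test_that("probe collapse takes per-sample medians and linear input is log2-transformed", {
  annot <- toy_annotation(reps = 1L)
  vals <- matrix(c(1, 3, 100, 2, 4, 100, 8, 8, 8, 8), nrow = 5, ncol = 4,
                 dimnames = list(c("miR-a", "miR-a", "miR-a", "miR-b",
                                   "miR-b"),
                                 annot$sample_id))
  out <- as_expression_matrix(vals)
  expect_equal(nrow(out), 2L)
  expect_equal(unname(out["miR-a", 1]), 3)  # median of 1, 3, 100
  lin <- matrix(c(2, 4, 8, 16), 1, 4,
                dimnames = list("miR-a", annot$sample_id))
  expect_equal(unname(as_expression_matrix(lin, linear_scale = TRUE)[1, ]),
               1:4)
  expect_error(as_expression_matrix(lin - 2, linear_scale = TRUE),
               "positive")
  # features with missing values are dropped with a message
  withna <- matrix(c(NA, 1, 2, 3, 4, 5, 6, 7), 2, 4,
                   dimnames = list(c("miR-a", "miR-b"), annot$sample_id))
  expect_message(kept <- as_expression_matrix(withna), "dropping 1")
  expect_equal(rownames(kept), "miR-b")
})

test_that("quantile normalization maps columns onto the rank-mean reference", {
  x <- matrix(c(1, 2, 3, 4, 6, 8), 3, 2,
              dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  q <- quantile_normalize(x)
  expect_equal(sort(q[, 1]), sort(q[, 2]))
  expect_equal(unname(q[, 1]), c(2.5, 4.0, 5.5))
  expect_equal(unname(q[, 2]), c(2.5, 4.0, 5.5))
  # identical columns unchanged; idempotence; exact value-multiset equality
  same <- matrix(rep(c(5, 1, 3), 3), 3, 3,
                 dimnames = list(paste0("f", 1:3), paste0("s", 1:3)))
  expect_equal(quantile_normalize(same), same)
  set.seed(3)
  r <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  q1 <- quantile_normalize(r)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  for (j in 2:6) {
    expect_equal(sort(unname(q1[, 1])), sort(unname(q1[, j])))
  }
  # ties receive the mean of the reference values at tied ranks
  tied <- matrix(c(1, 1, 4, 2, 6, 10), 3, 2,
                 dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  qt <- quantile_normalize(tied)
  expect_equal(unname(qt[1:2, 1]), rep(mean(c(1.5, 3.5)), 2))
  expect_error(quantile_normalize(r[, 1, drop = FALSE]), "two samples")
})

test_that("group means pool the requested cell types and never TP/TM", {
  annot <- sample_annotation(
    sample_id = c("E_C_1", "E_C_2", "I_C_1", "I_T_1", "TP_T_1"),
    cell_type = c("E", "E", "I", "I", "TP"),
    condition = c("C", "C", "C", "T", "T"),
    replicate = c(1, 2, 1, 1, 1))
  x <- matrix(c(2, 4, 3, 6, 100), 1, 5,
              dimnames = list("miR-a", annot$sample_id))
  gm <- group_means(x, annot)
  expect_equal(gm$mean_C, 3)   # mean of 2, 4, 3
  expect_equal(gm$mean_T, 6)   # TP sample (value 100) excluded
  expect_equal(attr(gm, "n_T"), 1L)
  # restricting to a cell type without both conditions is an error
  expect_error(group_means(x, annot, cell_types = "E"), "both conditions")
  # restricting to I uses only the I samples
  gm_i <- group_means(x, annot, cell_types = "I")
  expect_equal(gm_i$mean_C, 3)
  expect_equal(gm_i$mean_T, 6)
  expect_error(group_means(x, annot, cell_types = "TP"), "subset of E, I, K")
  # invariance under column permutation
  perm <- sample(ncol(x))
  gm2 <- group_means(x[, perm, drop = FALSE], annot[perm, ])
  expect_equal(gm2$mean_C, gm$mean_C)
  # within-cell-type averaging weighs cell types equally
  gmw <- group_means(x, annot, average_within_cell_type = TRUE)
  expect_equal(gmw$mean_C, mean(c(mean(c(2, 4)), 3)))
})

test_that("pooled TME-minus-control difference recovers a planted shift", {
  cfg <- simulation_config(n_mirnas = 200L, n_genes = 10L, seed = 5L,
                           effect_log2 = 3, noise_sd = 0.5)
  ds <- simulate_dataset(cfg)
  gm <- group_means(ds$mirna_matrix, ds$mirna_annotation)
  diff <- gm$mean_T - gm$mean_C
  names(diff) <- gm$feature_id
  planted <- diff[ds$truth$planted_down]
  se <- 0.5 * sqrt(1 / attr(gm, "n_C") + 1 / attr(gm, "n_T"))
  # cell-type offsets add a little spread beyond the noise SE
  expect_true(all(abs(planted + 3) < 3 * (se + cfg$celltype_sd)))
})

test_that("gene panel extraction preserves request order and reports absences", {
  x <- matrix(1:12, 3, 4,
              dimnames = list(c("Hdac7", "Sirt3", "Dnmt1"),
                              paste0("s", 1:4)))
  panel <- extract_gene_panel(x, c("SIRT3", "Hdac7"))
  expect_equal(rownames(panel), c("Sirt3", "Hdac7"))
  expect_message(p2 <- extract_gene_panel(x, c("Hdac7", "Nothere")),
                 "not in matrix")
  expect_equal(rownames(p2), "Hdac7")
  expect_equal(attr(p2, "missing"), "Nothere")
  expect_message(p3 <- extract_gene_panel(x, "Absent"), "not in matrix")
  expect_equal(nrow(p3), 0L)
})

test_that("GEO series-matrix files parse into annotated matrices", {
  lines <- c(
    "!Series_title\t\"toy\"",
    "!Sample_title\t\"E_C_1\"\t\"E_T_1\"\t\"TM_2\"",
    "!Sample_geo_accession\t\"GSM1\"\t\"GSM2\"\t\"GSM3\"",
    "!series_matrix_table_begin",
    "ID_REF\tGSM1\tGSM2\tGSM3",
    "miR-a\t1.5\t2.5\t3.5",
    "miR-b\t2\t3\t4",
    "!series_matrix_table_end")
  f <- withr::local_tempfile(lines = lines, fileext = ".txt")
  got <- read_geo_series_matrix(f)
  expect_equal(dim(got$matrix), c(2L, 3L))
  expect_equal(got$annotation$cell_type, c("E", "E", "TM"))
  expect_equal(got$annotation$condition, c("C", "T", "T"))  # TM defaults to T
  # unparsable title names the offender
  bad <- sub("E_T_1", "whatever", lines)
  fb <- withr::local_tempfile(lines = bad, fileext = ".txt")
  expect_error(read_geo_series_matrix(fb), "whatever")
  # missing markers
  fm <- withr::local_tempfile(lines = lines[-4], fileext = ".txt")
  expect_error(read_geo_series_matrix(fm), "markers")
  # quantile-normalized fixture re-read preserves column distributions
  ds <- simulate_dataset(simulation_config(n_mirnas = 20L, n_genes = 5L,
                                           n_planted_down = 3L,
                                           n_planted_down_geromirs = 1L,
                                           n_planted_up = 1L,
                                           n_planted_up_genes = 1L,
                                           seed = 2L))
  q <- quantile_normalize(ds$mirna_matrix)
  hdr <- paste(c("ID_REF", colnames(q)), collapse = "\t")
  body <- apply(cbind(rownames(q), format(q, digits = 12)), 1L,
                paste, collapse = "\t")
  titles <- paste0("\"", sub("_(\\d+)$", "_\\1", colnames(q)), "\"")
  geo <- c(paste(c("!Sample_title", titles), collapse = "\t"),
           "!series_matrix_table_begin", hdr, body,
           "!series_matrix_table_end")
  fg <- withr::local_tempfile(lines = geo, fileext = ".txt")
  back <- read_geo_series_matrix(fg)
  for (j in seq_len(ncol(q))) {
    expect_equal(sort(back$matrix[, j]), sort(q[, j]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})
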