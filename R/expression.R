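# Expression-matrix ingestion, annotation, quantile normalization, slicing.
# Matrices are plain numeric matrices (features x samples) with rownames and
# colnames; annotations are data.frames with one row per sample.

CELL_TYPES <- c("E", "I", "K", "TP", "TM")
TME_CELL_TYPES <- c("E", "I", "K")

#' Construct and validate a sample annotation table
#'
#' One row per sample: `sample_id`, `cell_type` (E, I, K for the liver
#' tumor-microenvironment cell types; TP, TM for primary-tumor and
#' liver-metastasis tumor-cell comparison columns), `condition` (C control,
#' T tumor microenvironment) and a positive integer `replicate`. The
#' (cell_type, condition, replicate) triple must be unique; TP/TM samples
#' are carried for comparison but never enter control-vs-TME contrasts.
#'
#' @param sample_id,cell_type,condition,replicate Equal-length vectors.
#' @return A validated data.frame of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, cell_type, condition, replicate) {
  df <- data.frame(sample_id = as.character(sample_id),
                   cell_type = as.character(cell_type),
                   condition = as.character(condition),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  validate_annotation(df)
}

validate_annotation <- function(df) {
  need <- c("sample_id", "cell_type", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_ct <- setdiff(unique(df$cell_type), CELL_TYPES)
  if (length(bad_ct) > 0L) {
    stop("unknown cell type(s): ", paste(bad_ct, collapse = ", "),
         call. = FALSE)
  }
  bad_cond <- setdiff(unique(df$condition), c("C", "T"))
  if (length(bad_cond) > 0L) {
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }
  if (any(duplicated(df$sample_id))) {
    stop("duplicate sample_id(s)", call. = FALSE)
  }
  key <- paste(df$cell_type, df$condition, df$replicate)
  if (any(duplicated(key))) {
    stop("duplicate (cell_type, condition, replicate) triple(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  if (any(!is.finite(df$replicate)) || any(df$replicate < 1L)) {
    stop("replicate indices must be positive integers", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Assemble an expression matrix from raw values
#'
#' Coerces to a numeric matrix, optionally log2-transforms linear-scale
#' intensities, collapses duplicate feature identifiers to their per-sample
#' median (standard probe summarization; order-independent), and drops
#' features with any missing value (the downstream thresholding rule has no
#' missing-data contract). Dropped features are reported via `message()`.
#'
#' @param values Numeric matrix-like, features x samples, with row and
#'   column names.
#' @param linear_scale If `TRUE`, values are linear intensities and are
#'   log2-transformed (non-positive values are an error); default assumes
#'   log2 input.
#' @return Numeric matrix with unique rownames and all-finite values.
#' @export
as_expression_matrix <- function(values, linear_scale = FALSE) {
  x <- as.matrix(values)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression values need feature rownames and sample colnames",
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (linear_scale) {
    if (any(x <= 0, na.rm = TRUE)) {
      stop("linear-scale intensities must be positive for log2 transform",
           call. = FALSE)
    }
    x <- log2(x)
  }
  if (anyDuplicated(rownames(x))) {
    x <- collapse_probes(x)
  }
  bad <- !stats::complete.cases(x) | apply(x, 1L, function(r) any(!is.finite(r)))
  if (any(bad)) {
    message("dropping ", sum(bad), " feature(s) with missing/non-finite values: ",
            paste(utils::head(rownames(x)[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "")
    x <- x[!bad, , drop = FALSE]
  }
  x
}

collapse_probes <- function(x) {
  idx <- split(seq_len(nrow(x)), rownames(x))
  out <- do.call(rbind, lapply(idx, function(i) {
    apply(x[i, , drop = FALSE], 2L, stats::median)
  }))
  # keep first-occurrence order of feature ids
  out[unique(rownames(x)), , drop = FALSE]
}

#' Read an expression matrix and its sample annotation from TSV
#'
#' The matrix file is tab-separated with a feature-identifier first column
#' and one column per sample; the annotation file carries `sample_id`,
#' `cell_type`, `condition`, `replicate`. Every matrix column must be
#' annotated; non-numeric cells and ragged rows are errors.
#'
#' @param path Matrix TSV path.
#' @param annotation_path Annotation TSV path.
#' @param linear_scale Passed to [as_expression_matrix()].
#' @return A list with elements `matrix` and `annotation`.
#' @export
read_expression_matrix <- function(path, annotation_path,
                                   linear_scale = FALSE) {
  for (p in c(path, annotation_path)) {
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  }
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix file has no sample columns", call. = FALSE)
  ids <- as.character(raw[[1L]])
  vals <- raw[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1L))
  if (any(!num)) {
    stop("non-numeric cell(s) in sample column(s): ",
         paste(names(vals)[!num], collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  annot <- validate_annotation(
    utils::read.delim(annotation_path, stringsAsFactors = FALSE))
  missing_annot <- setdiff(colnames(x), annot$sample_id)
  if (length(missing_annot) > 0L) {
    stop("matrix column(s) without annotation: ",
         paste(missing_annot, collapse = ", "), call. = FALSE)
  }
  annot <- annot[match(colnames(x), annot$sample_id), , drop = FALSE]
  list(matrix = as_expression_matrix(x, linear_scale = linear_scale),
       annotation = validate_annotation(annot))
}

#' Write an expression matrix as TSV
#'
#' Values are written at a stated decimal precision so that write/read
#' round-trips are exact at that precision.
#'
#' @param x Expression matrix.
#' @param path Output path.
#' @param digits Significant digits written (default 10).
#' @param id_column Name of the feature-identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, digits = 10L,
                                    id_column = "feature_id") {
  df <- data.frame(signif(x, digits), check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(x)), id_column), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sample_annotation
#' @param annot A `sample_annotation` data.frame.
#' @param path Output path.
#' @export
write_sample_annotation <- function(annot, path) {
  utils::write.table(as.data.frame(annot), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the common distribution of across-sample
#' rank means: after normalization each column's sorted values equal the
#' mean of the sorted columns of the input, with ties receiving the mean of
#' the reference values at their tied ranks. Feature and sample order are
#' unchanged; the operation is idempotent. Delegates to
#' `limma::normalizeQuantiles(..., ties = TRUE)`.
#'
#' @param x Expression matrix with at least two samples.
#' @return Normalized matrix with identical dimnames.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L) {
    stop("quantile normalization needs at least two samples", call. = FALSE)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Pooled control and TME group means
#'
#' Averages, per feature, all control-condition samples of the selected
#' cell types (`mean_C`) and all TME-condition samples (`mean_T`). TP/TM
#' comparison samples are never included. By default all samples of the
#' selected cell types are pooled directly; `average_within_cell_type`
#' first averages replicates within each cell type and then averages the
#' per-cell-type means.
#'
#' @param x Expression matrix.
#' @param annot Sample annotation covering the matrix columns.
#' @param cell_types Subset of E, I, K to include.
#' @param average_within_cell_type Logical; see Details.
#' @return A data.frame (`feature_id`, `mean_C`, `mean_T`) with attributes
#'   `n_C` and `n_T` giving group sizes.
#' @export
group_means <- function(x, annot, cell_types = TME_CELL_TYPES,
                        average_within_cell_type = FALSE) {
  annot <- validate_annotation(as.data.frame(annot))
  bad <- setdiff(cell_types, TME_CELL_TYPES)
  if (length(bad) > 0L) {
    stop("cell_types must be a subset of E, I, K; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  annot <- annot[match(colnames(x), annot$sample_id), , drop = FALSE]
  if (any(is.na(annot$sample_id))) {
    stop("annotation does not cover all matrix columns", call. = FALSE)
  }
  sel <- annot$cell_type %in% cell_types
  cols_for <- function(cond) which(sel & annot$condition == cond)
  iC <- cols_for("C"); iT <- cols_for("T")
  if (length(iC) == 0L || length(iT) == 0L) {
    stop("both conditions must be represented among the selected cell types",
         call. = FALSE)
  }
  one_mean <- function(idx) {
    if (!average_within_cell_type) {
      return(rowMeans(x[, idx, drop = FALSE]))
    }
    groups <- split(idx, annot$cell_type[idx])
    per_ct <- matrix(vapply(groups, function(i) {
      rowMeans(x[, i, drop = FALSE])
    }, numeric(nrow(x))), nrow = nrow(x))
    rowMeans(per_ct)
  }
  out <- data.frame(feature_id = rownames(x),
                    mean_C = unname(one_mean(iC)),
                    mean_T = unname(one_mean(iT)),
                    stringsAsFactors = FALSE)
  attr(out, "n_C") <- length(iC)
  attr(out, "n_T") <- length(iT)
  out
}

#' Extract a gene panel from an expression matrix
#'
#' Returns the submatrix for the requested gene symbols in request order.
#' Matching is case-insensitive (symbols move between mouse and human
#' capitalization); absent genes are reported with a message, not an error.
#'
#' @param x Expression matrix with gene-symbol rownames.
#' @param genes Character vector of requested symbols.
#' @return Submatrix (possibly 0-row) with attribute `missing` listing the
#'   requested symbols not found.
#' @export
extract_gene_panel <- function(x, genes) {
  idx <- match(tolower(genes), tolower(rownames(x)))
  found <- !is.na(idx)
  if (any(!found)) {
    message("gene panel: ", sum(!found), " symbol(s) not in matrix: ",
            paste(genes[!found], collapse = ", "))
  }
  out <- x[idx[found], , drop = FALSE]
  attr(out, "missing") <- genes[!found]
  out
}
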