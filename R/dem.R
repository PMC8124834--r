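# Differential-expression calling by the combined selection-threshold /
# significance-threshold rule: a feature is selected iff
# |mean_T - mean_C| >= log2(theta) on the log2 scale AND p < alpha from a
# two-sided two-sample location test between all pooled control and TME
# samples. Defaults theta = 4, alpha = 0.001.

#' Differential-expression calling parameters
#'
#' @param theta Fold-change selection threshold on the linear scale
#'   (>= 1); compared as `|log2 fold change| >= log2(theta)`, boundary
#'   values selected. Default 4.
#' @param alpha Significance threshold on the raw (uncorrected) p-value,
#'   strict inequality. Default 0.001.
#' @param test Two-sample location test on log2 intensities: `"welch"`
#'   (unequal-variance t, the default: replicate groups are small and
#'   unbalanced), `"student"` (pooled-variance t) or `"wilcoxon"`
#'   (rank-sum).
#' @return A `dem_params` list.
#' @export
dem_params <- function(theta = 4, alpha = 0.001,
                       test = c("welch", "student", "wilcoxon")) {
  test <- match.arg(test)
  if (!is.numeric(theta) || length(theta) != 1L || theta < 1) {
    stop("theta must be a single number >= 1", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(theta = theta, alpha = alpha, test = test),
            class = "dem_params")
}

# Vectorized two-sided row-wise t-tests (Welch or pooled-variance Student).
# Degenerate rows (zero variance in both groups) get p = 1 when the group
# means agree and p = 0 when they differ. Cross-checked against
# stats::t.test in the test suite.
row_t_test <- function(x, i1, i2, var_equal = FALSE) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(x[, i2, drop = FALSE], 1L, stats::var)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, nrow(x))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- !is.finite(p)
  p[degenerate] <- ifelse(abs(m1 - m2)[degenerate] < 1e-12, 1, 0)
  p
}

row_wilcoxon <- function(x, i1, i2) {
  apply(x, 1L, function(r) {
    suppressWarnings(
      stats::wilcox.test(r[i1], r[i2], exact = FALSE)$p.value)
  })
}

# Per-feature statistics for every tested feature (selected or not).
dem_stats <- function(x, annot, params = dem_params(),
                      cell_types = TME_CELL_TYPES) {
  stopifnot(inherits(params, "dem_params"))
  if (!is.matrix(x) || nrow(x) == 0L) {
    stop("empty expression matrix", call. = FALSE)
  }
  annot <- validate_annotation(as.data.frame(annot))
  annot <- annot[match(colnames(x), annot$sample_id), , drop = FALSE]
  sel <- annot$cell_type %in% cell_types
  iC <- which(sel & annot$condition == "C")
  iT <- which(sel & annot$condition == "T")
  if (length(iC) < 2L || length(iT) < 2L) {
    stop("need at least two samples per condition; have ",
         length(iC), " control and ", length(iT), " TME", call. = FALSE)
  }
  gm <- group_means(x, annot, cell_types = cell_types)
  p <- switch(params$test,
    welch = row_t_test(x, iT, iC, var_equal = FALSE),
    student = row_t_test(x, iT, iC, var_equal = TRUE),
    wilcoxon = row_wilcoxon(x, iT, iC))
  lfc <- gm$mean_T - gm$mean_C
  out <- data.frame(
    feature_id = gm$feature_id,
    mean_C = gm$mean_C,
    mean_T = gm$mean_T,
    log2_fc = lfc,
    p_value = unname(p),
    bh_q = stats::p.adjust(unname(p), method = "BH"),
    direction = ifelse(lfc < 0, "down", "up"),
    selected = abs(lfc) >= log2(params$theta) & p < params$alpha,
    stringsAsFactors = FALSE)
  attr(out, "n_C") <- length(iC)
  attr(out, "n_T") <- length(iT)
  out
}

#' Call differentially expressed features between control and TME
#'
#' Applies the combined rule to every feature: selected iff the absolute
#' log2 fold change (pooled TME mean minus pooled control mean) is at least
#' `log2(theta)` (boundary included) and the two-sided test p-value is
#' below `alpha`. No multiple-testing correction enters the rule; a
#' Benjamini-Hochberg column is reported for information only.
#'
#' @param x Expression matrix (log2 scale), features x samples.
#' @param annot Sample annotation.
#' @param params A [dem_params()] object.
#' @param cell_types Cell types whose samples are pooled (default E, I, K).
#' @return A `dem_table`: data.frame of selected records (`feature_id`,
#'   `mean_C`, `mean_T`, `log2_fc`, `p_value`, `bh_q`, `direction`), sorted
#'   by ascending p-value, with attributes `params` and `population_size`
#'   (number of features tested, the enrichment universe).
#' @export
call_dems <- function(x, annot, params = dem_params(),
                      cell_types = TME_CELL_TYPES) {
  st <- dem_stats(x, annot, params, cell_types)
  rec <- st[st$selected, setdiff(names(st), "selected"), drop = FALSE]
  rec <- rec[order(rec$p_value, rec$feature_id), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec,
            params = params,
            population_size = nrow(st),
            n_C = attr(st, "n_C"), n_T = attr(st, "n_T"),
            class = c("dem_table", "data.frame"))
}

#' @export
print.dem_table <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "dem_table: %d selected of %d tested (theta = %g, alpha = %g, %s test); %d down, %d up\n",
    nrow(x), attr(x, "population_size"), p$theta, p$alpha, p$test,
    sum(x$direction == "down"), sum(x$direction == "up")))
  print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Selected features of one direction
#'
#' @param table A `dem_table`.
#' @param direction `"down"` or `"up"`.
#' @return Character vector of feature identifiers.
#' @export
dem_features <- function(table, direction = c("down", "up")) {
  direction <- match.arg(direction)
  table$feature_id[table$direction == direction]
}

#' Rank selected features by statistical significance
#'
#' @param table A `dem_table`.
#' @param direction `"down"` or `"up"`.
#' @return Data.frame (`feature_id`, `neg_log10_p`) in stable descending
#'   order of `-log10(p)`; ties broken lexicographically by feature id.
#'   Underflowed zero p-values are floored at the smallest positive double
#'   for display.
#' @export
rank_dems <- function(table, direction = c("down", "up")) {
  direction <- match.arg(direction)
  sub <- table[table$direction == direction, , drop = FALSE]
  p <- pmax(sub$p_value, .Machine$double.xmin)
  out <- data.frame(feature_id = sub$feature_id,
                    neg_log10_p = -log10(p),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$neg_log10_p, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-feature volcano-plot coordinates
#'
#' One point per tested feature: log2 fold change, `-log10(p)` and the
#' selection flag of the combined rule (consistent with [call_dems()]).
#'
#' @inheritParams call_dems
#' @return Data.frame (`feature_id`, `log2_fc`, `neg_log10_p`, `selected`).
#' @export
volcano_points <- function(x, annot, params = dem_params(),
                           cell_types = TME_CELL_TYPES) {
  st <- dem_stats(x, annot, params, cell_types)
  data.frame(feature_id = st$feature_id,
             log2_fc = st$log2_fc,
             neg_log10_p = -log10(pmax(st$p_value, .Machine$double.xmin)),
             selected = st$selected,
             stringsAsFactors = FALSE)
}
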