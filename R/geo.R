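# Minimal GEO series-matrix reader: !-prefixed metadata, expression table
# between !series_matrix_table_begin / !series_matrix_table_end markers.

#' Read a GEO series-matrix file
#'
#' Parses the expression table delimited by the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers and
#' derives a sample annotation by matching each `!Sample_title` entry
#' against a regular pattern with three capture groups: cell type
#' (E, I, K, TP, TM), condition (C or T; optional for TP/TM titles, which
#' default to condition T) and replicate index. Titles that do not match
#' raise an error naming the offenders.
#'
#' @param path Series-matrix file path.
#' @param title_pattern Regular expression with capture groups
#'   (cell_type, condition, replicate).
#' @param linear_scale Passed to [as_expression_matrix()].
#' @return A list with elements `matrix`, `annotation` and `titles`.
#' @export
read_geo_series_matrix <- function(
    path,
    title_pattern = "^(E|I|K|TP|TM)[-_. ]?(C|T)?[-_. ]?([0-9]+)$",
    linear_scale = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop("series-matrix table markers missing or malformed", call. = FALSE)
  }
  tab <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  x <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids

  title_line <- grep("^!Sample_title\\b", lines, value = TRUE)
  if (length(title_line) != 1L) {
    stop("expected exactly one !Sample_title line", call. = FALSE)
  }
  titles <- gsub("\"", "", strsplit(title_line, "\t")[[1L]][-1L])
  if (length(titles) != ncol(x)) {
    stop("sample title count (", length(titles),
         ") does not match sample columns (", ncol(x), ")", call. = FALSE)
  }
  m <- regmatches(titles, regexec(title_pattern, titles))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    stop("unparsable sample title(s): ",
         paste(titles[bad], collapse = ", "), call. = FALSE)
  }
  parts <- do.call(rbind, m)
  cond <- parts[, 3L]
  cond[!nzchar(cond) & parts[, 2L] %in% c("TP", "TM")] <- "T"
  if (any(!nzchar(cond))) {
    stop("sample title(s) missing a condition code: ",
         paste(titles[!nzchar(cond)], collapse = ", "), call. = FALSE)
  }
  annot <- sample_annotation(sample_id = colnames(x),
                             cell_type = parts[, 2L],
                             condition = cond,
                             replicate = as.integer(parts[, 4L]))
  list(matrix = as_expression_matrix(x, linear_scale = linear_scale),
       annotation = annot,
       titles = titles)
}
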