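# GeromiR catalog: controlled hallmark vocabulary, miRNA-name harmonization,
# catalog construction from per-source hallmark tables, platform restriction.

#' Aging-hallmark vocabulary
#'
#' The closed vocabulary of fifteen hallmarks of aging used to annotate
#' geromiRs, with a unique internal code per hallmark and the single-letter
#' display label used in figure legends. Display letters are not unique
#' (the legend reuses "S" for regulation of splicing and cellular
#' senescence), which is why the internal codes exist.
#'
#' @return A data.frame with columns `code` (unique), `display` (legend
#'   letter, not unique) and `name` (hallmark name, unique).
#' @export
#' @examples
#' aging_hallmarks()
aging_hallmarks <- function() {
  data.frame(
    code = c("D", "T", "M", "H", "Ssp", "P", "N", "m", "Sse", "E", "I",
             "s", "h", "i", "C"),
    display = c("D", "T", "M", "H", "S", "P", "N", "m", "S", "E", "I",
                "s", "h", "i", "C"),
    name = c(
      "altered DNA damage response",
      "loss of telomeres",
      "DNA methylation",
      "histone modifications",
      "regulation of splicing",
      "changes to protein homeostasis",
      "altered nutrient sensing",
      "mitochondrial dysfunction",
      "cellular senescence",
      "stem cell exhaustion",
      "inflammaging",
      "epigenetic alterations (Sirtuins)",
      "stem cell homeostasis",
      "insulin/IGF1",
      "altered intercellular communication"),
    stringsAsFactors = FALSE)
}

assert_hallmarks <- function(hallmark) {
  bad <- setdiff(unique(hallmark), aging_hallmarks()$name)
  if (length(bad) > 0L) {
    stop("unknown aging hallmark(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(hallmark)
}

#' Harmonize a miRNA name
#'
#' Maps free-text miRNA tokens onto a canonical form: surrounding whitespace
#' and markup characters are stripped, species prefixes (`hsa-`, `mmu-`, ...)
#' are removed, and the family stem is re-capitalized to the `miR-` / `let-` /
#' `lin-` conventions. Numeric, letter and arm suffixes are preserved
#' verbatim; the function never merges distinct identifiers (so `miR-34` and
#' `miR-34a` stay distinct) and is idempotent.
#'
#' @param raw Character vector of miRNA tokens.
#' @return Character vector of canonical identifiers.
#' @export
#' @examples
#' normalize_mirna_name(c("mmu-miR-146a", " miR-29a*", "Let-7b"))
normalize_mirna_name <- function(raw) {
  if (!is.character(raw)) stop("miRNA names must be character", call. = FALSE)
  x <- gsub("[*\"'`’\\s]+", "", raw, perl = TRUE)
  if (any(!nzchar(x))) {
    stop("empty or all-markup miRNA token(s) at position(s): ",
         paste(which(!nzchar(x)), collapse = ", "), call. = FALSE)
  }
  # species prefix: three/four lower-case letters before the family stem
  x <- sub("^[A-Za-z]{3,4}-(?=(mir|let|lin)\\b)", "", x,
           perl = TRUE, ignore.case = TRUE)
  x <- sub("^mir(?=(-|$))", "miR", x, perl = TRUE, ignore.case = TRUE)
  x <- sub("^let(?=(-|$))", "let", x, perl = TRUE, ignore.case = TRUE)
  x <- sub("^lin(?=(-|$))", "lin", x, perl = TRUE, ignore.case = TRUE)
  x
}

new_catalog <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("geromir_catalog", "data.frame"))
}

validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  need <- c("canonical_name", "hallmark", "source", "on_platform",
            "downregulated_flag")
  miss <- setdiff(need, names(catalog))
  if (length(miss) > 0L) {
    stop("catalog lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  assert_hallmarks(catalog$hallmark)
  bad <- catalog$downregulated_flag & !catalog$on_platform
  if (any(bad)) {
    stop("downregulated flag set for off-platform miRNA(s): ",
         paste(unique(catalog$canonical_name[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(catalog)
}

#' Build a geromiR catalog from per-source hallmark tables
#'
#' Each source is a named list mapping hallmark names (from the closed
#' vocabulary, see [aging_hallmarks()]) to character vectors of raw miRNA
#' tokens. Tokens are harmonized with [normalize_mirna_name()] and
#' deduplicated; a miRNA listed under several hallmarks or by several
#' sources keeps the union of its annotations and provenance.
#'
#' @param source_tables Named list of sources; each element a named list
#'   `hallmark name -> character vector of miRNA tokens`.
#' @param alias_table Optional named character vector mapping canonical
#'   names onto replacement canonical names (explicit merges only; empty by
#'   default, and the packaged tables need none to reach their printed
#'   counts).
#' @return A `geromir_catalog`: a data.frame with one row per
#'   (miRNA, hallmark, source) triple and columns `canonical_name`,
#'   `hallmark`, `source`, `on_platform`, `downregulated_flag`.
#' @export
#' @examples
#' build_catalog(list(src = list("inflammaging" = c("miR-146a", "miR-155"))))
build_catalog <- function(source_tables, alias_table = character()) {
  stopifnot(is.list(source_tables))
  if (length(source_tables) == 0L) {
    return(new_catalog(data.frame(
      canonical_name = character(), hallmark = character(),
      source = character(), on_platform = logical(),
      downregulated_flag = logical(), stringsAsFactors = FALSE)))
  }
  if (is.null(names(source_tables)) || any(!nzchar(names(source_tables)))) {
    stop("source tables must be named", call. = FALSE)
  }
  rows <- lapply(names(source_tables), function(src) {
    tab <- source_tables[[src]]
    assert_hallmarks(names(tab))
    do.call(rbind, lapply(names(tab), function(hm) {
      nm <- normalize_mirna_name(tab[[hm]])
      hit <- nm %in% names(alias_table)
      nm[hit] <- unname(alias_table[nm[hit]])
      data.frame(canonical_name = nm, hallmark = hm, source = src,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- unique(do.call(rbind, rows))
  df <- df[order(df$canonical_name, df$hallmark, df$source), , drop = FALSE]
  df$on_platform <- FALSE
  df$downregulated_flag <- FALSE
  validate_catalog(new_catalog(df))
}

#' @export
print.geromir_catalog <- function(x, ...) {
  cat(sprintf(
    "geromir_catalog: %d miRNA(s), %d on platform, %d flagged downregulated\n",
    length(catalog_names(x)),
    length(unique(x$canonical_name[x$on_platform])),
    length(unique(x$canonical_name[x$downregulated_flag]))))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x), "annotation rows )\n")
  invisible(x)
}

#' Unique canonical miRNA names in a catalog
#'
#' @param catalog A `geromir_catalog`.
#' @return Sorted character vector of unique canonical names.
#' @export
catalog_names <- function(catalog) {
  sort(unique(catalog$canonical_name))
}

#' Restrict a catalog to the miRNAs represented on a platform
#'
#' Keeps exactly the records whose canonical name is in `platform_mirnas`
#' (already-normalized identifiers) and marks survivors as on-platform.
#' Never adds names; an empty intersection yields a valid empty catalog.
#'
#' @param catalog A `geromir_catalog`.
#' @param platform_mirnas Character vector of canonical miRNA identifiers.
#' @return The restricted `geromir_catalog`.
#' @export
restrict_to_platform <- function(catalog, platform_mirnas) {
  validate_catalog(catalog)
  keep <- catalog$canonical_name %in% platform_mirnas
  out <- catalog[keep, , drop = FALSE]
  out$on_platform <- rep(TRUE, nrow(out))
  new_catalog(out)
}

#' Members of one aging hallmark
#'
#' @param catalog A `geromir_catalog`.
#' @param hallmark A hallmark name from [aging_hallmarks()].
#' @return Sorted character vector of canonical names annotated to the
#'   hallmark (no duplicates).
#' @export
hallmark_members <- function(catalog, hallmark) {
  stopifnot(length(hallmark) == 1L)
  assert_hallmarks(hallmark)
  sort(unique(catalog$canonical_name[catalog$hallmark == hallmark]))
}

#' Downregulation-flagged miRNAs of a catalog
#'
#' @param catalog A `geromir_catalog`.
#' @return Sorted character vector of unique flagged canonical names.
#' @export
downregulated_geromirs <- function(catalog) {
  sort(unique(catalog$canonical_name[catalog$downregulated_flag]))
}

#' Read / write a catalog as tab-separated text
#'
#' The serialized form is one row per (miRNA, hallmark, source) triple with
#' columns `canonical_name`, `hallmark`, `source`, `on_platform`,
#' `downregulated_flag`; writing then re-reading reproduces the catalog
#' exactly.
#'
#' @param path File path.
#' @return `read_catalog` returns a `geromir_catalog`; `write_catalog`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("no such catalog file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$on_platform <- as.logical(df$on_platform)
  df$downregulated_flag <- as.logical(df$downregulated_flag)
  validate_catalog(new_catalog(df))
}

#' @rdname read_catalog
#' @param catalog A `geromir_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged literature-curated geromiR tables
#'
#' `geromir_source_tables()` returns the three-review compilation of
#' geromiRs by aging hallmark (one named list per source), ready for
#' [build_catalog()]; the union contains 115 distinct harmonized miRNAs.
#' `geromir_platform_table()` returns the platform-restricted annotation
#' table (75 distinct miRNAs measurable on the arrays) whose
#' `downregulated` column flags the 26 miRNAs called significantly
#' downregulated in the tumor-microenvironment cells.
#'
#' @return For `geromir_source_tables()`, a named list of per-source
#'   hallmark tables. For `geromir_platform_table()`, a data.frame with
#'   columns `hallmark`, `mirna`, `downregulated`.
#' @export
geromir_source_tables <- function() {
  path <- system.file("extdata", "geromir_sources.tsv", package = "geromir",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$source), function(s) {
    lapply(split(s, s$hallmark), function(r) r$mirna)
  })
}

#' @rdname geromir_source_tables
#' @export
geromir_platform_table <- function() {
  path <- system.file("extdata", "geromir_platform.tsv", package = "geromir",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$downregulated <- as.logical(df$downregulated)
  df
}

#' The packaged geromiR catalogs
#'
#' `geromir_catalog()` builds the full 115-miRNA catalog from the packaged
#' three-source compilation and annotates platform representation and
#' downregulation flags from the platform table. `platform_catalog()`
#' returns the 75-miRNA on-platform catalog with the hallmark assignments
#' of the platform-restricted table itself.
#'
#' @return A `geromir_catalog`.
#' @export
geromir_catalog <- function() {
  cat <- build_catalog(geromir_source_tables())
  plat <- geromir_platform_table()
  cat$on_platform <- cat$canonical_name %in% plat$mirna
  flagged <- unique(plat$mirna[plat$downregulated])
  cat$downregulated_flag <- cat$canonical_name %in% flagged
  validate_catalog(cat)
}

#' @rdname geromir_catalog
#' @export
platform_catalog <- function() {
  plat <- geromir_platform_table()
  flagged <- unique(plat$mirna[plat$downregulated])
  df <- data.frame(
    canonical_name = normalize_mirna_name(plat$mirna),
    hallmark = plat$hallmark,
    source = "platform_table",
    stringsAsFactors = FALSE)
  df <- unique(df)
  df$on_platform <- TRUE
  df$downregulated_flag <- df$canonical_name %in% flagged
  df <- df[order(df$canonical_name, df$hallmark), , drop = FALSE]
  validate_catalog(new_catalog(df))
}

#' Catalog summary counts
#'
#' @param catalog A `geromir_catalog`.
#' @return Named integer vector: total unique miRNAs, on-platform uniques,
#'   downregulation-flagged uniques.
#' @export
catalog_stats <- function(catalog) {
  validate_catalog(catalog)
  c(total = length(unique(catalog$canonical_name)),
    on_platform = length(unique(catalog$canonical_name[catalog$on_platform])),
    downregulated =
      length(unique(catalog$canonical_name[catalog$downregulated_flag])))
}
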