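# Over-representation statistics: one-sided (upper-tail) hypergeometric
# tests for geromiRs among DEMs and for aging hallmarks among downregulated
# geromiRs, plus a permutation oracle.

#' Hypergeometric set over-representation
#'
#' Upper-tail probability of observing at least `k = |hits ∩ category|`
#' category members in a hit list of size `n` drawn from a population of
#' size `N` containing `K` category members:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. One-sided
#' over-representation only; `k = 0` gives p = 1.
#'
#' @param hits Character vector of hit identifiers (subset of population).
#' @param category Character vector of category identifiers (subset of
#'   population).
#' @param population Character vector: the tested universe.
#' @param category_id Optional label carried into the result.
#' @return An `enrichment_result`: one-row data.frame with columns
#'   `category_id`, `k`, `K`, `n`, `N`, `p_value`, `bh_q`.
#' @export
#' @examples
#' set_enrichment(letters[1:5], letters[3:6], letters[1:10])
set_enrichment <- function(hits, category, population,
                           category_id = "set") {
  hits <- unique(hits); category <- unique(category)
  population <- unique(population)
  if (!all(hits %in% population)) {
    stop("hits are not contained in the population: ",
         paste(utils::head(setdiff(hits, population), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (!all(category %in% population)) {
    stop("category is not contained in the population: ",
         paste(utils::head(setdiff(category, population), 5L),
               collapse = ", "), call. = FALSE)
  }
  k <- length(intersect(hits, category))
  K <- length(category); n <- length(hits); N <- length(population)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(data.frame(category_id = category_id, k = k, K = K, n = n,
                       N = N, p_value = p, bh_q = p,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Hallmark over-representation among downregulated geromiRs
#'
#' Runs one upper-tail hypergeometric test per aging hallmark: `K` is the
#' number of on-platform catalog members annotated to the hallmark, `n`
#' the number of downregulated geromiRs, `N` the universe size. Results
#' are ranked by ascending p-value, ties broken by descending `k` then by
#' hallmark name. A miRNA annotated to several hallmarks counts once per
#' hallmark (categories overlap by design). Benjamini-Hochberg values
#' across the hallmarks are reported for information; ranking uses raw p.
#'
#' @param down_geromirs Character vector of downregulated geromiR names
#'   (must be contained in the catalog).
#' @param platform_catalog An on-platform `geromir_catalog`.
#' @param population_size Size of the tested universe. The default
#'   (`NULL`) uses the on-platform catalog size; pass the number of
#'   distinct miRNAs measured on the platform (e.g. a `dem_table`'s
#'   `population_size` attribute) to test against the full platform
#'   universe, which is the pipeline's choice.
#' @return Data.frame of ranked `enrichment_result` rows with a `rank`
#'   column.
#' @export
hallmark_enrichment <- function(down_geromirs, platform_catalog,
                                population_size = NULL) {
  validate_catalog(platform_catalog)
  cat_names <- catalog_names(platform_catalog)
  down_geromirs <- unique(down_geromirs)
  if (!all(down_geromirs %in% cat_names)) {
    stop("downregulated geromiRs not in the catalog: ",
         paste(utils::head(setdiff(down_geromirs, cat_names), 5L),
               collapse = ", "), call. = FALSE)
  }
  N <- if (is.null(population_size)) length(cat_names) else population_size
  if (N < length(cat_names)) {
    stop("population_size smaller than the catalog", call. = FALSE)
  }
  hallmarks <- sort(unique(platform_catalog$hallmark))
  rows <- do.call(rbind, lapply(hallmarks, function(hm) {
    members <- hallmark_members(platform_catalog, hm)
    k <- length(intersect(down_geromirs, members))
    K <- length(members); n <- length(down_geromirs)
    data.frame(category_id = hm, k = k, K = K, n = n, N = N,
               p_value = stats::phyper(k - 1L, K, N - K, n,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rows$bh_q <- stats::p.adjust(rows$p_value, method = "BH")
  ord <- order(rows$p_value, -rows$k, rows$category_id)
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}

#' Calibrate the universe size behind a reported enrichment statistic
#'
#' Over-representation p-values depend on the universe size `N`, which
#' published analyses often omit. Given a reported upper-tail
#' hypergeometric p-value together with its overlap `k`, category size `K`
#' and hit-list size `n`, this searches an integer range of `N` for the
#' value whose exact p is closest (on the log scale) to the reported one.
#' Useful as a documentation aid when reconstructing a published universe;
#' the returned `N` is a calibration estimate, not an assertion.
#'
#' @param p_target Reported p-value.
#' @param k,K,n Overlap, category size, hit-list size.
#' @param N_range Integer search range (default `max(K, n)` to 5000).
#' @return The calibrated `N`, with attribute `p` giving its exact
#'   p-value.
#' @export
calibrate_universe <- function(p_target, k, K, n,
                               N_range = seq(max(K, n), 5000L)) {
  stopifnot(p_target > 0, p_target <= 1, k <= min(K, n))
  p <- stats::phyper(k - 1L, K, N_range - K, n, lower.tail = FALSE)
  best <- which.min(abs(log(p) - log(p_target)))
  structure(N_range[best], p = p[best])
}

#' Permutation null for set over-representation
#'
#' Empirical upper-tail probability of drawing at least `k` category
#' members in a uniform random subset of size `hits_size` from the
#' population, with add-one smoothing: `(#exceedances + 1) / (reps + 1)`.
#' Serves as an independent Monte-Carlo check on [set_enrichment()].
#'
#' @param k Observed category-hit count.
#' @param hits_size Size of the random hit list.
#' @param category,population Identifier vectors (category within
#'   population).
#' @param reps Number of random draws (>= 1000).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return Empirical p-value (single numeric).
#' @export
permutation_null <- function(k, hits_size, category, population,
                             reps = 10000L, seed = 1L) {
  if (reps < 1000L) stop("reps must be at least 1000", call. = FALSE)
  category <- unique(category); population <- unique(population)
  if (!all(category %in% population)) {
    stop("category is not contained in the population", call. = FALSE)
  }
  is_cat <- population %in% category
  exceed <- withr_seed(seed, {
    draws <- vapply(seq_len(reps), function(i) {
      sum(is_cat[sample.int(length(population), hits_size)])
    }, integer(1L))
    sum(draws >= k)
  })
  (exceed + 1) / (reps + 1)
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
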