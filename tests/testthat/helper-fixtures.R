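# Shared in-code fixtures for the test suite.

# Small annotated matrix: two cell types, both conditions, n replicates.
toy_annotation <- function(reps = 3L, cell_types = c("E", "I")) {
  grid <- expand.grid(replicate = seq_len(reps), condition = c("C", "T"),
                      cell_type = cell_types, stringsAsFactors = FALSE)
  sample_annotation(
    sample_id = sprintf("%s_%s_%d", grid$cell_type, grid$condition,
                        grid$replicate),
    cell_type = grid$cell_type, condition = grid$condition,
    replicate = grid$replicate)
}

# Deterministic matrix with optional planted log2 shifts in condition T.
toy_matrix <- function(features, annot, baseline = 8, shift = NULL,
                       noise_sd = 0, seed = 1L) {
  set.seed(seed)
  x <- matrix(stats::rnorm(length(features) * nrow(annot), baseline,
                           noise_sd),
              nrow = length(features),
              dimnames = list(features, annot$sample_id))
  if (!is.null(shift)) {
    tcols <- annot$condition == "T"
    for (f in names(shift)) x[f, tcols] <- x[f, tcols] + shift[[f]]
  }
  x
}

# Exhaustive hypergeometric oracle: enumerate all size-n subsets of a
# population with K category members and count those with >= k hits.
enumerate_tail_p <- function(k, K, n, N) {
  pop <- seq_len(N)
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)  # category = first K elements
  mean(hits >= k)
}

# Tiny catalog built from explicit hallmark lists.
toy_catalog <- function(...) {
  build_catalog(list(src = list(...)))
}
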