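# Small fixtures built in code.

toy_counts <- function(counts, otu_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- otu_ids %||% paste0("OTU", seq_len(nrow(m)))
  colnames(m) <- sample_ids %||% paste0("S", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

# random valid count matrix
random_counts <- function(n_otus = 30, n_samples = 6, lambda = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_otus * n_samples, lambda), n_otus, n_samples)
    m[1, ] <- m[1, ] + 1L  # no all-zero sample
    toy_counts(m)
  })
}

toy_metadata <- function(n = 6, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = paste0("S", seq_len(n)),
    station = paste0("St", seq_len(n)),
    bay = rep_len(c("A", "B", "C"), n),
    layer = rep_len(c("surface", "bottom"), n),
    latitude = 21 + 4 * seq(0, 1, length.out = n),
    longitude = 110 + 8 * seq(0, 1, length.out = n),
    temperature = 20 + rnorm(n),
    pH = 8 + 0.1 * rnorm(n),
    TN = exp(rnorm(n, 0, 0.3))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all n! permutations of 1:n, one per row (for exhaustive oracles)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
  }))
}
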