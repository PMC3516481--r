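#' Random training/validation partitions
#'
#' Generates replicated random splits of `n` lines into a training and a
#' validation set. The same partition list is intended to be reused across
#' every model under comparison, so that per-partition metrics are paired.
#' The validation-set size is `round(validation_fraction * n)` with ties
#' rounded half away from zero (306 lines at 10\% gives 31 validation
#' lines).
#'
#' @param n number of lines (>= 10).
#' @param n_partitions number of random partitions (default 50).
#' @param validation_fraction fraction assigned to the validation set,
#'   in (0, 0.5] (default 0.10).
#' @param seed integer seed; the full list is deterministic given it.
#' @return list of partitions, each a list with `partition_index`,
#'   `train_idx`, `test_idx` and `seed`.
#' @export
make_partitions <- function(n, n_partitions = 50,
                            validation_fraction = 0.10, seed = 1L) {
  if (n < 10) stop("n must be >= 10")
  if (validation_fraction <= 0 || validation_fraction > 0.5)
    stop("validation_fraction must be in (0, 0.5]")
  n_test <- floor(validation_fraction * n + 0.5)  # round half away from zero
  if (n_test < 1) stop("validation set would be empty")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n_partitions), function(k) {
    test <- sort(sample.int(n, n_test))
    list(partition_index = k,
         train_idx = setdiff(seq_len(n), test),
         test_idx = test,
         seed = seed)
  })
}

# Deterministic per-(partition, model) sub-seed so models can be run in any
# order, or alone, against identical partitions. Kept below 2^31.
derive_seed <- function(master_seed, partition_index, model = "") {
  h <- sum(utf8ToInt(model) * seq_along(utf8ToInt(model)))
  as.integer((as.double(master_seed) * 48271 + partition_index * 9973 +
                h * 31 + 17) %% 2147483647)
}
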