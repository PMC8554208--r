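# Shared internals: scoped RNG and stratified fold assignment.

# Run `fn()` under a temporary seed, restoring the caller's RNG stream.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Derive a child seed from a base seed and a stream label; stays < 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483629 + 1
}

# Stratified k-fold assignment: within each class, fold labels are randomly
# permuted over the class members so per-class fold sizes differ by at most
# one.  Assignment is keyed to `ids` (default: row position): permuting the
# rows and their ids together leaves each id's fold unchanged.
# Returns an integer vector of fold ids in 1..k.
stratified_folds <- function(y, k, seed, ids = seq_along(y)) {
  y <- as.integer(y)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  counts <- table(y)
  if (any(counts < k))
    stop("stratification error: class ", names(counts)[counts < k][[1L]],
         " has fewer members (", min(counts), ") than k = ", k,
         call. = FALSE)
  folds <- integer(length(y))
  with_seed(seed, function() {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[order(ids[idx])]
      folds[idx] <<- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}
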