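# Synthetic active/decoy descriptor tables.
#
# The generator emulates a literature-curated virtual-screening dataset: a
# small set of active compounds against a three-fold excess of decoys
# (default 88 actives / 264 decoys), described by continuous molecular
# descriptors.  Three signal structures are available:
#
#   "blobs"          two Gaussian classes separated by a mean shift on a
#                    random informative feature subset;
#   "complementary"  three feature blocks carrying linear-margin, XOR-like
#                    interaction, and local-cluster signal respectively, so
#                    linear, tree and neighbourhood learners are
#                    differentially informative (the stacking benchmark);
#   "null"           labels independent of all features (leakage canary).

#' Specification of a synthetic active/decoy dataset
#'
#' @param n_pos Number of active compounds (default 88).
#' @param n_neg Number of decoys (default 264, a 1:3 imbalance).
#' @param m Number of molecular descriptors (default 50).
#' @param structure `"complementary"` (default), `"blobs"` or `"null"`.
#' @param noise_sd Descriptor noise standard deviation (default 1); the
#'   class signal has fixed absolute magnitude, so larger noise weakens it.
#' @param seed Integer seed; the table is fully determined by the spec.
#' @return A list of class `dataset_spec`.
#' @export
dataset_spec <- function(n_pos = 88L, n_neg = 264L, m = 50L,
                         structure = c("complementary", "blobs", "null"),
                         noise_sd = 1, seed = 1L) {
  spec <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
               m = as.integer(m), structure = match.arg(structure),
               noise_sd = noise_sd, seed = as.integer(seed))
  if (spec$n_pos < 1L || spec$n_neg < 1L)
    stop("n_pos and n_neg must be at least 1", call. = FALSE)
  if (spec$m < 2L) stop("m must be at least 2", call. = FALSE)
  if (spec$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  class(spec) <- "dataset_spec"
  spec
}

#' Generate a labelled synthetic descriptor table
#'
#' @param spec A [dataset_spec()].
#' @return A list of class `labeled_table`: `ids` (character), `features`
#'   (n x m numeric matrix, columns d1..dm), `label` (integer 0/1, actives
#'   = 1), `spec`.
#' @examples
#' d <- generate_dataset(dataset_spec(n_pos = 10, n_neg = 30, m = 10,
#'                                    seed = 42))
#' table(d$label)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  n <- spec$n_pos + spec$n_neg
  m <- spec$m
  sd <- spec$noise_sd
  with_seed(spec$seed, function() {
    X <- matrix(stats::rnorm(n * m, 0, sd), n, m)
    y <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
    pos <- y == 1L

    if (spec$structure == "blobs") {
      n_inf <- max(2L, ceiling(m / 5))
      inf <- sample.int(m, n_inf)
      X[pos, inf] <- X[pos, inf] + 2
    } else if (spec$structure == "complementary") {
      # Three signal blocks, each aimed at a different learner family:
      # masked linear-contrast pairs (linear margins recover them, axis
      # splits and marginal models barely do), a sign-correlation XOR
      # block (zero marginal shift, so linear models are blind; depth-2
      # axis splits recover it), and oblique interleaved local clusters
      # (neighbourhood methods recover them).  Block sizes scale with m;
      # remaining features are pure noise.
      n_lin <- max(2L, min(12L, floor(m / 4)))
      lin <- seq_len(min(n_lin, m))
      n_xor <- max(0L, min(6L, m - length(lin)))
      n_xor <- n_xor - n_xor %% 2L
      xor <- length(lin) + seq_len(n_xor)
      clu <- length(lin) + n_xor +
        seq_len(max(0L, min(8L, m - length(lin) - n_xor)))
      # linear-contrast block: pairs of strongly co-varying descriptors
      # whose *difference* carries the class signal.  A per-pair latent
      # factor dominates both features, so every marginal looks almost
      # class-free and axis-additive splits gain little at this sample
      # size, while any linear margin recovers the contrast
      # u - v = delta * y + noise.
      for (p in seq_len(length(lin) %/% 2L)) {
        u <- lin[[2L * p - 1L]]
        v <- lin[[2L * p]]
        zp <- stats::rnorm(n, 0, 2 * sd)
        X[, u] <- zp + 0.45 * X[, u] + 0.25 * pos
        X[, v] <- zp - 0.45 * X[, v] - 0.25 * pos
      }
      # XOR-like pairs: same-sign for actives, opposite-sign for decoys
      for (p in seq_len(length(xor) %/% 2L)) {
        a <- xor[[2L * p - 1L]]
        b <- xor[[2L * p]]
        s <- sample(c(-1, 1), n, replace = TRUE)
        X[, a] <- X[, a] + s * 0.85
        X[, b] <- X[, b] + ifelse(pos, s, -s) * 0.85
      }
      # local clusters: classes live on interleaved cluster centres; the
      # block is then rotated obliquely so the clusters stay visible to
      # neighbourhood methods (rotation-invariant distances) but are hard
      # for axis-aligned splits
      if (length(clu) >= 2L) {
        n_clusters <- 4L
        centers_pos <- matrix(stats::runif(n_clusters * length(clu),
                                           -1.0, 1.0), n_clusters)
        centers_neg <- matrix(stats::runif(n_clusters * length(clu),
                                           -1.0, 1.0), n_clusters)
        assign_pos <- sample.int(n_clusters, sum(pos), replace = TRUE)
        assign_neg <- sample.int(n_clusters, sum(!pos), replace = TRUE)
        X[pos, clu] <- X[pos, clu] * 0.8 + centers_pos[assign_pos, ,
                                                       drop = FALSE]
        X[!pos, clu] <- X[!pos, clu] * 0.8 + centers_neg[assign_neg, ,
                                                         drop = FALSE]
        rot <- qr.Q(qr(matrix(stats::rnorm(length(clu)^2), length(clu))))
        X[, clu] <- X[, clu, drop = FALSE] %*% rot
      }
    }
    # "null": X stays independent of y

    perm <- sample.int(n)
    X <- X[perm, , drop = FALSE]
    y <- y[perm]
    colnames(X) <- paste0("d", seq_len(m))
    structure(list(ids = sprintf("cmpd_%04d", seq_len(n)), features = X,
                   label = y, spec = spec),
              class = "labeled_table")
  })
}

#' @export
print.labeled_table <- function(x, ...) {
  cat("Labelled descriptor table: ", length(x$label), " compounds x ",
      ncol(x$features), " descriptors (", sum(x$label == 1L), " active, ",
      sum(x$label == 0L), " decoy; structure '", x$spec$structure, "')\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.labeled_table <- function(x, ...) {
  data.frame(id = x$ids, x$features, label = x$label,
             stringsAsFactors = FALSE)
}

#' Fixed worked example for the Gaussian neuron-operator recursion
#'
#' Returns a frozen 2-operator / 3-leaf flexible neural tree together with
#' four input vectors and their hand-computed outputs (evaluated directly
#' from the operator formula, recorded here as constants).  Used as a
#' cross-implementation anchor for tree evaluation and serialization.
#'
#' @return List with `tree` (an `fnt_tree` over 3 inputs), `inputs` (4 x 3
#'   matrix) and `outputs` (length-4 numeric vector of expected values).
#' @export
generate_worked_fixture <- function() {
  inner <- fnt_op(c(0.6, -0.4), 0.2, 0.5, list(fnt_var(1), fnt_var(2)))
  root <- fnt_op(c(0.8, 0.3), 0.5, 0.9, list(inner, fnt_var(3)))
  tree <- fnt_tree(root, n_inputs = 3L, max_depth = 2L)
  inputs <- rbind(c(0.10, 0.20, 0.30),
                  c(0.90, 0.50, 0.70),
                  c(0.00, 1.00, 0.50),
                  c(0.42, 0.13, 0.77))
  colnames(inputs) <- c("c1", "c2", "c3")
  outputs <- c(0.92620353246339315, 0.77908143665129881,
               0.96871381281985736, 0.70602826985713951)
  list(tree = tree, inputs = inputs, outputs = outputs)
}
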