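# Per-residue embedding matrices.
#
# An embedding matrix is an n_residues x dim numeric matrix whose rownames
# are the structure's residue keys, row i describing residue i. Real
# embeddings come from an external inverse-folding embedder through the
# provider contract; tests use the planted-signal synthetic generator.

#' Validate an embedding matrix against a structure
#' @param values numeric matrix, rows aligned to structure residues
#' @param structure the `protein_structure` the rows describe
#' @return the matrix, with rownames set to the residue keys
#' @export
embedding_matrix <- function(values, structure) {
  values <- as.matrix(values)
  if (nrow(values) != n_residues(structure))
    stop("embedding has ", nrow(values), " rows but structure has ",
         n_residues(structure), " residues")
  if (!all(is.finite(values))) stop("non-finite embedding values")
  rownames(values) <- structure$residue_keys
  values
}

#' Create an embedding provider
#'
#' A provider is a callable contract: given a `protein_structure` it returns
#' an embedding matrix with one row per residue. The deterministic flag
#' promises identical output for identical input.
#'
#' @param fun function(structure) -> numeric matrix
#' @param name provider label
#' @param deterministic logical
#' @return object of class `embedding_provider`
#' @export
embedding_provider <- function(fun, name = "custom", deterministic = TRUE) {
  stopifnot(is.function(fun))
  structure(list(fun = fun, name = name, deterministic = deterministic),
            class = "embedding_provider")
}

#' Obtain validated embeddings for a structure
#' @param structure a `protein_structure`
#' @param provider an [embedding_provider()]
#' @return embedding matrix (n_residues x dim, rownames = residue keys)
#' @export
get_embeddings <- function(structure, provider) {
  stopifnot(inherits(provider, "embedding_provider"))
  embedding_matrix(provider$fun(structure), structure)
}

#' Unit direction of the planted embedding signal
#'
#' The synthetic generator shifts binding-residue rows along a fixed unit
#' direction drawn from the seed; sharing one direction across conformers of
#' a protein emulates one embedder applied to each of them. The direction is
#' sparse: its support is a small seeded random subset of channels
#' (default 4, fewer for tiny dims) with Gaussian loadings. This mirrors how
#' discriminative information in learnt residue embeddings concentrates in a
#' few channels, and keeps the planted signal visible to axis-aligned tree
#' splits at realistic sample sizes; a dense isotropic direction would
#' spread an `effect_size` shift over every channel (about
#' `effect_size/sqrt(dim)` per channel), which no tree ensemble can recover
#' from hundreds of residues.
#'
#' @param dim embedding dimension
#' @param seed integer seed
#' @param n_active number of non-zero channels (default
#'   `min(4, max(2, dim %/% 4))`)
#' @return unit-norm numeric vector of length `dim`
#' @export
planted_direction <- function(dim, seed,
                              n_active = min(4, max(2, dim %/% 4))) {
  stopifnot(n_active >= 1, n_active <= dim)
  withr_seed(seed, {
    idx <- sample.int(dim, n_active)
    u <- numeric(dim)
    u[idx] <- rnorm(n_active)
    u / sqrt(sum(u^2))
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic per-residue embeddings with a planted mean shift
#'
#' Non-binding rows are isotropic Gaussian noise; binding rows receive an
#' additional mean shift of `effect_size` along a unit direction drawn from
#' the seed. This is the simplest signal structure that lets the ensemble
#' classifier and its dose response be tested: at `effect_size = 0` the two
#' classes are indistinguishable, and separability grows with
#' `effect_size / noise_sd`.
#'
#' @param structure a `protein_structure`
#' @param true_binding_keys residue keys of the binding class
#' @param dim embedding dimension (default 512, matching the real embedder)
#' @param effect_size mean shift along the planted direction
#' @param noise_sd isotropic noise standard deviation (> 0)
#' @param seed integer seed (controls direction and noise)
#' @param direction optional pre-drawn unit direction (overrides the seed's)
#' @return embedding matrix
#' @export
synthetic_embeddings <- function(structure, true_binding_keys, dim = 512,
                                 effect_size = 3, noise_sd = 1, seed = 1,
                                 direction = NULL) {
  stopifnot(dim >= 2, noise_sd > 0)
  keys <- structure$residue_keys
  unknown <- setdiff(true_binding_keys, keys)
  if (length(unknown))
    stop("unknown residue key(s) in true_binding_keys: ",
         paste(head(unknown, 3), collapse = ", "))
  u <- if (is.null(direction)) planted_direction(dim, seed) else {
    stopifnot(length(direction) == dim)
    direction / sqrt(sum(direction^2))
  }
  n <- length(keys)
  vals <- withr_seed(seed + 1L,
                     matrix(rnorm(n * dim, sd = noise_sd), n, dim))
  is_pos <- keys %in% true_binding_keys
  vals[is_pos, ] <- sweep(vals[is_pos, , drop = FALSE], 2,
                          effect_size * u, "+")
  embedding_matrix(vals, structure)
}

#' Provider wrapping the synthetic generator
#'
#' @param true_binding_keys residue keys carrying the planted signal
#' @inheritParams synthetic_embeddings
#' @return an [embedding_provider()]
#' @export
synthetic_embedding_provider <- function(true_binding_keys, dim = 512,
                                         effect_size = 3, noise_sd = 1,
                                         seed = 1, direction = NULL) {
  embedding_provider(
    function(structure)
      synthetic_embeddings(structure, intersect(true_binding_keys,
                                                structure$residue_keys),
                           dim = dim, effect_size = effect_size,
                           noise_sd = noise_sd, seed = seed,
                           direction = direction),
    name = "synthetic", deterministic = TRUE)
}

#' Write/read an embedding cache
#'
#' Plain-text cache: a TSV matrix plus the residue keys as the first column.
#'
#' @param emb embedding matrix with residue-key rownames
#' @param path file path
#' @return `path` (write) or the embedding matrix (read)
#' @export
write_embedding_cache <- function(emb, path) {
  df <- data.frame(key = rownames(emb), emb, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_cache
#' @export
read_embedding_cache <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$key
  m
}
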