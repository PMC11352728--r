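# Alternative ligand/substrate encodings for the modeling benchmark:
# circular (Morgan) fingerprints, one-hot identity indicators, and the
# random-descriptor control that probes whether models learn chemistry or
# mere object identity.

#' Circular (Morgan/ECFP4) fingerprints
#'
#' Hashed extended-connectivity fingerprints of radius 2 ("ECFP4") with a
#' fixed bit length, computed with rdkit through the bundled helper.
#'
#' @param smiles Character vector of SMILES (dative metal-ligand bonds are
#'   written as single bonds).
#' @param radius Morgan radius (default 2, i.e. ECFP4).
#' @param n_bits Bit-vector length (default 512).
#' @return Tibble with one row per input: `smiles` followed by integer
#'   columns `fp_0001` ... `fp_<n_bits>`.
#' @export
circular_fingerprint <- function(smiles, radius = 2, n_bits = 512) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  out <- run_chemtools("ecfp", list(smiles = as.list(smiles),
                                    radius = radius, n_bits = n_bits))
  bits <- out$bits
  if (is.list(bits)) bits <- do.call(rbind, lapply(bits, as.integer))
  bits <- matrix(as.integer(bits), nrow = length(smiles))
  colnames(bits) <- sprintf("fp_%04d", seq_len(n_bits))
  dplyr::bind_cols(tibble::tibble(smiles = smiles),
                   tibble::as_tibble(bits))
}

#' One-hot (identity) encoding
#'
#' @param ids Character vector of identifiers (repeats allowed).
#' @return Tibble with one row per input id, an `id` column and one 0/1
#'   indicator column per unique id in sorted order; every row sums to 1.
#' @export
one_hot <- function(ids) {
  ids <- as.character(ids)
  levels <- sort(unique(ids))
  mat <- outer(ids, levels, `==`) * 1L
  colnames(mat) <- levels
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(mat))
}

#' Random-descriptor control vectors
#'
#' Assigns every unique id one reproducible vector of values drawn
#' uniformly from \[low, high\].  Each occurrence of an id maps to the same
#' vector, so these features encode identity and nothing else -- the
#' control used to test whether descriptor "meaning" matters to a model.
#'
#' @param ids Character vector of identifiers.
#' @param n_features Vector length per id (default 34, matching the
#'   catalyst schema).
#' @param low,high Uniform bounds (defaults -100, +100).
#' @param seed RNG seed (required for reproducibility).
#' @return Tibble with one row per unique id (sorted): `id` plus columns
#'   `rand_01` ... `rand_<n_features>`.
#' @export
random_descriptors <- function(ids, n_features = 34, low = -100,
                               high = 100, seed) {
  if (n_features <= 0) stop("n_features must be positive", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  levels <- sort(unique(as.character(ids)))
  old <- .Random.seed_exists()
  set.seed(seed)
  mat <- matrix(stats::runif(length(levels) * n_features, low, high),
                nrow = length(levels), byrow = TRUE)
  on.exit(restore_seed(old), add = TRUE)
  colnames(mat) <- sprintf("rand_%02d", seq_len(n_features))
  dplyr::bind_cols(tibble::tibble(id = levels), tibble::as_tibble(mat))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
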