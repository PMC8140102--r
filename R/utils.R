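# Internal helpers shared across modules.

# Flatten a frames x atoms x 3 array to frames x 3N (atom-major: a1x a1y a1z
# a2x ...) and back. All featurization works on the flat layout.
flattenCoords <- function(arr) {
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] == 3L)
  matrix(aperm(arr, c(1L, 3L, 2L)), nrow = dim(arr)[1])
}

unflattenCoords <- function(mat, nAtoms) {
  stopifnot(ncol(mat) == 3L * nAtoms)
  aperm(array(mat, dim = c(nrow(mat), 3L, nAtoms)), c(1L, 3L, 2L))
}

# Coordinate (column) indices of a set of atom indices in the flat layout.
coordIdx <- function(atomIdx) {
  as.vector(vapply(atomIdx, function(a) (3L * (a - 1L)) + 1:3, integer(3)))
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
localSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Logistic nonlinearity used on all hidden layers and the classifier head.
sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopUnless <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
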