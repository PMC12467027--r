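`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global random stream. A NULL seed evaluates the expression
#' under the ambient RNG state.
#'
#' @param seed integer seed or NULL
#' @param code expression to evaluate
#' @return the value of `code`
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues formula; `axis` need not be normalized. Angle in radians.
#'
#' @param axis length-3 numeric
#' @param angle radians
#' @return 3x3 rotation matrix (determinant +1)
#' @export
rotation_matrix <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero length")
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Uniform random rotation via a normalized Gaussian quaternion.
random_rotation_matrix <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)

element_mass <- function(element) {
  m <- ELEMENT_MASSES[element]
  m[is.na(m)] <- 12.011
  unname(m)
}

# Collapse a sorted integer vector to "a-b,c" run notation (report formatting).
runs_to_string <- function(x) {
  x <- sort(unique(x))
  if (length(x) == 0L) return("")
  brk <- c(0L, which(diff(x) != 1L), length(x))
  paste(vapply(seq_len(length(brk) - 1L), function(i) {
    seg <- x[(brk[i] + 1L):brk[i + 1L]]
    if (length(seg) == 1L) as.character(seg)
    else paste0(seg[1], "-", seg[length(seg)])
  }, character(1)), collapse = ",")
}
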