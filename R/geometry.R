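# Periodic geometry: minimum-image distances and dihedral angles.

#' Minimum-image distance in an orthorhombic box
#'
#' @param a,b numeric length-3 points or n x 3 matrices (Angstrom).
#' @param box numeric length-3 positive box edges (Angstrom).
#' @return distance(s) in Angstrom.
#' @export
min_image_distance <- function(a, b, box) {
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive lengths")
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  min_image_dist_cpp(a, b, as.numeric(box))
}

# Brute-force minimum over the 27 neighbor images; independent oracle used
# by the test suite (kept exported-internal so tests exercise one code path
# against the other).
min_image_distance_27 <- function(a, b, box) {
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- Inf
  for (i in seq_len(nrow(shifts))) {
    d <- a - (b + shifts[i, ] * box)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# Dihedral angle (degrees, (-180, 180]) through points p1-p2-p3-p4,
# IUPAC sign convention (cis = 0); matches the MD-analysis standard.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2)) * 180 / pi
  fold_angle(ang)
}

# Fold an angle (degrees) into (-180, 180].
fold_angle <- function(x) {
  y <- x - 360 * round(x / 360)
  y[y <= -180] <- y[y <= -180] + 360
  y
}

# Seeded RNG scope: evaluates expr with a local RNG state. The seed
# argument is forced before the caller's RNG state is saved, so seed
# expressions that themselves draw from the RNG behave as expected.
with_seed <- function(seed, expr) {
  force(seed)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
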