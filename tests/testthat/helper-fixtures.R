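# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no data files.

# A random periodic point cloud posing as a three-class structure.
random_structure <- function(n, box = c(40, 40, 40), seed = 1) {
  set.seed(seed)
  cls <- sample(c("cellulose", "xylan", "lignin"), n, replace = TRUE)
  rt <- c(cellulose = "GLC", xylan = "XYL", lignin = "SYR")[cls]
  atoms <- atom_table(rep("C", n), paste0("C", seq_len(n) %% 9 + 1),
                      seq_len(n), rt, as.integer(factor(cls)),
                      runif(n, 0, box[1]), runif(n, 0, box[2]),
                      runif(n, 0, box[3]), polymer_class = cls)
  scw_structure(atoms, box = box)
}

# 27-image brute-force minimum distance (independent of the C++ path).
min_image_27 <- function(a, b, box) {
  sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- Inf
  for (i in 1:27) best <- min(best, sqrt(sum((a - (b + sh[i, ] * box))^2)))
  best
}

# Independent dihedral: Gram-Schmidt projection ("praxeolitic") formula,
# distinct from the package's cross-product implementation.
dihedral_gs <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  n <- b2 / sqrt(sum(b2^2))
  v <- b0 - sum(b0 * n) * n
  w <- b3 - sum(b3 * n) * n
  x <- sum(v * w)
  y <- sum((c(n[2] * v[3] - n[3] * v[2],
              n[3] * v[1] - n[1] * v[3],
              n[1] * v[2] - n[2] * v[1])) * w)
  ang <- atan2(y, x) * 180 / pi
  ang - 360 * round(ang / 360)
}

# Small assembled toys reused across tests (cached per session).
toy_model <- local({
  cache <- list()
  function(scenario = "a", seed = 3) {
    key <- paste(scenario, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- assemble_scenario(
        scenario_spec(scenario, n_fibrils = 2, n_xylan = 6, n_lignin = 6,
                      dp = 10, seed = seed))
    cache[[key]]
  }
})

# Per-chain min-distance based clash census: every heavy-atom pair either
# sits in the bonded band [1.2, 1.6] A or at least `floor` apart.
pair_distance_census <- function(s, floor = 1.8) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  d <- as.matrix(dist(m)); diag(d) <- Inf
  dv <- d[upper.tri(d)]
  list(n_bondlike = sum(dv >= 1.2 & dv <= 1.6),
       n_bad = sum(dv < floor & (dv < 1.2 | dv > 1.6)),
       min = min(dv))
}
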