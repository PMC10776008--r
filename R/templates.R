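# Idealized heavy-atom residue templates and screw-axis chain growth.
#
# The cellulose I-beta unit cell of the crystal structure this work builds
# on has a = 7.784, b = 8.201, c = 10.380 A (monoclinic, gamma = 96.5 deg),
# with the chain axis along c and two residues per c repeat. The builders
# use an idealized orthogonalized version of that lattice:
#   * per-residue rise c/2 = 5.19 A with a 180 deg (2_1) screw,
#   * in-sheet chain spacing b = 8.2 A,
#   * sheet stacking distance 3.9 A (the (200) d-spacing, a/2 sin gamma),
#   * alternate sheets staggered by c/4 = 2.595 A along the chain axis.
# Residue internal coordinates are idealized (chair ring projected onto a
# ribbon): bond lengths 1.45-1.55 A (C-C) and 1.36-1.43 A (C-O). Chemistry
# beyond heavy-atom connectivity is not modeled.

IB_RISE <- 5.19          # per-residue rise along the fibril axis, A
IB_CHAIN_SPACING <- 8.2  # within-sheet chain spacing, A
IB_SHEET_SPACING <- 3.9  # sheet stacking distance, A
IB_STAGGER <- 2.595      # c/4 stagger of alternate sheets, A
XYLAN3_RISE <- 4.95      # threefold (3_1) xylan per-residue rise, A

RING_RADIUS <- 1.45
RING_PUCKER <- 0.25
B_CO <- 1.43             # C-O bond, A
B_CC <- 1.53             # C-C bond, A
O3_SWING <- -95          # azimuthal swing of O3 about the chain axis (deg),
                         # calibrated so O3-borne acetates match the O2 face

# Geometry calibration of the glycan residue placement: dx shifts the
# screw axis relative to the ring center, tilt_y rotates the ring within
# its own (zx) plane, tilt_x tips it out of plane, and gamma picks the
# direction of the bridging O4 off the C4..C1' chord (see glycan_link_O4).
# Values are calibrated once so that the twofold builder reproduces the
# 2_1 anchor phi+psi ~ +120 deg and the threefold builder lands in the 3_1
# regime; see the methods vignette. They are geometry constants, not
# fitting parameters.
GLYCAN_GEOM <- list(
  twofold   = list(twist = 180,  rise = IB_RISE, dx = -0.6, gamma = 100,
                   tilt_x = 20, tilt_y = -10),
  threefold = list(twist = -120, rise = XYLAN3_RISE, dx = 0.0, gamma = 60,
                   tilt_x = 20, tilt_y = 0)
)

rotz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

unitv <- function(v) v / sqrt(sum(v^2))

# rotate the (x, z) components of v by deg within the zx-plane
rot_zx <- function(v, deg) {
  th <- deg * pi / 180
  c(cos(th) * v[1] + sin(th) * v[3], v[2],
    -sin(th) * v[1] + cos(th) * v[3])
}

# Pyranose ring template: chair projected onto a ribbon in the zx-plane
# (z = chain axis), puckered +-RING_PUCKER along y. Returns positions
# (rows = labels) and elements. "GLC" adds the C6/O6 hydroxymethyl, "GLCA"
# the C6 carboxylate instead.
pyranose_template <- function(sugar = c("XYL", "GLC", "GLCA")) {
  sugar <- match.arg(sugar)
  r <- RING_RADIUS; p <- RING_PUCKER
  ring_lab <- c("C1", "C2", "C3", "C4", "C5", "O5")
  ang <- (0:5) * 60 * pi / 180
  pos <- cbind(x = r * sin(ang), y = p * ifelse(seq_len(6) %% 2 == 1, 1, -1),
               z = r * cos(ang))
  rownames(pos) <- ring_lab
  radial <- function(atom) unitv(c(pos[atom, "x"], 0, pos[atom, "z"]))
  add <- function(m, label, xyz) rbind(m, matrix(xyz, 1, 3,
                                                 dimnames = list(label)))
  pos <- add(pos, "O2", pos["C2", ] + B_CO * radial("C2"))
  # O3 is swung azimuthally toward O2 so that an acetate carried on O3 (a
  # GlcA-bearing residue) orients like its O2-borne neighbors; calibrated
  # against the theta2f ~ 0 anchor of the twofold decoration face.
  pos <- add(pos, "O3", pos["C3", ] +
               B_CO * drop(rotz(O3_SWING) %*% radial("C3")))
  elem <- c(rep("C", 5), "O", "O", "O")
  if (sugar %in% c("GLC", "GLCA")) {
    pos <- add(pos, "C6", pos["C5", ] + B_CC * radial("C5"))
    if (sugar == "GLC") {
      pos <- add(pos, "O6", pos["C6", ] + B_CO * rot_zx(radial("C5"), 60))
      elem <- c(elem, "C", "O")
    } else {
      # carboxylate oxygens of the uronic acid
      pos <- add(pos, "O6A", pos["C6", ] + 1.25 * rot_zx(radial("C5"), 50))
      pos <- add(pos, "O6B", pos["C6", ] + 1.25 * rot_zx(radial("C5"), -50))
      elem <- c(elem, "C", "O", "O")
    }
  }
  list(pos = pos, elem = elem)
}

# Bridging O4 for a glycosidic link under a screw step (twist deg about the
# z axis through -dx relative to the template, rise A of descent). The
# oxygen is placed equidistant (B_CO) from C4 of the current residue and C1
# of the next; gamma (deg) selects where on that circle.
glycan_link_O4 <- function(tpl_pos, twist, rise, gamma) {
  C1n <- drop(rotz(twist) %*% tpl_pos["C1", ]) + c(0, 0, -rise)
  C4 <- tpl_pos["C4", ]
  chord <- C1n - C4
  h <- sqrt(sum(chord^2)) / 2
  if (h >= B_CO)
    stop("glycosidic geometry infeasible: C4..C1' chord exceeds 2 bond lengths")
  u <- unitv(chord)
  w1 <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u
  if (sqrt(sum(w1^2)) < 1e-6) w1 <- c(0, 1, 0) - sum(c(0, 1, 0) * u) * u
  w1 <- unitv(w1)
  w2 <- c(u[2] * w1[3] - u[3] * w1[2],
          u[3] * w1[1] - u[1] * w1[3],
          u[1] * w1[2] - u[2] * w1[1])
  rho <- sqrt(B_CO^2 - h^2)
  g <- gamma * pi / 180
  (C4 + C1n) / 2 + rho * (cos(g) * w1 + sin(g) * w2)
}

roty <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
         3, 3, byrow = TRUE)
}

rotx <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
         3, 3, byrow = TRUE)
}

# Grow a beta(1->4) glycan chain along -z. `twists` gives the per-linkage
# screw rotation (deg, length dp; the last entry orients the terminal O4);
# `rises` the per-linkage descent. Residues are numbered from the reducing
# end (residue 1 has the free anomeric carbon at the top).
build_glycan_chain <- function(dp, sugar, twists, rises, dx, gamma,
                               chain_id = 1L, tilt_x = 0, tilt_y = 0) {
  stopifnot(dp >= 1)
  tpl <- pyranose_template(sugar)
  pos0 <- t(roty(tilt_y) %*% rotx(tilt_x) %*% t(tpl$pos))
  pos0 <- sweep(pos0, 2, c(-dx, 0, 0)) # shift so screw axis is at x = 0
  if (length(twists) == 1) twists <- rep(twists, dp)
  if (length(rises) == 1) rises <- rep(rises, dp)
  angles <- cumsum(c(0, twists))[seq_len(dp)]
  zs <- cumsum(c(0, rises))[seq_len(dp)]
  rtype <- switch(sugar, XYL = "XYL", GLC = "GLC", GLCA = "GLCA")
  out <- vector("list", dp)
  for (j in seq_len(dp)) {
    O4 <- glycan_link_O4(pos0, twists[j], rises[j], gamma)
    pj <- rbind(pos0, O4 = O4)
    ej <- c(tpl$elem, "O")
    R <- rotz(angles[j])
    pj <- t(R %*% t(pj))
    pj[, 3] <- pj[, 3] - zs[j]
    out[[j]] <- atom_table(ej, rownames(pj), j, rtype, chain_id,
                           pj[, 1], pj[, 2], pj[, 3])
  }
  atoms <- do.call(rbind, out)
  # mirror across the zx-plane: fixes the chain chirality so the calibrated
  # screw geometries give the canonical torsion signs (phi+psi ~ +120 deg
  # for the twofold) under the IUPAC dihedral convention
  atoms$y <- -atoms$y
  atoms$atom_id <- seq_len(nrow(atoms)) - 1L
  atoms
}

# Acetyl group grafted onto oxygen `o_pos` of a ring, extending along
# `dir` (unit vector away from the ring). Labels: AcCO (carbonyl carbon,
# 170 ppm), AcO (carbonyl oxygen), AcMe (methyl carbon, 22 ppm).
acetyl_atoms <- function(o_pos, dir, residue_index, chain_id) {
  d1 <- unitv(dir)
  q <- c(d1[2], -d1[1], 0)
  if (sqrt(sum(q^2)) < 1e-6) q <- c(1, 0, 0)
  q <- unitv(q)
  acc <- o_pos + 1.36 * d1
  aco <- acc + 1.22 * unitv(0.5 * d1 + 0.866 * q)
  acme <- acc + 1.50 * unitv(0.5 * d1 - 0.866 * q)
  atom_table(c("C", "O", "C"), c("AcCO", "AcO", "AcMe"),
             residue_index, "ACE", chain_id,
             c(acc[1], aco[1], acme[1]), c(acc[2], aco[2], acme[2]),
             c(acc[3], aco[3], acme[3]))
}

# Glucuronosyl unit grafted onto a backbone oxygen at `o_pos`, ring plane
# containing `dir` (outward) and the chain axis; the anomeric C1 sits next
# to the bridging oxygen (the host O2) and the ring extends outward.
glca_atoms <- function(o_pos, dir, residue_index, chain_id) {
  tpl <- pyranose_template("GLCA")
  # terminal O4 hydroxyl extends past C4, i.e. outward (local -z)
  pos <- rbind(tpl$pos, O4 = tpl$pos["C4", ] + B_CO * c(0, 0, -1))
  elem <- c(tpl$elem, "O")
  d <- unitv(c(dir[1], dir[2], 0))
  # map local +z (the C1 side of the ring) onto -d so C1 faces the host
  R <- cbind(c(0, 0, 1), c(-d[2], d[1], 0), -d) # images of local x, y, z
  center <- o_pos + (B_CO + RING_RADIUS) * d
  pos <- t(R %*% t(pos))
  pos <- sweep(pos, 2, center, "+")
  atom_table(elem, rownames(pos), residue_index, "GLCA", chain_id,
             pos[, 1], pos[, 2], pos[, 3])
}
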