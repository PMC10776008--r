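# Single-polymer builders: cellulose elementary fibrils, decorated xylan
# chains, and syringyl/guaiacyl lignin 20-mers.

#' Elementary cellulose fibril specification
#'
#' Defaults describe the consensus 18-chain I-beta elementary fibril with a
#' 2-3-4-4-3-2 cross-section row profile and chains of 40 glucose units,
#' exposing the (100), (200), (110) and (1-10) crystallographic faces.
#'
#' @param n_chains number of glucan chains (default 18).
#' @param arrangement integer row profile of the cross-section; must sum to
#'   `n_chains`.
#' @param dp glucose units per chain (default 40).
#' @param allomorph only "Ibeta" is supported.
#' @return a `fibril_spec` list.
#' @export
fibril_spec <- function(n_chains = 18L, arrangement = c(2, 3, 4, 4, 3, 2),
                        dp = 40L, allomorph = "Ibeta") {
  if (sum(arrangement) != n_chains)
    stop("arrangement rows must sum to n_chains")
  if (dp < 1) stop("dp must be >= 1")
  if (allomorph != "Ibeta") stop("only the Ibeta allomorph is supported")
  structure(list(n_chains = as.integer(n_chains),
                 arrangement = as.integer(arrangement),
                 dp = as.integer(dp), allomorph = allomorph),
            class = "fibril_spec")
}

# Cross-section lattice of a fibril: chain axis offsets (x, y) and the c/4
# z-stagger of alternate sheets. Rows are sheets stacked along y; chains
# within a sheet are spaced along x and each row is centered, so rows of
# unequal parity interdigitate naturally (the 234432 diamond).
fibril_lattice <- function(arrangement) {
  nk <- length(arrangement)
  do.call(rbind, lapply(seq_len(nk), function(k) {
    n <- arrangement[k]
    data.frame(x = (seq_len(n) - (n + 1) / 2) * IB_CHAIN_SPACING,
               y = (k - (nk + 1) / 2) * IB_SHEET_SPACING,
               z = IB_STAGGER * (k %% 2))
  }))
}

#' Build an elementary cellulose fibril
#'
#' Chains are parallel to z with the twofold screw of the I-beta lattice;
#' the cross-section follows the row profile of `spec`. A chain of DP
#' residues spans `dp * 5.19` A, matching the periodic box length assembly
#' uses, so fibrils continue seamlessly across the z boundary.
#'
#' @param spec a [fibril_spec()].
#' @return an `scw_structure` (non-periodic until assembled).
#' @export
build_cellulose_fibril <- function(spec = fibril_spec()) {
  stopifnot(inherits(spec, "fibril_spec"))
  lat <- fibril_lattice(spec$arrangement)
  g <- GLYCAN_GEOM$twofold
  tabs <- lapply(seq_len(nrow(lat)), function(k) {
    a <- build_glycan_chain(spec$dp, "GLC", g$twist, g$rise, g$dx, g$gamma,
                            chain_id = k, tilt_x = g$tilt_x,
                            tilt_y = g$tilt_y)
    a$x <- a$x + lat$x[k]; a$y <- a$y + lat$y[k]; a$z <- a$z + lat$z[k]
    a
  })
  atoms <- do.call(rbind, tabs)
  scw_structure(atoms)
}

#' Decorated xylan specification
#'
#' Default: DP-40 beta(1->4) xylan, acetylated on O2 of every other xylose
#' and carrying a glucuronosyl (GlcA) unit on O2 every 8 residues; when O2
#' is occupied by GlcA the acetyl moves to O3. All decorations sit on
#' even-numbered residues counted from the reducing end, so a twofold chain
#' carries them all on one face.
#'
#' @param dp xylose units (default 40).
#' @param acetyl_period acetylation period (default 2).
#' @param glca_period GlcA period (default 8).
#' @param glca_phase first GlcA-bearing residue, one of 2, 4, 6, 8.
#' @param conformation "twofold" (2_1), "threefold" (3_1) or "disordered"
#'   (randomized glycosidic twists; a synthetic stand-in for unbound xylan).
#' @return an `xylan_spec` list.
#' @export
xylan_spec <- function(dp = 40L, acetyl_period = 2L, glca_period = 8L,
                       glca_phase = 2L,
                       conformation = c("twofold", "threefold", "disordered")) {
  conformation <- match.arg(conformation)
  if (glca_phase %% 2 != 0)
    stop("glca_phase must be even: decorations sit on even residues only")
  structure(list(dp = as.integer(dp), acetyl_period = as.integer(acetyl_period),
                 glca_period = as.integer(glca_period),
                 glca_phase = as.integer(glca_phase),
                 conformation = conformation),
            class = "xylan_spec")
}

#' Build a decorated xylan chain
#'
#' @param spec an [xylan_spec()].
#' @param chain_id chain identifier for the emitted atoms.
#' @param seed RNG seed; used only for the "disordered" conformation.
#' @return an `scw_structure`.
#' @export
build_xylan <- function(spec = xylan_spec(), chain_id = 1L, seed = 1L) {
  stopifnot(inherits(spec, "xylan_spec"))
  dp <- spec$dp
  if (spec$conformation == "disordered") {
    g <- GLYCAN_GEOM$threefold
    twists <- with_seed(seed, runif(dp, -180, 180))
    atoms <- build_glycan_chain(dp, "XYL", twists, g$rise, g$dx, g$gamma,
                                chain_id, tilt_x = g$tilt_x,
                                tilt_y = g$tilt_y)
  } else {
    g <- GLYCAN_GEOM[[spec$conformation]]
    atoms <- build_glycan_chain(dp, "XYL", g$twist, g$rise, g$dx, g$gamma,
                                chain_id, tilt_x = g$tilt_x,
                                tilt_y = g$tilt_y)
  }
  ace_res <- if (spec$acetyl_period <= dp)
    seq(spec$acetyl_period, dp, by = spec$acetyl_period) else integer()
  glca_res <- if (spec$glca_phase <= dp)
    seq(spec$glca_phase, dp, by = spec$glca_period) else integer()
  deco <- list()
  for (j in glca_res) {
    o2 <- atoms[atoms$residue_index == j & atoms$atom_label == "O2", ]
    c2 <- atoms[atoms$residue_index == j & atoms$atom_label == "C2", ]
    dir <- unitv(c(o2$x - c2$x, o2$y - c2$y, o2$z - c2$z))
    deco[[length(deco) + 1L]] <-
      glca_atoms(c(o2$x, o2$y, o2$z), dir, j, chain_id)
  }
  for (j in ace_res) {
    olab <- if (j %in% glca_res) "O3" else "O2"
    clab <- sub("O", "C", olab)
    oa <- atoms[atoms$residue_index == j & atoms$atom_label == olab, ]
    ca <- atoms[atoms$residue_index == j & atoms$atom_label == clab, ]
    dir <- unitv(c(oa$x - ca$x, oa$y - ca$y, oa$z - ca$z))
    deco[[length(deco) + 1L]] <-
      acetyl_atoms(c(oa$x, oa$y, oa$z), dir, j, chain_id)
  }
  atoms <- do.call(rbind, c(list(atoms), deco))
  scw_structure(atoms)
}

#' Lignin 20-mer specification
#'
#' Defaults follow the hardwood 20-mer scheme: 13 syringyl + 7 guaiacyl
#' units (S:G = 65:35) joined by 19 inter-unit linkages with 80%
#' beta-O-4 content; the minor linkages split the remaining 20% as
#' beta-beta 10%, beta-5 6%, 5-5 2%, 4-O-5 2% (configurable).
#'
#' @param n_monomers chain length (default 20).
#' @param n_syringyl,n_guaiacyl monomer counts; must sum to `n_monomers`.
#' @param linkage_fractions named fractions over linkage types, summing to 1.
#' @param shape "extended" or "globular".
#' @return a `lignin_spec` list.
#' @export
lignin_spec <- function(n_monomers = 20L, n_syringyl = 13L, n_guaiacyl = 7L,
                        linkage_fractions = c("beta-O-4" = 0.80,
                                              "beta-beta" = 0.10,
                                              "beta-5" = 0.06,
                                              "5-5" = 0.02,
                                              "4-O-5" = 0.02),
                        shape = c("extended", "globular")) {
  shape <- match.arg(shape)
  if (n_syringyl + n_guaiacyl != n_monomers)
    stop("n_syringyl + n_guaiacyl must equal n_monomers")
  if (abs(sum(linkage_fractions) - 1) > 1e-8)
    stop("linkage fractions must sum to 1")
  structure(list(n_monomers = as.integer(n_monomers),
                 n_syringyl = as.integer(n_syringyl),
                 n_guaiacyl = as.integer(n_guaiacyl),
                 linkage_fractions = linkage_fractions, shape = shape),
            class = "lignin_spec")
}

# Monolignol heavy-atom template: planar aromatic ring in the zx-plane
# (C1 up, C4 down), phenoxy O4 below C4 (the inter-unit attachment point),
# propanoid sidechain (CA, CB, CG + hydroxyls OA, OG) above C1 with CB the
# donor atom of the inter-unit bond, and methoxyls on C3 (G, S) and C5 (S).
# Ring carbons are labelled S1..S6 / G1..G6 so the ssNMR source carbons
# (S3, S5, G3, G4) are directly addressable.
lignin_monomer_template <- function(unit = c("S", "G")) {
  unit <- match.arg(unit)
  r <- 1.40
  ang <- (0:5) * 60 * pi / 180
  pos <- cbind(x = r * sin(ang), y = 0, z = r * cos(ang))
  rownames(pos) <- paste0(unit, 1:6)
  add <- function(m, label, xyz) rbind(m, matrix(xyz, 1, 3,
                                                 dimnames = list(label)))
  pos <- add(pos, "O4", c(0, 0, -2.76))
  pos <- add(pos, "CA", c(0.62, 0, 2.75))
  pos <- add(pos, "OA", c(2.00, 0, 3.15))
  pos <- add(pos, "CB", c(0.35, 0, 4.14))
  # gamma carbon branches sideways off CB (the chain axis continues to the
  # next unit's O4 through CB)
  pos <- add(pos, "CG", c(-0.64, 0.99, 3.81))
  pos <- add(pos, "OG", c(-1.78, 1.85, 3.81))
  elem <- c(rep("C", 6), "O", "C", "O", "C", "C", "O")
  pos <- add(pos, "O3M", c(2.39, 0, -1.38))
  pos <- add(pos, "OMe3", c(3.63, 0, -2.10))
  elem <- c(elem, "O", "C")
  if (unit == "S") {
    pos <- add(pos, "O5M", c(-2.39, 0, -1.38))
    pos <- add(pos, "OMe5", c(-3.63, 0, -2.10))
    elem <- c(elem, "O", "C")
  }
  list(pos = pos, elem = elem)
}

# Spacing between consecutive monomer frames so that the CB(i) -> O4(i+1)
# inter-unit bond has length B_CO (next unit is flipped 180 deg about z, so
# its O4 local x negates).
lignin_step <- function() {
  cb <- c(0.35, 0, 4.14); o4 <- c(0, 0, -2.76)
  # |(cb - (-o4x, -o4y, o4z + L))| = B_CO with o4 x=y=0
  (cb[3] - o4[3]) + sqrt(B_CO^2 - cb[1]^2)
}

#' Build a lignin 20-mer
#'
#' Monomers are placed sequentially with an idealized inter-unit bond
#' geometry shared by all linkage types (the type list is bookkeeping for
#' composition statistics; detailed linkage stereochemistry is not
#' modeled). The extended shape is a straight rod; the globular shape bends
#' the growth direction randomly at each junction under a self-avoidance
#' check (reject-and-retry, seeded).
#'
#' @param spec a [lignin_spec()].
#' @param seed integer RNG seed; same seed gives a bit-identical chain.
#' @param chain_id chain identifier.
#' @param n_beta_o4 number of beta-O-4 linkages to realize in this chain;
#'   default `round(0.8 * (n_monomers - 1))`. [build_lignin_ensemble()]
#'   balances these integers so an ensemble hits the target fraction
#'   exactly.
#' @return list with elements `structure` (an `scw_structure`) and
#'   `linkages` (data.frame: from, to, type).
#' @export
build_lignin <- function(spec = lignin_spec(), seed = 1L, chain_id = 1L,
                         n_beta_o4 = NULL) {
  stopifnot(inherits(spec, "lignin_spec"))
  n <- spec$n_monomers
  nl <- n - 1L
  fr <- spec$linkage_fractions
  if (is.null(n_beta_o4)) n_beta_o4 <- round(fr[["beta-O-4"]] * nl)
  n_beta_o4 <- min(n_beta_o4, nl)
  L <- lignin_step()
  res <- with_seed(seed, {
    units <- sample(c(rep("S", spec$n_syringyl), rep("G", spec$n_guaiacyl)))
    minor <- setdiff(names(fr), "beta-O-4")
    wts <- fr[minor]
    types <- character(nl)
    if (nl > 0) {
      bo4_at <- sort(sample.int(nl, n_beta_o4))
      types[bo4_at] <- "beta-O-4"
      rest <- setdiff(seq_len(nl), bo4_at)
      if (length(rest) > 0)
        types[rest] <- if (sum(wts) > 0)
          sample(minor, length(rest), replace = TRUE, prob = wts)
        else "beta-O-4"
    }
    tpls <- lapply(c(S = "S", G = "G"), lignin_monomer_template)
    frames_R <- vector("list", n); origins <- vector("list", n)
    frames_R[[1]] <- diag(3); origins[[1]] <- c(0, 0, 0)
    placed <- NULL
    atom_sets <- vector("list", n)
    place_unit <- function(i, R, o) {
      tp <- tpls[[units[i]]]
      p <- t(R %*% t(tp$pos))
      sweep(p, 2, o, "+")
    }
    atom_sets[[1]] <- place_unit(1, frames_R[[1]], origins[[1]])
    placed <- atom_sets[[1]]
    for (i in seq_len(n - 1)) {
      Rbase <- frames_R[[i]] %*% rotz(180)
      obase <- origins[[i]] + drop(frames_R[[i]] %*% c(0, 0, L))
      pivot <- obase + drop(Rbase %*% c(0, 0, -2.76)) # the new unit's O4
      if (spec$shape == "extended") {
        Rnew <- Rbase; onew <- obase
      } else {
        best <- NULL; best_clash <- Inf
        for (try in seq_len(60)) {
          axis <- unitv(rnorm(3))
          theta <- runif(1, 30, 100) * pi / 180
          K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                        -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
          Rr <- diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
          Rc <- Rr %*% Rbase
          oc <- drop(Rr %*% (obase - pivot)) + pivot
          # bias the walk back toward the chain origin for compactness
          cand <- place_unit(i + 1, Rc, oc)
          dmin <- min_cross_distance(cand, placed, skip = c("O4", "C4"))
          ctr_pen <- sqrt(sum((oc - c(0, 0, 0))^2))
          score <- ifelse(dmin >= MIN_CONTACT, ctr_pen, 1e4 - dmin)
          if (score < best_clash) {
            best_clash <- score; best <- list(R = Rc, o = oc)
          }
          if (dmin >= MIN_CONTACT && ctr_pen < 3.5 * L) break
        }
        Rnew <- best$R; onew <- best$o
      }
      frames_R[[i + 1]] <- Rnew; origins[[i + 1]] <- onew
      atom_sets[[i + 1]] <- place_unit(i + 1, Rnew, onew)
      placed <- rbind(placed, atom_sets[[i + 1]])
    }
    tabs <- lapply(seq_len(n), function(i) {
      tp <- tpls[[units[i]]]
      p <- atom_sets[[i]]
      atom_table(tp$elem, rownames(tp$pos), i,
                 if (units[i] == "S") "SYR" else "GUA", chain_id,
                 p[, 1], p[, 2], p[, 3])
    })
    list(atoms = do.call(rbind, tabs),
         linkages = if (nl > 0) data.frame(from = seq_len(nl),
                                           to = seq_len(nl) + 1L,
                                           type = types,
                                           stringsAsFactors = FALSE)
                    else data.frame(from = integer(), to = integer(),
                                    type = character()))
  })
  list(structure = scw_structure(res$atoms), linkages = res$linkages)
}

# Minimum distance between a candidate atom block and placed atoms,
# ignoring rows of `cand` whose label is in `skip` (the linkage
# neighborhood that is legitimately close to the previous unit).
min_cross_distance <- function(cand, placed, skip = character()) {
  keep <- !(rownames(cand) %in% skip)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0 || is.null(placed) || nrow(placed) == 0) return(Inf)
  d <- min_dist_to_set_cpp(cand, placed, 50, c(1, 1, 1), FALSE)
  min(d)
}

#' Build a balanced lignin ensemble
#'
#' Distributes integer beta-O-4 counts across chains by largest remainder,
#' so that whenever the requested fraction times the total linkage count is
#' an integer (e.g. the default 80% over any multiple of 5 chains of
#' 20-mers) the ensemble composition is exact.
#'
#' @param n_chains number of chains.
#' @param spec a [lignin_spec()].
#' @param seed base seed; chain k uses `seed + k`.
#' @param globular_fraction fraction of chains built globular (placed last).
#' @return list of [build_lignin()] results.
#' @export
build_lignin_ensemble <- function(n_chains, spec = lignin_spec(), seed = 1L,
                                  globular_fraction = 0) {
  nl <- spec$n_monomers - 1L
  total <- round(spec$linkage_fractions[["beta-O-4"]] * n_chains * nl)
  base <- total %/% n_chains
  extra <- total - base * n_chains
  # spread the +1 chains evenly across the ensemble
  plus <- if (extra > 0) round(seq(1, n_chains, length.out = extra)) else integer()
  n_glob <- round(globular_fraction * n_chains)
  lapply(seq_len(n_chains), function(k) {
    sp <- spec
    sp$shape <- if (k > n_chains - n_glob) "globular" else "extended"
    build_lignin(sp, seed = seed + k, chain_id = k,
                 n_beta_o4 = base + (k %in% plus))
  })
}
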