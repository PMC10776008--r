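# Xylan conformational metrics: glycosidic phi+psi sums, the
# acetate-orientation dihedral theta2f between consecutive acetylated
# xyloses, and cellulose-bound/unbound chain classification.

# Fetch one atom's coordinates from a chain's residue, or NULL when absent.
res_atom <- function(a, res, label) {
  i <- which(a$residue_index == res & a$atom_label == label &
             a$residue_type %in% c("XYL", "GLC"))
  if (length(i) == 0) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

#' Glycosidic phi + psi sums along a glycan chain
#'
#' For each adjacent residue pair (i, i+1) of a beta(1->4) glycan the
#' torsions are computed over heavy atoms with the convention
#' phi = O5(i+1)-C1(i+1)-O4(i)-C4(i) and psi = C1(i+1)-O4(i)-C4(i)-C5(i),
#' and their sum is folded into (-180, 180]. The twofold (2_1) screw is the
#' ~+120 deg anchor; the threefold (3_1) regime lies near ~50 or ~190 deg.
#'
#' @param s an `scw_structure`.
#' @param chain chain id of a glycan chain.
#' @return a `torsion_series` list: chain_id, metric, residue pairs, phi,
#'   psi and values (the folded sums, degrees). Pairs with missing atoms
#'   are skipped (recorded in `skipped`).
#' @export
phi_psi_sum <- function(s, chain) {
  a <- s$atoms[s$atoms$chain_id == chain, ]
  back <- sort(unique(a$residue_index[a$residue_type %in% c("XYL", "GLC")]))
  pairs <- list(); phi <- psi <- vals <- numeric(); skipped <- integer()
  for (j in back[(back + 1) %in% back]) {
    O5n <- res_atom(a, j + 1, "O5"); C1n <- res_atom(a, j + 1, "C1")
    O4 <- res_atom(a, j, "O4"); C4 <- res_atom(a, j, "C4")
    C5 <- res_atom(a, j, "C5")
    if (is.null(O5n) || is.null(C1n) || is.null(O4) || is.null(C4) ||
        is.null(C5)) {
      skipped <- c(skipped, j)
      next
    }
    ph <- dihedral_angle(O5n, C1n, O4, C4)
    ps <- dihedral_angle(C1n, O4, C4, C5)
    pairs[[length(pairs) + 1L]] <- c(j, j + 1)
    phi <- c(phi, ph); psi <- c(psi, ps)
    vals <- c(vals, fold_angle(ph + ps))
  }
  if (length(skipped))
    message(sprintf("phi_psi_sum: skipped %d residue pairs with missing atoms",
                    length(skipped)))
  structure(list(chain_id = chain, metric = "phi_psi_sum",
                 pairs = do.call(rbind, pairs), phi = phi, psi = psi,
                 values = vals, skipped = skipped),
            class = "torsion_series")
}

#' Acetate-orientation dihedral between consecutive acetylated xyloses
#'
#' For each adjacent pair of acetylated xylose residues (i, j) along a
#' chain (j the next acetylated residue, normally i+2 since acetyls sit on
#' alternating residues), computes the dihedral through the acetate-bound
#' oxygen of i, C5 of i, C5 of j and the acetate-bound oxygen of j. The
#' acetate-bound oxygen is O2 unless the residue also carries a GlcA on O2,
#' in which case its acetyl (and this dihedral) uses O3. A value near 0 deg
#' means consecutive acetates point the same way (the twofold, one-face
#' arrangement); disordered chains spread over the full circle.
#'
#' @param s an `scw_structure`.
#' @param chain chain id of a xylan chain.
#' @return a `torsion_series`; empty when fewer than 2 acetylated residues.
#' @export
theta_2f <- function(s, chain) {
  a <- s$atoms[s$atoms$chain_id == chain, ]
  ace_res <- sort(unique(a$residue_index[a$residue_type == "ACE"]))
  glca_res <- unique(a$residue_index[a$residue_type == "GLCA"])
  empty <- structure(list(chain_id = chain, metric = "theta_2f",
                          pairs = NULL, values = numeric()),
                     class = "torsion_series")
  if (length(ace_res) < 2) return(empty)
  olab <- ifelse(ace_res %in% glca_res, "O3", "O2")
  pairs <- list(); vals <- numeric()
  for (k in seq_len(length(ace_res) - 1)) {
    i <- ace_res[k]; j <- ace_res[k + 1]
    Oi <- res_atom(a, i, olab[k]); Ci <- res_atom(a, i, "C5")
    Cj <- res_atom(a, j, "C5"); Oj <- res_atom(a, j, olab[k + 1])
    if (is.null(Oi) || is.null(Ci) || is.null(Cj) || is.null(Oj)) next
    pairs[[length(pairs) + 1L]] <- c(i, j)
    vals <- c(vals, dihedral_angle(Oi, Ci, Cj, Oj))
  }
  structure(list(chain_id = chain, metric = "theta_2f",
                 pairs = do.call(rbind, pairs), values = vals),
            class = "torsion_series")
}

#' @export
print.torsion_series <- function(x, ...) {
  cat(sprintf("<torsion_series> %s, chain %d, %d values\n", x$metric,
              x$chain_id, length(x$values)))
  if (length(x$values))
    cat(sprintf("  mean %.1f deg, circular sd %.1f deg\n",
                mean(x$values), circular_sd(x$values)))
  invisible(x)
}

# Circular standard deviation (degrees); appropriate for angle spreads.
circular_sd <- function(deg) {
  th <- deg * pi / 180
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  sqrt(-2 * log(max(R, 1e-12))) * 180 / pi
}

# Circular mean (degrees, (-180, 180]).
circular_mean <- function(deg) {
  th <- deg * pi / 180
  fold_angle(atan2(mean(sin(th)), mean(cos(th))) * 180 / pi)
}

#' Classify a xylan chain as cellulose-bound or unbound
#'
#' A chain counts as bound when at least half of its backbone residues have
#' any heavy atom within `cutoff` (default 4.5 A) of a cellulose atom
#' (minimum image when periodic). The per-chain contact fraction is
#' returned alongside the verdict; both thresholds are configurable.
#'
#' @param s an `scw_structure` containing cellulose.
#' @param chain xylan chain id.
#' @param cutoff heavy-atom contact distance, Angstrom.
#' @param majority residue fraction required for "bound" (default 0.5).
#' @return list: `bound` (logical), `contact_fraction`, `cutoff`.
#' @export
classify_bound <- function(s, chain, cutoff = 4.5, majority = 0.5) {
  cel <- s$atoms[s$atoms$polymer_class == "cellulose", ]
  if (nrow(cel) == 0) stop("no cellulose in structure")
  xy <- s$atoms[s$atoms$chain_id == chain & s$atoms$residue_type == "XYL", ]
  if (nrow(xy) == 0) stop("chain ", chain, " has no xylose backbone")
  box <- if (s$periodic) as.numeric(s$box) else c(1, 1, 1)
  d <- min_dist_to_set_cpp(as.matrix(xy[, c("x", "y", "z")]),
                           as.matrix(cel[, c("x", "y", "z")]),
                           cutoff + 1e-9, box, s$periodic)
  contact <- tapply(d < cutoff, xy$residue_index, any)
  frac <- mean(contact)
  list(bound = frac >= majority, contact_fraction = frac, cutoff = cutoff)
}
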