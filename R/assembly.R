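# Whole-SCW assembly: packing scenarios, compression to target density,
# solvation and neutralization.
#
# All chains are built with their long axis along z and the periodic box z
# edge equals the glycan repeat (dp * 5.19 A), so cellulose chains continue
# seamlessly across the boundary. Compression therefore scales the
# cross-section (x, y) only; see the methods vignette for why this
# replaces an isotropic shrink.

# Scenario letter <-> construction-protocol roman numeral mapping.
# This table is the single source of truth; the two naming systems in the
# source material do not align one-to-one ("h" is defined by the figure
# naming: hemicellulose interspersed within the fibril cluster).
SCENARIO_TABLE <- data.frame(
  scenario = c("a", "b", "c", "b.8", "b.10", "f", "g", "h", "e", "d"),
  roman    = c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x"),
  n_fibrils = c(4, 4, 4, 8, 10, 4, 4, 4, 4, 4),
  bound_fraction   = c(1.0, 0.7, 0.0, 0.6, 0.6, 0.7, 0.6, 0.0, 0.0, 0.0),
  trapped_fraction = c(0.0, 0.0, 0.0, 0.1, 0.1, 0.0, 0.1, 1.0, 0.0, 0.0),
  lignin_globular_fraction = c(0, 0, 0, 0, 0, 0.3, 0.3, 0, 0, 0),
  xylan_conformation = c("twofold", "twofold", "twofold", "twofold",
                         "twofold", "twofold", "twofold", "twofold",
                         "threefold", "threefold"),
  lignin_on_cellulose = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                          FALSE, FALSE, TRUE),
  phase_separated = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

# Default matrix-polymer counts: 30 xylan / 58 lignin for four fibrils,
# 116 lignin for eight and 145 for ten; xylan for the larger systems is
# scaled to preserve the four-fibril xylan:lignin ratio.
default_counts <- function(n_fibrils) {
  if (n_fibrils <= 4) list(n_xylan = 30L, n_lignin = 58L)
  else if (n_fibrils <= 8) list(n_xylan = 60L, n_lignin = 116L)
  else list(n_xylan = 75L, n_lignin = 145L)
}

#' Packing-scenario specification
#'
#' @param scenario scenario name: one of a..h, b.8, b.10 (figure naming) or
#'   a roman numeral i..x (protocol naming); see `SCENARIO_TABLE`.
#' @param n_fibrils,n_xylan,n_lignin counts; defaults depend on scenario.
#' @param bound_fraction,trapped_fraction fractions of xylan bound on
#'   cellulose surfaces / trapped between fibril bundles; the remainder is
#'   interspersed in the matrix. Defaults per scenario.
#' @param target_density compression target, g/cm^3 (default 1.5).
#' @param moisture solvation target, mass % water (default 3).
#' @param dp degree of polymerization of the glycans (default 40; smaller
#'   values give fast toy systems for testing).
#' @param seed integer seed controlling all stochastic placement.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(scenario = "a", n_fibrils = NULL, n_xylan = NULL,
                          n_lignin = NULL, bound_fraction = NULL,
                          trapped_fraction = NULL, target_density = 1.5,
                          moisture = 3, dp = 40L, seed = 1L) {
  row <- SCENARIO_TABLE[SCENARIO_TABLE$scenario == scenario |
                        SCENARIO_TABLE$roman == scenario, ]
  if (nrow(row) != 1) stop("unknown scenario: ", scenario)
  if (is.null(n_fibrils)) n_fibrils <- row$n_fibrils
  cnt <- default_counts(n_fibrils)
  if (is.null(n_xylan)) n_xylan <- cnt$n_xylan
  if (is.null(n_lignin)) n_lignin <- cnt$n_lignin
  if (is.null(bound_fraction)) bound_fraction <- row$bound_fraction
  if (is.null(trapped_fraction)) trapped_fraction <- row$trapped_fraction
  if (bound_fraction + trapped_fraction > 1 + 1e-9)
    stop("bound + trapped fractions exceed 1")
  if (n_xylan < 0 || n_lignin < 0 || n_fibrils < 0) stop("counts must be >= 0")
  structure(list(
    scenario = row$scenario, roman = row$roman,
    n_fibrils = as.integer(n_fibrils), n_xylan = as.integer(n_xylan),
    n_lignin = as.integer(n_lignin),
    bound_fraction = bound_fraction, trapped_fraction = trapped_fraction,
    lignin_globular_fraction = row$lignin_globular_fraction,
    xylan_conformation = row$xylan_conformation,
    lignin_on_cellulose = row$lignin_on_cellulose,
    phase_separated = row$phase_separated,
    target_density = target_density, moisture = moisture,
    dp = as.integer(dp), seed = as.integer(seed)), class = "scenario_spec")
}

# Fibril cluster centers (x, y). Four fibrils form a 2 x 2 core with
# ~25 A center-to-center spacing along the thin (sheet-stacking) direction.
# Eight = two 2x2 bundles with a gap for trapped xylan; ten = 2 x 5 with
# widened columns; "wide" spreads fibrils apart so xylan fits between them.
cluster_centers <- function(n_fibrils, arrangement = c(2, 3, 4, 4, 3, 2),
                            wide = FALSE) {
  w <- (max(arrangement) - 1) * IB_CHAIN_SPACING + 11   # fibril x footprint
  dy <- if (wide) 39 else 25
  dxf <- if (wide) w + 14 else w + 2.5
  if (n_fibrils <= 4) {
    nx <- ceiling(n_fibrils / 2)
    g <- expand.grid(ix = seq_len(nx), iy = 1:2)[seq_len(n_fibrils), ]
    cbind(x = (g$ix - (nx + 1) / 2) * dxf, y = (g$iy - 1.5) * dy)
  } else if (n_fibrils == 8) {
    bundle <- cbind(x = rep(c(-dxf / 2, dxf / 2), 2),
                    y = rep(c(-dy / 2, dy / 2), each = 2))
    gap <- 30 # inter-bundle gap hosting trapped xylan
    rbind(sweep(bundle, 2, c(-(dxf + gap / 2 + w / 2 - dxf / 2), 0), "+"),
          sweep(bundle, 2, c((dxf + gap / 2 + w / 2 - dxf / 2), 0), "+"))
  } else {
    nx <- ceiling(n_fibrils / 2)
    g <- expand.grid(ix = seq_len(nx), iy = 1:2)[seq_len(n_fibrils), ]
    cbind(x = (g$ix - (nx + 1) / 2) * (w + 16), y = (g$iy - 1.5) * dy)
  }
}

# Surface slots on the exterior of the placed cellulose: positions (absolute
# xy) + outward normals for laying chains onto the fibril surface. Slots
# drape over the actual surface-height profile (the fibril cross-sections
# are diamonds, so flat faces would leave shoulder positions floating):
# for each lateral station the slot sits `offset` beyond the outermost
# cellulose atom within a +-4 A window. Stations with no cellulose in the
# window (e.g. over the inter-bundle gap) are skipped. Placement nudges
# chains outward until the 1.8 A steric floor is respected, leaving
# van-der-Waals-like contact.
surface_slots <- function(cel_m, offset = 1.5, spacing = 6.5) {
  xr <- range(cel_m[, 1]); yr <- range(cel_m[, 2])
  station <- function(along, lo, hi) {
    if (hi - lo > 8) seq(lo + 4, hi - 4, by = spacing) else mean(c(lo, hi))
  }
  face <- function(axis, sign) {
    # axis 1: slots along x probing y (top/bottom); axis 2: the reverse
    at <- if (axis == 1) station(1, xr[1], xr[2]) else station(2, yr[1], yr[2])
    out <- lapply(at, function(u) {
      sel <- abs(cel_m[, axis] - u) < 4
      if (!any(sel)) return(NULL)
      probe <- cel_m[sel, 3 - axis]
      edge <- if (sign > 0) max(probe) else min(probe)
      if (axis == 1) c(x = u, y = edge + sign * offset, nx = 0, ny = sign)
      else c(x = edge + sign * offset, y = u, nx = sign, ny = 0)
    })
    do.call(rbind, out)
  }
  rbind(face(1, 1), face(1, -1), face(2, 1), face(2, -1))
}

# Rotate a built chain about z so its decoration face (mean radial direction
# of acetyl methyl carbons, falling back to O2) points along `normal`.
orient_decorations <- function(s, normal) {
  a <- s$atoms
  sel <- a$atom_label == "AcMe"
  if (!any(sel)) sel <- a$atom_label == "O2"
  ctr <- c(mean(a$x), mean(a$y))
  v <- c(mean(a$x[sel]) - ctr[1], mean(a$y[sel]) - ctr[2])
  if (sqrt(sum(v^2)) < 1e-6) return(s)
  ang <- (atan2(normal[2], normal[1]) - atan2(v[2], v[1])) * 180 / pi
  rotate_structure_z(s, ang, origin = c(ctr, 0))
}

#' Assemble a whole-SCW periodic model under a packing scenario
#'
#' Fibrils are placed first (clustered core, with trapped xylan between
#' bundles/fibrils where the scenario asks for it), bound xylan is laid on
#' the exterior fibril surfaces in twofold conformation with the decorated
#' face outward, and the remaining xylan plus all lignin are placed
#' randomly (seeded) in the surrounding volume, rejecting any placement
#' with heavy-atom contacts under 1.8 A. Scenario d lays lignin on the
#' cellulose and keeps xylan in an outer shell; scenario e phase-separates
#' xylan (top half) from lignin (bottom half); scenario h widens the fibril
#' cluster and intersperses the xylan inside it.
#'
#' @param spec a [scenario_spec()].
#' @param max_tries placement attempts per matrix chain before erroring.
#' @return list with `structure` (periodic `scw_structure`) and `report`
#'   (assembly bookkeeping: counts, mass, box, density).
#' @export
assemble_scenario <- function(spec = scenario_spec(), max_tries = 400L) {
  stopifnot(inherits(spec, "scenario_spec"))
  dp <- spec$dp
  boxz <- dp * IB_RISE
  arrangement <- c(2, 3, 4, 4, 3, 2)
  fib <- build_cellulose_fibril(fibril_spec(dp = dp))
  fw <- max(fib$atoms$x) - min(fib$atoms$x)
  fh <- max(fib$atoms$y) - min(fib$atoms$y)
  centers <- cluster_centers(spec$n_fibrils, arrangement,
                             wide = (spec$scenario == "h"))

  n_trap <- round(spec$trapped_fraction * spec$n_xylan)
  n_bound <- round(spec$bound_fraction * spec$n_xylan)
  n_matrix_x <- spec$n_xylan - n_trap - n_bound
  if (n_matrix_x < 0) stop("bound + trapped xylan exceed n_xylan")

  # polymer inventories -----------------------------------------------------
  phase_cycle <- c(2L, 4L, 6L, 8L)
  xychains <- lapply(seq_len(spec$n_xylan), function(k) {
    conf <- if (k <= n_trap + n_bound) "twofold" else spec$xylan_conformation
    build_xylan(xylan_spec(dp = dp, glca_phase = phase_cycle[(k - 1) %% 4 + 1],
                           conformation = conf),
                chain_id = 1L, seed = spec$seed + 1000L + k)
  })
  lchains <- if (spec$n_lignin > 0)
    build_lignin_ensemble(spec$n_lignin, lignin_spec(), seed = spec$seed + 5000L,
                          globular_fraction = spec$lignin_globular_fraction)
  else list()

  # box size: cluster footprint plus an annulus sized for the matrix mass at
  # a loose initial packing density (compression tightens it later)
  matrix_mass <- sum(vapply(xychains, structure_mass, 0)) +
    sum(vapply(lchains, function(l) structure_mass(l$structure), 0))
  a_cluster <- (diff(range(centers[, 1])) + fw + 20) *
               (diff(range(centers[, 2])) + fh + 20)
  rho_place <- 0.18 # g/cm^3 in the matrix annulus at initial placement
  a_total <- a_cluster + matrix_mass * 1.10703 / (rho_place * boxz)
  side <- max(sqrt(a_total),
              diff(range(centers[, 1])) + fw + 26,
              diff(range(centers[, 2])) + fh + 26)
  box <- c(side, side, boxz)
  ctr <- c(side / 2, side / 2)

  placed <- list(); coords_acc <- NULL
  report_counts <- list()
  add_placed <- function(s) {
    placed[[length(placed) + 1L]] <<- s
    coords_acc <<- rbind(coords_acc, coords_matrix(s))
  }
  clashes <- function(m) {
    if (is.null(coords_acc)) 0L
    else count_clashes_cpp(coords_acc, m, MIN_CONTACT, box, TRUE, 1L)
  }

  # 1. fibrils --------------------------------------------------------------
  for (i in seq_len(spec$n_fibrils))
    add_placed(translate_structure(fib, c(ctr[1] + centers[i, 1],
                                          ctr[2] + centers[i, 2], boxz - 1)))

  # 2. trapped xylan between bundles / fibrils ------------------------------
  xq <- 1L
  if (n_trap > 0) {
    gaps <- trapped_sites(centers, fw, fh, n_trap, spec$n_fibrils)
    for (g in seq_len(n_trap)) {
      s <- orient_decorations(xychains[[xq]], c(0, 1))
      s <- center_chain_xy(s)
      s <- translate_structure(s, c(ctr[1] + gaps[g, 1], ctr[2] + gaps[g, 2],
                                    boxz - 1))
      if (clashes(coords_matrix(s)) > 0)
        stop("trapped xylan placement clashes; widen the cluster")
      add_placed(s)
      xq <- xq + 1L
    }
  }

  # 3. chains bound on the cellulose surface --------------------------------
  cel_m <- coords_acc # cellulose (and trapped xylan) placed so far
  n_lig_bound <- if (spec$lignin_on_cellulose && spec$n_lignin > 0)
    spec$n_lignin else 0L
  bound_assign <- if (n_bound > 0 || n_lig_bound > 0) {
    slots <- surface_slots(cel_m)
    n_lig_bound <- min(n_lig_bound, nrow(slots))
    if (nrow(slots) < n_bound)
      stop(sprintf("only %d surface slots for %d bound chains", nrow(slots),
                   n_bound))
    with_seed(spec$seed + 77L, slots[sample.int(nrow(slots)), , drop = FALSE])
  }
  if (n_bound > 0) {
    for (g in seq_len(n_bound)) {
      sl <- bound_assign[g, ]
      s <- orient_decorations(xychains[[xq]], c(sl["nx"], sl["ny"]))
      s <- center_chain_xy(s)
      s <- translate_structure(s, c(sl["x"], sl["y"], boxz - 1))
      s <- nudge_until_clear(s, c(sl["nx"], sl["ny"], 0), box, coords_acc)
      add_placed(s)
      xq <- xq + 1L
    }
  }
  lq <- 1L
  if (n_lig_bound > 0) {
    for (g in seq_len(n_lig_bound)) {
      sl <- bound_assign[g, ]
      s <- center_chain_xy(lchains[[lq]]$structure)
      s <- translate_structure(s, c(sl["x"], sl["y"], boxz / 2))
      s <- nudge_until_clear(s, c(sl["nx"], sl["ny"], 0), box, coords_acc)
      add_placed(s)
      lq <- lq + 1L
    }
  }

  # 4. randomly placed matrix chains ----------------------------------------
  # matrix polymers surround the fibril core: centers are rejected inside
  # the cluster footprint (which also keeps random lignin out of the
  # inter-bundle gaps that host trapped xylan)
  core_lo <- c(min(cel_m[, 1]), min(cel_m[, 2])) - 2
  core_hi <- c(max(cel_m[, 1]), max(cel_m[, 2])) + 2
  core_r <- max(sqrt((abs(centers[, 1]) + fw / 2)^2 +
                     (abs(centers[, 2]) + fh / 2)^2)) + 4
  region <- if (spec$lignin_on_cellulose) "shell" else "annulus"
  mat_specs <- c(
    rep(list(list(kind = "xylan")), n_matrix_x),
    lapply(seq_len(spec$n_lignin - n_lig_bound) + n_lig_bound,
           function(i) list(kind = "lignin", idx = i))
  )
  with_seed(spec$seed + 31L, {
    order_ix <- sample(seq_along(mat_specs))
    for (ix in order_ix) {
      ms <- mat_specs[[ix]]
      if (ms$kind == "xylan") {
        s0 <- center_chain_xy(xychains[[xq]]); xq <<- xq + 1L
        half <- "top"
      } else {
        s0 <- center_chain_xy(lchains[[ms$idx]]$structure)
        half <- "bottom"
      }
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        s <- rotate_structure_z(s0, runif(1, 0, 360))
        pos <- random_matrix_site(box, ctr, core_r,
                                  region = if (ms$kind == "xylan") region
                                           else "annulus",
                                  half = if (spec$phase_separated) half
                                         else NULL,
                                  core_lo = core_lo, core_hi = core_hi)
        s <- translate_structure(s, c(pos[1], pos[2], runif(1, 0, box[3])))
        m <- coords_matrix(wrap_structure(
          scw_structure(s$atoms, box = box)))
        if (clashes(m) == 0) {
          add_placed(set_coords(s, m)); ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf("could not place %s chain without steric overlap after %d tries (placed %d chains, box %.0f A)",
                     ms$kind, max_tries, length(placed), box[1]))
    }
  })

  out <- combine_structures(placed, box = box, periodic = TRUE)
  out <- wrap_structure(out)
  report <- assembly_report(out, spec, n_bound, n_trap, n_matrix_x,
                            n_lig_bound)
  list(structure = out, report = report)
}

# xy sites for trapped xylan: between the two bundles (8 fibrils), between
# columns (10), or inside the widened cluster (4, scenario h).
trapped_sites <- function(centers, fw, fh, n, n_fibrils) {
  ux <- sort(unique(round(centers[, 1], 3)))
  uy <- sort(unique(round(centers[, 2], 3)))
  if (n_fibrils == 8) {
    # midline between the two bundles
    xs <- mean(range(centers[, 1]))
    ys <- seq(min(uy) - fh / 3, max(uy) + fh / 3, length.out = max(n, 2))
    cbind(x = rep(c(xs - 4, xs + 4), length.out = n), y = ys[seq_len(n)])
  } else {
    # column midpoints x row midpoints inside the cluster
    xm <- if (length(ux) > 1) (head(ux, -1) + tail(ux, -1)) / 2 else ux
    ym <- if (length(uy) > 1) (head(uy, -1) + tail(uy, -1)) / 2 else uy
    g <- expand.grid(x = xm, y = c(ym, uy))
    g <- g[order(abs(g$y)), , drop = FALSE]
    if (nrow(g) < n) {
      extra <- expand.grid(x = xm + 5, y = c(ym, uy))
      g <- rbind(g, extra)
    }
    as.matrix(g[seq_len(n), , drop = FALSE])
  }
}

# Center a chain in xy on its backbone axis (glycan backbone or lignin
# units), so decorations extend outward from the placement point.
center_chain_xy <- function(s) {
  a <- s$atoms
  bb <- a$residue_type %in% c("XYL", "GLC", "SYR", "GUA")
  if (!any(bb)) bb <- rep(TRUE, nrow(a))
  translate_structure(s, c(-mean(range(a$x[bb])), -mean(range(a$y[bb])), 0))
}

# Push a surface-laid chain outward along `dir` until it clears existing
# atoms by MIN_CONTACT (keeps it as close to the surface as possible).
nudge_until_clear <- function(s, dir, box, coords_acc, step = 0.25,
                              max_steps = 150) {
  if (is.null(coords_acc)) return(s)
  for (i in seq_len(max_steps)) {
    if (count_clashes_cpp(coords_acc, coords_matrix(s), MIN_CONTACT, box,
                          TRUE, 1L) == 0) return(s)
    s <- translate_structure(s, dir * step)
  }
  stop("surface chain could not be cleared of steric overlap")
}

random_matrix_site <- function(box, ctr, core_r, region = "annulus",
                               half = NULL, core_lo = NULL,
                               core_hi = NULL) {
  for (i in seq_len(400)) {
    p <- c(runif(1, 0, box[1]), runif(1, 0, box[2]))
    if (!is.null(core_lo) &&
        all(p >= core_lo) && all(p <= core_hi)) next
    r <- sqrt(sum((p - ctr)^2))
    if (region == "shell" && r < core_r + 8) next
    if (!is.null(half)) {
      if (half == "top" && p[2] < ctr[2]) next
      if (half == "bottom" && p[2] >= ctr[2]) next
    }
    return(p)
  }
  stop("could not draw a matrix placement site outside the fibril core")
}

assembly_report <- function(s, spec, n_bound, n_trap, n_matrix_x,
                            n_lig_bound = 0L) {
  a <- s$atoms
  chains_by_class <- tapply(a$chain_id, a$polymer_class,
                            function(x) length(unique(x)))
  mass <- structure_mass(s)
  wat <- sum(a$residue_type == "WAT")
  structure(list(
    scenario = spec$scenario, roman = spec$roman, seed = spec$seed,
    n_fibrils = spec$n_fibrils,
    n_chains = as.list(chains_by_class),
    n_xylan_bound = n_bound, n_xylan_trapped = n_trap,
    n_xylan_matrix = n_matrix_x, n_lignin_bound = n_lig_bound,
    n_atoms = nrow(a), mass_da = mass, box = s$box,
    density = structure_density(s),
    moisture = 100 * wat * 18.015 / mass,
    counterions = sum(a$residue_type == "NA")
  ), class = "scw_assembly_report")
}

#' @export
print.scw_assembly_report <- function(x, ...) {
  cat(sprintf("<assembly report> scenario %s (%s), %d fibrils, seed %d\n",
              x$scenario, x$roman, x$n_fibrils, x$seed))
  cat(sprintf("  atoms %d, mass %.0f Da, box %.1f x %.1f x %.1f A\n",
              x$n_atoms, x$mass_da, x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  density %.3f g/cm^3, moisture %.2f%%, counterions %d\n",
              x$density, x$moisture, x$counterions))
  cat("  chains:", paste(sprintf("%s=%d", names(x$n_chains),
                                 unlist(x$n_chains)), collapse = ", "), "\n")
  cat(sprintf("  xylan: %d bound, %d trapped, %d matrix\n",
              x$n_xylan_bound, x$n_xylan_trapped, x$n_xylan_matrix))
  invisible(x)
}

#' Compress a periodic model to a target density
#'
#' The box cross-section is scaled down in small steps (0.99 per step) with
#' chains moved as rigid bodies (their centroids scale with the box, their
#' internal geometry is untouched) and a seeded steric relaxation after
#' each step pushes overlapping chains apart until no cross-chain
#' heavy-atom pair is closer than 1.8 A. The fiber-axis (z) dimension is
#' kept fixed because the glycan chains are built commensurate with it.
#'
#' @param s a periodic `scw_structure`.
#' @param target target density, g/cm^3.
#' @param seed seed for the relaxation jiggle.
#' @param max_relax relaxation iterations per shrink step.
#' @return the compressed `scw_structure` (density within 1% of target).
#' @export
compress_to_density <- function(s, target = 1.5, seed = 1L,
                                max_relax = 3000L) {
  if (!s$periodic) stop("compression requires a periodic structure")
  rho <- structure_density(s)
  if (abs(rho - target) <= 0.01 * target) return(s)
  if (rho > target)
    stop(sprintf("structure already denser (%.3f) than target %.3f", rho,
                 target))
  a <- s$atoms
  chain_of <- as.integer(factor(a$chain_id)) - 1L
  m <- coords_matrix(s)
  box <- s$box
  # Iteratively push overlapping chains apart (all three directions: the
  # chains are z-periodic, so sliding along the fiber axis is a legitimate
  # move that lets decorated rods interdigitate). Per-chain displacements
  # are capped; stagnation triggers a random kick.
  relax <- function(m, box) {
    best <- Inf; since_best <- 0L
    for (it in seq_len(max_relax)) {
      r <- chain_push_cpp(m, chain_of, MIN_CONTACT, box, TRUE)
      if (r$n_clash == 0) return(list(m = m, ok = TRUE))
      if (r$n_clash < best) { best <- r$n_clash; since_best <- 0L }
      else since_best <- since_best + 1L
      push <- r$push
      nrm <- sqrt(rowSums(push^2))
      scale <- ifelse(nrm > 0.8, 0.8 / nrm, 1)
      push <- push * scale
      kick <- if (since_best > 40) 0.4 else 0.04
      jig <- matrix(rnorm(length(push), 0, kick), nrow(push))
      if (since_best > 40) { best <- r$n_clash; since_best <- 0L }
      disp <- (push + jig)[chain_of + 1L, , drop = FALSE]
      m <- m + disp
      for (k in 1:3) m[, k] <- m[, k] - box[k] * floor(m[, k] / box[k])
    }
    list(m = m, ok = FALSE)
  }
  with_seed(seed, {
    repeat {
      rho <- structure_mass(s) * 1.66054 / prod(box)
      if (rho >= target * 0.99) break
      f <- 0.99
      # do not overshoot past +1%: land exactly on target if the next full
      # step would pass it
      if (structure_mass(s) * 1.66054 / (prod(box) * f * f) > target)
        f <- sqrt(structure_mass(s) * 1.66054 / (target * prod(box)))
      cents <- chain_centroids(m, chain_of)
      newc <- cents; newc[, 1:2] <- newc[, 1:2] * f
      disp <- (newc - cents)[chain_of + 1L, , drop = FALSE]
      m <- m + disp
      box[1:2] <- box[1:2] * f
      for (k in 1:2) m[, k] <- m[, k] - box[k] * floor(m[, k] / box[k])
      r <- relax(m, box)
      if (!r$ok)
        stop(sprintf("compression stalled by steric overlap at %.3f g/cm^3 (target %.3f)",
                     structure_mass(s) * 1.66054 / prod(box), target))
      m <- r$m
    }
  })
  s <- set_coords(s, m)
  s$box <- box
  wrap_structure(s)
}

chain_centroids <- function(m, chain_of) {
  cx <- tapply(m[, 1], chain_of, mean)
  cy <- tapply(m[, 2], chain_of, mean)
  cz <- tapply(m[, 3], chain_of, mean)
  cbind(cx, cy, cz)
}

#' Solvate to a target moisture and neutralize with sodium
#'
#' Adds the number of waters `n_w` that brings `n_w * 18.015 / (dry mass +
#' n_w * 18.015)` within one water of the requested mass percentage, placed
#' on interstitial void sites at least 2.4 A from any heavy atom (seeded
#' order), plus one sodium counterion per GlcA carboxylate so the total
#' charge is zero. Waters are represented by their oxygen site; their mass
#' is counted as the full 18.015 Da.
#'
#' @param s a periodic `scw_structure`.
#' @param moisture target mass % water.
#' @param seed seed for the site order.
#' @return solvated, neutralized `scw_structure`.
#' @export
solvate_and_neutralize <- function(s, moisture = 3, seed = 1L) {
  if (!s$periodic) stop("solvation requires a periodic structure")
  dry <- structure_mass(s)
  f <- moisture / 100
  n_w <- if (f <= 0) 0L else as.integer(round(f * dry / (18.015 * (1 - f))))
  n_na <- sum(s$atoms$residue_type == "GLCA" & s$atoms$atom_label == "C1")
  n_extra <- n_w + n_na
  if (n_extra == 0) return(s)
  grid_sp <- 2.8
  gx <- seq(grid_sp / 2, s$box[1] - grid_sp / 4, by = grid_sp)
  gy <- seq(grid_sp / 2, s$box[2] - grid_sp / 4, by = grid_sp)
  gz <- seq(grid_sp / 2, s$box[3] - grid_sp / 4, by = grid_sp)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dmin <- min_dist_to_set_cpp(pts, coords_matrix(s), 2.4, s$box, TRUE)
  void <- pts[dmin >= 2.4 - 1e-9, , drop = FALSE]
  if (nrow(void) < n_extra)
    stop(sprintf("no interstitial space: %d void sites for %d waters+ions",
                 nrow(void), n_extra))
  pick <- with_seed(seed, void[sample.int(nrow(void), n_extra), ,
                               drop = FALSE])
  max_chain <- if (nrow(s$atoms)) max(s$atoms$chain_id) else 0L
  tabs <- list(s$atoms)
  if (n_w > 0) {
    w <- pick[seq_len(n_w), , drop = FALSE]
    tabs[[2]] <- atom_table(rep("O", n_w), rep("O", n_w), seq_len(n_w),
                            rep("WAT", n_w), max_chain + 1L,
                            w[, 1], w[, 2], w[, 3])
  }
  if (n_na > 0) {
    io <- pick[n_w + seq_len(n_na), , drop = FALSE]
    tabs[[length(tabs) + 1L]] <-
      atom_table(rep("NA", n_na), rep("NA", n_na), seq_len(n_na),
                 rep("NA", n_na), max_chain + 2L, io[, 1], io[, 2], io[, 3])
  }
  atoms <- do.call(rbind, tabs)
  scw_structure(atoms, box = s$box, periodic = TRUE)
}
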