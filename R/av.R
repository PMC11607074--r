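#' Van der Waals radii used for steric exclusion
#'
#' @return named vector of radii in Angstrom; elements not listed fall
#'   back to \code{default}
#' @param default radius for unknown elements
#' @export
vdw_radii <- function(default = 1.5) {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    default = default)
}

#' Load a molecular structure from a PDB file
#'
#' Parsing is delegated to \code{bio3d::read.pdb}; atoms receive van der
#' Waals radii from \code{\link{vdw_radii}} keyed on the element symbol,
#' with a warning and the default radius for unknown elements.
#'
#' @param file PDB file path
#' @param include_hetero keep HETATM records
#' @return an \code{av_structure}: data frame (eleno, elety, element,
#'   chain, resno, x, y, z, radius)
#' @export
load_structure <- function(file, include_hetero = FALSE) {
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  if (!include_hetero) a <- a[a$type == "ATOM", , drop = FALSE]
  el <- toupper(trimws(a$elesy))
  el[is.na(el) | el == ""] <- toupper(substr(trimws(a$elety[is.na(el) | el == ""]), 1, 1))
  rad <- vdw_radii()
  r <- rad[el]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            "; using default radius ", rad["default"])
    r[unknown] <- rad["default"]
  }
  structure(data.frame(eleno = a$eleno, elety = trimws(a$elety),
                       element = el, chain = a$chain, resno = a$resno,
                       x = a$x, y = a$y, z = a$z, radius = unname(r),
                       stringsAsFactors = FALSE),
            class = c("av_structure", "data.frame"))
}

#' Construct a structure from raw atom coordinates
#'
#' Convenience constructor for toy structures in tests and geometry
#' studies, bypassing file parsing.
#'
#' @param xyz n x 3 matrix of coordinates (Angstrom)
#' @param element element symbols (recycled)
#' @param chain chain identifiers (recycled)
#' @export
structure_from_xyz <- function(xyz, element = "C", chain = "A") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  rad <- vdw_radii()
  el <- rep_len(toupper(element), n)
  r <- rad[el]
  r[is.na(r)] <- rad["default"]
  structure(data.frame(eleno = seq_len(n), elety = el, element = el,
                       chain = rep_len(chain, n), resno = seq_len(n),
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       radius = unname(r), stringsAsFactors = FALSE),
            class = c("av_structure", "data.frame"))
}

#' Dye model for accessible-volume simulation
#'
#' The flexible linker is a tube of length L and width w anchored at the
#' attachment atom; the fluorophore itself is approximated by three radii
#' whose AV clouds are superposed with equal weight (the three-radii AV).
#' Shipped parameter values are plausible dye geometries, not published
#' ones (see \code{\link{dye_presets}}).
#'
#' @param linker_length L (Angstrom, > 0)
#' @param linker_width w (Angstrom, > 0)
#' @param radii three dye radii (Angstrom)
#' @param attach_id atom serial number (eleno) of the attachment atom
#' @export
dye_model <- function(linker_length = 20, linker_width = 4.5,
                      radii = c(5, 4.5, 1.5), attach_id = 1) {
  if (linker_length <= 0 || linker_width <= 0 || any(radii <= 0))
    stop("linker dimensions and dye radii must be > 0")
  structure(list(linker_length = linker_length, linker_width = linker_width,
                 radii = radii, attach_id = attach_id),
            class = "dye_model")
}

#' Plausible dye-cloud parameter sets
#'
#' Linker and radius values for the fluorophores used in the recombinase
#' experiments.  These are generic literature-style AV geometries supplied
#' as documented defaults -- the exact values used in the original FPS
#' runs are not published, so derived distances are indicative only.
#'
#' @return data frame of dye, linker_length, linker_width, r1, r2, r3
#' @export
dye_presets <- function() {
  data.frame(dye = c("alexa488", "atto532", "cy3b", "cy5"),
             linker_length = c(20.0, 20.5, 20.5, 21.0),
             linker_width = c(4.5, 4.5, 4.5, 4.5),
             r1 = c(5.0, 4.9, 6.8, 11.0),
             r2 = c(4.5, 3.5, 3.0, 3.0),
             r3 = c(1.5, 1.5, 1.5, 1.5),
             stringsAsFactors = FALSE)
}

#' Accessible volume of a tethered dye
#'
#' Grid-based AV: a dye position is accessible when (i) the dye sphere of
#' each radius clears all atoms inflated by that radius, and (ii) the
#' geodesic linker path from the attachment point through linker-free
#' space is no longer than the linker.  Distances come from Dijkstra on
#' the 26-neighbour grid graph seeded with exact line-of-sight distances.
#' The final AV superposes the clouds of the three dye radii with equal
#' weight.  Deterministic given the spacing.
#'
#' @param structure an \code{av_structure}
#' @param dye a \code{dye_model}; its attach_id must exist in the structure
#' @param spacing grid spacing (Angstrom); 1.0 default, 0.5 for
#'   high-accuracy work
#' @return an \code{accessible_volume}: points (x, y, z, weight, dist),
#'   attach point, spacing, per-radius point counts
#' @export
compute_av <- function(structure, dye, spacing = 1.0) {
  stopifnot(inherits(structure, "av_structure"), inherits(dye, "dye_model"))
  i <- match(dye$attach_id, structure$eleno)
  if (is.na(i)) stop("attachment atom ", dye$attach_id, " not found")
  attach <- c(structure$x[i], structure$y[i], structure$z[i])
  obst <- structure[-i, , drop = FALSE]    # the attachment atom never clashes
  coords <- cbind(obst$x, obst$y, obst$z)
  key_all <- character(0)
  pts <- list(); counts <- integer(0)
  for (r in dye$radii) {
    g <- av_grid_cpp(coords, obst$radius, attach, dye$linker_length,
                     dye$linker_width / 2, r, spacing)
    counts <- c(counts, nrow(g$points))
    pts[[length(pts) + 1]] <- cbind(g$points, g$dist)
  }
  all_pts <- do.call(rbind, pts)
  if (is.null(all_pts) || nrow(all_pts) == 0)
    stop("no accessible volume: attachment point is buried")
  key <- apply(round(all_pts[, 1:3, drop = FALSE] / spacing), 1, paste,
               collapse = ",")
  w <- rep(1 / length(dye$radii), nrow(all_pts))
  agg_w <- tapply(w, key, sum)
  first <- !duplicated(key)
  uk <- key[first]
  out <- data.frame(x = all_pts[first, 1], y = all_pts[first, 2],
                    z = all_pts[first, 3], dist = all_pts[first, 4],
                    weight = as.numeric(agg_w[uk]))
  base::structure(list(points = out, attach = attach, spacing = spacing,
                       n_per_radius = counts, dye = dye),
                  class = "accessible_volume")
}

#' FRET-averaged distance between two accessible volumes
#'
#' E_avg is the weight-averaged efficiency over dye position pairs and
#' the FRET-averaged distance is R0 ((1 - E_avg)/E_avg)^(1/6).  All pairs
#' are enumerated when their number is at most \code{n_pairs}; otherwise
#' a seeded Monte-Carlo subsample of positions is used.
#'
#' @param av_donor,av_acceptor \code{accessible_volume} objects
#' @param R0 Forster radius (Angstrom)
#' @param n_pairs pair budget for exact enumeration / sampling
#' @param seed optional integer seed (sampling branch only)
#' @return list(R_da, E_avg, sd_r, n_pairs, exact)
#' @export
mean_fret_distance <- function(av_donor, av_acceptor, R0, n_pairs = 2e5,
                               seed = NULL) {
  pd <- av_donor$points; pa <- av_acceptor$points
  if (nrow(pd) == 0 || nrow(pa) == 0) stop("empty accessible volume")
  exact <- as.double(nrow(pd)) * nrow(pa) <= n_pairs
  if (!exact) {
    if (!is.null(seed)) set.seed(seed)
    m <- ceiling(sqrt(n_pairs))
    pd <- pd[sample.int(nrow(pd), min(m, nrow(pd)), prob = pd$weight,
                        replace = nrow(pd) < m), , drop = FALSE]
    pa <- pa[sample.int(nrow(pa), min(m, nrow(pa)), prob = pa$weight,
                        replace = nrow(pa) < m), , drop = FALSE]
    wd <- rep(1, nrow(pd)); wa <- rep(1, nrow(pa))
  } else {
    wd <- pd$weight; wa <- pa$weight
  }
  dx <- outer(pd$x, pa$x, "-"); dy <- outer(pd$y, pa$y, "-")
  dz <- outer(pd$z, pa$z, "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  w <- outer(wd, wa)
  Ei <- 1 / (1 + (r / R0)^6)
  E_avg <- sum(w * Ei) / sum(w)
  mr <- sum(w * r) / sum(w)
  sd_r <- sqrt(sum(w * (r - mr)^2) / sum(w))
  list(R_da = R0 * ((1 - E_avg) / E_avg)^(1 / 6), E_avg = E_avg,
       sd_r = sd_r, n_pairs = length(r), exact = exact)
}

# Rodrigues rotation of points about a unit axis through `origin`.
rotate_points <- function(xyz, origin, axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, origin) %*% t(Rm), 2, origin, "+")
}

#' Rigid-body subunit-rotation scan
#'
#' Rotates one half of the structure about the given axis in steps,
#' recomputes the accessible volume of the dye riding on the rotated
#' half, and records the FRET-averaged inter-dye distance and efficiency
#' at each angle.  At 0 degrees the profile equals the unrotated (cnr)
#' geometry, and 360 degrees returns to it within grid tolerance.
#'
#' @param structure an \code{av_structure}
#' @param rotating logical vector (or atom indices) selecting the
#'   rotating half; must be a proper nonempty subset
#' @param axis_point1,axis_point2 two points defining the rotation axis
#' @param step angle increment in degrees; must divide 360
#' @param dye_rot dye attached to the rotating half (\code{dye_model})
#' @param dye_fix dye attached to the fixed half
#' @param R0 Forster radius (Angstrom)
#' @param spacing AV grid spacing
#' @param n_pairs,seed passed to \code{\link{mean_fret_distance}}
#' @return \code{rotation_profile}: data frame (angle, R_da, E_avg)
#' @export
rotation_scan <- function(structure, rotating, axis_point1, axis_point2,
                          step = 15, dye_rot, dye_fix, R0, spacing = 1.0,
                          n_pairs = 2e5, seed = NULL) {
  n <- nrow(structure)
  sel <- if (is.logical(rotating)) rotating else seq_len(n) %in% rotating
  if (!any(sel) || all(sel))
    stop("rotating selection must be a proper nonempty subset")
  if (360 %% step != 0) stop("step must divide 360")
  axis <- axis_point2 - axis_point1
  if (sum(axis^2) == 0) stop("axis points coincide")
  if (!dye_rot$attach_id %in% structure$eleno[sel])
    stop("dye_rot must attach to the rotating half")
  if (!dye_fix$attach_id %in% structure$eleno[!sel])
    stop("dye_fix must attach to the fixed half")
  av_fix <- compute_av(structure, dye_fix, spacing)
  angles <- seq(0, 360, by = step)
  rda <- eavg <- numeric(length(angles))
  for (ai in seq_along(angles)) {
    s2 <- structure
    xyz <- cbind(s2$x, s2$y, s2$z)
    xyz[sel, ] <- rotate_points(xyz[sel, , drop = FALSE], axis_point1,
                                axis, angles[ai])
    s2$x <- xyz[, 1]; s2$y <- xyz[, 2]; s2$z <- xyz[, 3]
    av_rot <- compute_av(s2, dye_rot, spacing)
    mf <- mean_fret_distance(av_rot, av_fix, R0, n_pairs = n_pairs,
                             seed = seed)
    rda[ai] <- mf$R_da; eavg[ai] <- mf$E_avg
  }
  base::structure(data.frame(angle = angles, R_da = rda, E_avg = eavg),
                  class = c("rotation_profile", "data.frame"))
}
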