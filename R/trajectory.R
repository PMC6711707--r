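# Per-frame geometric descriptors of a membrane-protein trajectory:
# membrane plane fit, TM helix tilt, ectodomain inclination, domain-bilayer
# distance, backbone-segment normal span, phi/psi dihedrals, atom-pair
# distances and normalised probability distributions.
#
# A trajectory is a plain data.frame with columns
#   frame, atom, resno, resname, chain, x, y, z    (coordinates in Angstrom)
# and a single frame is the same data.frame restricted to one frame index.

.vnorm <- function(v) sqrt(sum(v^2))
.unit <- function(v) {
  n <- .vnorm(v)
  if (n == 0) stop("zero-length vector")
  v / n
}
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Expand "222-224" / "222" / numeric vectors into integer residue numbers.
parse_resno <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  out <- lapply(strsplit(x, ",")[[1]], function(part) {
    part <- trimws(part)
    if (grepl("^\\d+-\\d+$", part)) {
      r <- as.integer(strsplit(part, "-")[[1]])
      seq(r[1], r[2])
    } else {
      as.integer(part)
    }
  })
  unlist(out)
}

#' Select atoms from a frame
#'
#' Filters an atom table by residue number (vector or range string such as
#' `"222-224"`), atom name, chain and residue name. A selection string
#' `"chain:resno[:atom]"` is also accepted via `sel`.
#'
#' @param frame Single-frame atom data.frame.
#' @param resno Residue numbers (integer vector or range string).
#' @param atom Atom name(s), e.g. `"CA"` or `c("N","CA","C","O")`.
#' @param chain,resname Optional additional filters.
#' @param sel Optional `"chain:resno[:atom]"` selection string.
#' @return The matching rows of `frame`.
#' @export
select_atoms <- function(frame, resno = NULL, atom = NULL, chain = NULL,
                         resname = NULL, sel = NULL) {
  if (!is.null(sel)) {
    parts <- strsplit(sel, ":")[[1]]
    if (length(parts) < 2) stop("selection must look like 'chain:resno[:atom]'")
    chain <- parts[1]
    resno <- parse_resno(parts[2])
    if (length(parts) >= 3) atom <- parts[3]
  }
  keep <- rep(TRUE, nrow(frame))
  if (!is.null(resno)) keep <- keep & frame$resno %in% parse_resno(resno)
  if (!is.null(atom)) keep <- keep & frame$atom %in% atom
  if (!is.null(chain)) keep <- keep & frame$chain %in% chain
  if (!is.null(resname)) keep <- keep & frame$resname %in% resname
  frame[keep, , drop = FALSE]
}

.coords <- function(frame) as.matrix(frame[, c("x", "y", "z"), drop = FALSE])

# Standard atomic masses keyed by element symbol; element guessed from the
# leading alphabetic character of the atom name (PDB convention).
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06)

.atom_masses <- function(atom_names) {
  el <- toupper(substr(gsub("^[0-9]+", "", atom_names), 1, 1))
  m <- .atomic_masses[el]
  fallback <- is.na(m)
  m[fallback] <- 1
  structure(as.numeric(m), fallback = any(fallback))
}

#' Centre of mass of a set of atoms
#'
#' Masses are inferred from the leading element letter of each atom name;
#' unknown elements fall back to unit mass and set the `unit_mass_fallback`
#' attribute.
#'
#' @param frame Atom data.frame (already selected).
#' @return Numeric xyz vector with attribute `unit_mass_fallback`.
#' @export
center_of_mass <- function(frame) {
  if (nrow(frame) == 0) stop("empty selection")
  m <- .atom_masses(frame$atom)
  xyz <- .coords(frame)
  structure(colSums(xyz * m) / sum(m),
            unit_mass_fallback = attr(m, "fallback"))
}

#' Fit (or fix) the membrane plane
#'
#' Least-squares plane through the selected anchor atoms (typically lipid
#' phosphate markers) of one frame, via SVD of the centred coordinates. The
#' returned normal points toward `orient_ref` when one is given; otherwise
#' it points toward positive laboratory z (the bilayer-normal convention
#' for membrane-builder frames). Passing an explicit reference point makes
#' the signed descriptors invariant under arbitrary rigid transforms.
#'
#' @param frame Single-frame atom data.frame.
#' @param atom,resno,chain,resname,sel Anchor selection (see
#'   [select_atoms()]); default atom name `"P"`.
#' @param orient_ref Optional xyz point the normal should point toward.
#' @return An object of class `membrane_plane`: unit `normal`, anchor
#'   `centroid`, scalar `offset` (`normal . centroid`), `source`.
#' @export
membrane_plane <- function(frame, atom = "P", resno = NULL, chain = NULL,
                           resname = NULL, sel = NULL, orient_ref = NULL) {
  anchors <- select_atoms(frame, resno = resno, atom = atom, chain = chain,
                          resname = resname, sel = sel)
  xyz <- .coords(anchors)
  if (nrow(xyz) < 3) stop("need at least 3 anchor atoms to fit a plane")
  centroid <- colMeans(xyz)
  centred <- sweep(xyz, 2, centroid)
  sv <- svd(centred)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("anchor atoms are collinear; plane undefined")
  }
  normal <- sv$v[, 3]
  ref_dir <- if (!is.null(orient_ref)) orient_ref - centroid else c(0, 0, 1)
  if (sum(normal * ref_dir) < 0) normal <- -normal
  structure(list(normal = .unit(normal), centroid = centroid,
                 offset = sum(.unit(normal) * centroid), source = "fitted"),
            class = "membrane_plane")
}

#' Fixed membrane plane
#'
#' A plane given directly by its unit normal and a point, for toy data or
#' externally aligned frames.
#'
#' @param normal Plane normal (normalised internally).
#' @param point A point on the plane (default origin).
#' @return A `membrane_plane` with `source = "fixed"`.
#' @export
fixed_membrane_plane <- function(normal = c(0, 0, 1), point = c(0, 0, 0)) {
  n <- .unit(normal)
  structure(list(normal = n, centroid = point, offset = sum(n * point),
                 source = "fixed"),
            class = "membrane_plane")
}

#' @export
print.membrane_plane <- function(x, ...) {
  cat(sprintf("Membrane plane (%s): normal = (%.4f, %.4f, %.4f), offset = %.3f A\n",
              x$source, x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Transmembrane helix tilt angle
#'
#' Angle between the helix axis and the membrane plane, in degrees within
#' `[0, 90]`. The axis is the first principal axis (SVD) of the selected
#' C-alpha coordinates, oriented from the N- to the C-terminal residue; the
#' tilt is `asin(|axis . normal|)`, i.e. 90 degrees minus the angle to the
#' normal.
#'
#' @param frame Single-frame atom data.frame.
#' @param plane A `membrane_plane`.
#' @param resno Helix residue numbers (range string allowed), >= 4 C-alpha.
#' @param atom Atom name used for the axis (default `"CA"`).
#' @param chain Optional chain filter.
#' @return Tilt angle in degrees.
#' @export
helix_tilt_angle <- function(frame, plane, resno, atom = "CA", chain = NULL) {
  ca <- select_atoms(frame, resno = resno, atom = atom, chain = chain)
  ca <- ca[order(ca$resno), , drop = FALSE]
  if (nrow(ca) < 4) stop("need at least 4 helix C-alpha atoms")
  xyz <- .coords(ca)
  centred <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(centred)
  if (sv$d[1] < 1e-9) stop("degenerate helix selection (zero variance)")
  axis <- sv$v[, 1]
  if (sum(axis * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) axis <- -axis  # N -> C
  asin(min(1, abs(sum(axis * plane$normal)))) * 180 / pi
}

#' Ectodomain inclination angle
#'
#' Signed angle, in degrees within `[-90, 90]`, between the membrane plane
#' and the vector from the centroid of the TM N-terminal residues (default
#' 222-224) to the centroid of the inter-domain linker residues (default
#' 130-132). Negative values point into the bilayer. C-alpha centroids by
#' default; set `atom = NULL` for all-atom centroids.
#'
#' @param frame Single-frame atom data.frame.
#' @param plane A `membrane_plane`.
#' @param tm_resno,linker_resno Residue selections for the two centroids.
#' @param atom Atom name(s) for the centroids (`NULL` = all atoms).
#' @param chain Optional chain filter.
#' @return Inclination angle in degrees (signed).
#' @export
ectodomain_inclination <- function(frame, plane, tm_resno = "222-224",
                                   linker_resno = "130-132", atom = "CA",
                                   chain = NULL) {
  tm <- select_atoms(frame, resno = tm_resno, atom = atom, chain = chain)
  lk <- select_atoms(frame, resno = linker_resno, atom = atom, chain = chain)
  if (nrow(tm) == 0 || nrow(lk) == 0) stop("missing residue group for inclination")
  v <- colMeans(.coords(lk)) - colMeans(.coords(tm))
  asin(max(-1, min(1, sum(.unit(v) * plane$normal)))) * 180 / pi
}

#' Domain-to-membrane distance along the bilayer normal
#'
#' Signed projection, onto the membrane normal, of the vector from the
#' anchor-atom centroid (the phosphate plane) to the centre of mass of the
#' selected domain.
#'
#' @param frame Single-frame atom data.frame.
#' @param plane A `membrane_plane`.
#' @param resno,atom,chain,resname,sel Domain selection (see
#'   [select_atoms()]).
#' @return Distance in Angstrom (positive on the normal side).
#' @export
domain_membrane_distance <- function(frame, plane, resno = NULL, atom = NULL,
                                     chain = NULL, resname = NULL, sel = NULL) {
  dom <- select_atoms(frame, resno = resno, atom = atom, chain = chain,
                      resname = resname, sel = sel)
  if (nrow(dom) == 0) stop("empty domain selection")
  com <- center_of_mass(dom)
  sum((com - plane$centroid) * plane$normal)
}

#' Backbone-segment span along the bilayer normal
#'
#' Absolute difference of the normal-projections of the backbone-atom
#' centroids (N, CA, C, O) of two residues.
#'
#' @param frame Single-frame atom data.frame.
#' @param plane A `membrane_plane`.
#' @param res_a,res_b Residue numbers (e.g. 218 and 221).
#' @param chain Optional chain filter.
#' @return Span in Angstrom.
#' @export
segment_normal_length <- function(frame, plane, res_a = 218, res_b = 221,
                                  chain = NULL) {
  bb <- c("N", "CA", "C", "O")
  a <- select_atoms(frame, resno = res_a, atom = bb, chain = chain)
  b <- select_atoms(frame, resno = res_b, atom = bb, chain = chain)
  if (nrow(a) < 4 || nrow(b) < 4) {
    stop("backbone atoms (N, CA, C, O) required for both residues")
  }
  pa <- sum(colMeans(.coords(a)) * plane$normal)
  pb <- sum(colMeans(.coords(b)) * plane$normal)
  abs(pa - pb)
}

#' Dihedral angle of four points
#'
#' Signed torsion in degrees within `(-180, 180]`, IUPAC convention.
#'
#' @param p1,p2,p3,p4 xyz coordinate vectors.
#' @return Dihedral angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  if (.vnorm(n1) == 0 || .vnorm(n2) == 0) stop("collinear atoms; dihedral undefined")
  ang <- atan2(sum(.cross(n1, n2) * .unit(b2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi dihedrals of a residue
#'
#' `phi = dihedral(C(i-1), N, CA, C)`, `psi = dihedral(N, CA, C, N(i+1))`,
#' both signed in `(-180, 180]`. Fails at chain termini where the flanking
#' atoms are absent.
#'
#' @param frame Single-frame atom data.frame.
#' @param resno Residue number i.
#' @param chain Optional chain filter.
#' @return Named numeric vector `c(phi = , psi = )` in degrees.
#' @export
backbone_dihedrals <- function(frame, resno, chain = NULL) {
  one <- function(rn, at) {
    s <- select_atoms(frame, resno = rn, atom = at, chain = chain)
    if (nrow(s) != 1) {
      stop(sprintf("atom %s of residue %d missing (or ambiguous)", at, rn))
    }
    as.numeric(.coords(s))
  }
  c_prev <- one(resno - 1, "C")
  n_i <- one(resno, "N"); ca_i <- one(resno, "CA"); c_i <- one(resno, "C")
  n_next <- one(resno + 1, "N")
  c(phi = dihedral_angle(c_prev, n_i, ca_i, c_i),
    psi = dihedral_angle(n_i, ca_i, c_i, n_next))
}

#' Distance between two atoms (nearest candidate)
#'
#' Euclidean distance between one atom and the nearest of a candidate set
#' (e.g. a hydroxyl oxygen versus the backbone O atoms of a neighbouring
#' residue), with a hydrogen-bond call at a configurable cutoff.
#'
#' @param frame Single-frame atom data.frame.
#' @param sel_a,sel_b `"chain:resno:atom"` selection strings (or lists of
#'   [select_atoms()] arguments). `sel_a` must match exactly one atom;
#'   `sel_b` may match several, in which case the minimum distance is
#'   reported.
#' @param hbond_cutoff Hydrogen-bond distance cutoff in Angstrom
#'   (default 3.5).
#' @return List with `distance` (Angstrom), `hbond` (logical),
#'   `cutoff`.
#' @export
atom_pair_distance <- function(frame, sel_a, sel_b, hbond_cutoff = 3.5) {
  pick <- function(s) {
    if (is.character(s)) select_atoms(frame, sel = s)
    else do.call(select_atoms, c(list(frame), s))
  }
  a <- pick(sel_a); b <- pick(sel_b)
  if (nrow(a) != 1) stop("`sel_a` must select exactly one atom")
  if (nrow(b) < 1) stop("`sel_b` selected no atoms")
  d2 <- rowSums(sweep(.coords(b), 2, as.numeric(.coords(a)))^2)
  d <- sqrt(min(d2))
  list(distance = d, hbond = d <= hbond_cutoff, cutoff = hbond_cutoff)
}

#' Normalised probability distribution of a descriptor series
#'
#' Histogram with bin edges aligned to integer multiples of `bin_width`;
#' probabilities sum to one and the modal bin centre is reported. Default
#' bin widths elsewhere in the package are 2 degrees for angles and 0.5
#' Angstrom for distances.
#'
#' @param values Numeric descriptor values (>= 1).
#' @param bin_width Bin width, > 0.
#' @return Object of class `descriptor_histogram`: `edges`, `prob`,
#'   `mid`, `mode`, `bin_width`, `n`.
#' @export
probability_distribution <- function(values, bin_width) {
  if (length(values) < 1) stop("empty series")
  stopifnot(is.finite(bin_width), bin_width > 0, all(is.finite(values)))
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  nbins <- round((hi - lo) / bin_width)
  idx <- pmin(pmax(floor((values - lo) / bin_width) + 1, 1), nbins)
  prob <- tabulate(idx, nbins) / length(values)
  edges <- lo + bin_width * (0:nbins)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(edges = edges, prob = prob, mid = mid,
                 mode = mid[which.max(prob)], bin_width = bin_width,
                 n = length(values)),
            class = "descriptor_histogram")
}

#' @export
print.descriptor_histogram <- function(x, ...) {
  cat(sprintf("Probability distribution: %d values, %d bins of width %g, mode at %g\n",
              x$n, length(x$prob), x$bin_width, x$mode))
  invisible(x)
}

#' Apply a per-frame descriptor over a trajectory
#'
#' @param traj Trajectory data.frame (with a `frame` column).
#' @param fun Function taking a single-frame data.frame as first argument.
#' @param ... Passed on to `fun`.
#' @return Numeric vector with one value per frame, in frame order.
#' @examples
#' traj <- build_toy_trajectory(n_frames = 3)
#' per_frame(traj, function(fr) {
#'   helix_tilt_angle(fr, fixed_membrane_plane(), resno = "222-248")
#' })
#' @export
per_frame <- function(traj, fun, ...) {
  ids <- sort(unique(traj$frame))
  vapply(ids, function(i) fun(traj[traj$frame == i, , drop = FALSE], ...),
         numeric(1))
}
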