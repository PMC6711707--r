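# Analytic toy membrane-protein trajectory with known geometry, used as
# ground truth for the descriptor suite. Laboratory frame: bilayer normal
# along +z, phosphate-marker plane at z = 0.

#' Build a toy membrane-protein trajectory with known geometry
#'
#' Constructs frames containing (i) a 3x3 grid of phosphate-marker atoms in
#' the z = 0 plane (chain `"M"`, atom `"P"`); (ii) a straight TM
#' pseudo-helix of C-alpha atoms, residues 222-248, whose axis makes the
#' requested tilt angle with the plane; (iii) C-alpha markers for the TM
#' N-terminal group (222-224, shared with the helix) and the inter-domain
#' linker group (130-132) realising the requested ectodomain inclination;
#' (iv) a three-atom first-Ig-domain marker (residues 101-103) whose centre
#' of mass sits at the requested height above the plane; (v) backbone atoms
#' (N, CA, C, O) of residues 218 and 221 whose centroids are separated by
#' the requested span along the normal; plus a serine-like side-chain
#' oxygen on residue 232 placed 3.0 Angstrom from the backbone O of residue
#' 228 (a formed hydrogen bond) for the atom-pair descriptor. On jitter-free
#' output the descriptor suite recovers the requested values exactly (to 1e-6 degrees /
#' Angstrom); with `jitter_sd > 0`, independent Gaussian noise of that sd is
#' added to every coordinate of every atom in every frame.
#'
#' @param tilt_deg TM helix tilt angle in degrees, in (0, 90].
#' @param incl_deg Ectodomain inclination angle in degrees, in (0, 90].
#' @param d_c1 First-Ig-domain to bilayer distance in Angstrom.
#' @param span_s218_p221 Normal-direction span of the 218/221 backbone
#'   centroids in Angstrom.
#' @param n_frames Number of frames, >= 1.
#' @param jitter_sd Per-coordinate Gaussian noise sd in Angstrom, >= 0.
#' @param seed Integer seed (used only when `jitter_sd > 0`).
#' @return Trajectory data.frame with columns `frame`, `atom`, `resno`,
#'   `resname`, `chain`, `x`, `y`, `z`.
#' @examples
#' traj <- build_toy_trajectory(tilt_deg = 40, incl_deg = 40,
#'                              d_c1 = 30, span_s218_p221 = 11)
#' fr <- traj[traj$frame == 1, ]
#' helix_tilt_angle(fr, fixed_membrane_plane(), resno = "222-248")
#' @export
build_toy_trajectory <- function(tilt_deg = 40, incl_deg = 40, d_c1 = 30,
                                 span_s218_p221 = 11, n_frames = 1,
                                 jitter_sd = 0, seed = 1L) {
  stopifnot(tilt_deg > 0, tilt_deg <= 90, incl_deg > 0, incl_deg <= 90,
            n_frames >= 1, jitter_sd >= 0)
  th <- tilt_deg * pi / 180
  ph <- incl_deg * pi / 180

  row <- function(atom, resno, resname, chain, xyz) {
    data.frame(atom = atom, resno = resno, resname = resname, chain = chain,
               x = xyz[1], y = xyz[2], z = xyz[3])
  }

  atoms <- list()
  # (i) phosphate-marker plane at z = 0
  grid <- expand.grid(x = c(-20, 0, 20), y = c(-20, 0, 20))
  for (i in seq_len(nrow(grid))) {
    atoms[[length(atoms) + 1]] <- row("P", i, "MEM", "M",
                                      c(grid$x[i], grid$y[i], 0))
  }
  # (ii) TM pseudo-helix: residue 222 at the top, axis descending into the
  # membrane at the requested tilt (1.5 A rise per residue)
  u <- c(cos(th), 0, sin(th))          # unit axis, angle `th` to the plane
  p0 <- c(0, 0, -1)
  helix_res <- 222:248
  for (i in seq_along(helix_res)) {
    pos <- p0 - (i - 1) * 1.5 * u
    atoms[[length(atoms) + 1]] <- row("CA", helix_res[i], "ALA", "A", pos)
  }
  # (iii) linker markers 130-132: centroid at tm-centroid + L * incl vector
  c_tm <- p0 - 1 * 1.5 * u             # centroid of residues 222-224
  L <- 40
  c_link <- c_tm + L * c(cos(ph), 0, sin(ph))
  deltas <- list(c(0, 1, 0), c(0, -1, 0), c(0, 0, 0))   # sum to zero
  for (i in 1:3) {
    atoms[[length(atoms) + 1]] <- row("CA", 129 + i, "GLY", "A",
                                      c_link + deltas[[i]])
  }
  # (iv) first-Ig-domain marker: carbon atoms, equal masses, COM at d_c1
  for (i in 1:3) {
    atoms[[length(atoms) + 1]] <- row("CA", 100 + i, "GLY", "A",
                                      c(8, 0, d_c1) + deltas[[i]])
  }
  # (v) backbone atoms of residues 218 and 221, centroids span apart in z
  bb <- function(resno, resname, zc) {
    off <- list(N = c(1, 0, 0), CA = c(-1, 0, 0), C = c(0, 1, 0), O = c(0, -1, 0))
    lapply(names(off), function(a) {
      row(a, resno, resname, "A", c(5, 0, zc) + off[[a]])
    })
  }
  atoms <- c(atoms, bb(218, "SER", 3), bb(221, "PRO", 3 + span_s218_p221))
  # minimal 216/217 backbone so phi/psi of residue 217 is defined
  # (217 N -> 218 N closes psi via the bb() N of residue 218)
  atoms <- c(atoms, list(
    row("C", 216, "ILE", "A", c(8, 0, 1.8)),
    row("N", 217, "PRO", "A", c(7.5, 0.5, 2.1)),
    row("CA", 217, "PRO", "A", c(7.0, 0.0, 2.4)),
    row("C", 217, "PRO", "A", c(6.5, 0.2, 2.9))))
  # side-chain hydroxyl oxygen of 232 near the backbone O of 228 (3.0 A)
  atoms[[length(atoms) + 1]] <- row("OG1", 232, "THR", "A", c(10, 10, -5))
  atoms[[length(atoms) + 1]] <- row("O", 228, "VAL", "A", c(10, 10, -8))

  base <- do.call(rbind, atoms)
  if (jitter_sd > 0) set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    fr <- base
    if (jitter_sd > 0) {
      fr[, c("x", "y", "z")] <- fr[, c("x", "y", "z")] +
        matrix(stats::rnorm(nrow(fr) * 3, 0, jitter_sd), ncol = 3)
    }
    cbind(frame = f, fr)
  })
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  out
}

#' Apply a rigid transform to a trajectory or frame
#'
#' Rotates all coordinates by matrix `R` and then translates by `t`.
#' Utility for invariance checks and for aligning external frames.
#'
#' @param traj Trajectory or single-frame data.frame.
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation vector.
#' @return The transformed data.frame.
#' @export
rigid_transform <- function(traj, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(traj[, c("x", "y", "z")])
  traj[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, -t)
  traj
}

#' Random rotation matrix
#'
#' Uniform (Haar) random rotation via QR decomposition of a Gaussian
#' matrix, determinant fixed to +1.
#'
#' @param seed Optional integer seed.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
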