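# Readers and writers for the plain-text dialects the analysis modules
# exchange: cycle-level adhesion CSV, per-cell FRET CSV, genotype-row CSV,
# multi-model PDB and per-frame coordinate CSV trajectories.

#' Read cycle-level adhesion records
#'
#' Input columns: `cell_pair_id`, `tc_s`, `cycle_index`, `adhesion` (0/1).
#' Cycles are aggregated per cell pair and contact time into an
#' [adhesion_curve()]; the surface densities are supplied by the caller
#' (they come from an independent calibration, never from the cycle file).
#'
#' @param file CSV path.
#' @param mr,ml Receptor and ligand surface densities (per square micron).
#' @param label Curve label.
#' @return An [adhesion_curve()].
#' @export
read_adhesion_cycles <- function(file, mr, ml, label = basename(file)) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("cell_pair_id", "tc_s", "cycle_index", "adhesion")
  if (!all(req %in% names(d))) {
    stop("cycle CSV needs columns ", paste(req, collapse = ", "))
  }
  if (!all(d$adhesion %in% c(0, 1))) stop("`adhesion` must be 0/1")
  agg <- stats::aggregate(adhesion ~ cell_pair_id + tc_s, d,
                          function(x) c(n = length(x), k = sum(x)))
  obs <- data.frame(cell_pair_id = agg$cell_pair_id, tc = agg$tc_s,
                    n_cycles = agg$adhesion[, "n"],
                    n_adhesions = agg$adhesion[, "k"])
  adhesion_curve(obs, density_pair(mr, ml), label)
}

#' Write the cycle table of a simulated curve
#'
#' @param curve An [adhesion_curve()] carrying a `"cycles"` attribute (as
#'   produced by [simulate_adhesion_cycles()]).
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_adhesion_cycles <- function(curve, file) {
  cycles <- attr(curve, "cycles")
  if (is.null(cycles)) stop("curve carries no cycle-level table")
  utils::write.csv(cycles, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export a fit as a JSON-ready record and per-tc table
#'
#' @param fit An `adhesion_fit`.
#' @return List with `record` (parameters, SEs, flags — suitable for JSON
#'   serialisation) and `table` (per contact time observed and fitted Pa).
#' @export
fit_record <- function(fit) {
  stopifnot(inherits(fit, "adhesion_fit"))
  rec <- list(AcKa = if (fit$nd) NA_real_ else fit$params$AcKa,
              koff = if (fit$nd) NA_real_ else fit$params$koff,
              Ackon = if (fit$nd) NA_real_ else fit$params$Ackon,
              se_AcKa = unname(fit$se["AcKa"]),
              se_koff = unname(fit$se["koff"]),
              se_Ackon = unname(fit$se["Ackon"]),
              converged = fit$converged, nd = fit$nd,
              n_obs = nrow(fit$curve$observations),
              method = fit$method)
  tab <- fit$pool
  if (!fit$nd) tab$fitted <- predict(fit)
  list(record = rec, table = tab)
}

#' Read per-cell FRET intensities
#'
#' Input columns: `cell_id`, `group`, `Q`, `DQ`, optional `background`.
#'
#' @param file CSV path.
#' @return data.frame of cells.
#' @export
read_fret_cells <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("cell_id", "group", "Q", "DQ")
  if (!all(req %in% names(d))) {
    stop("FRET CSV needs columns ", paste(req, collapse = ", "))
  }
  d
}

#' Read labelled genotype-count rows
#'
#' Input columns: `label`, `row_text`, with `row_text` in the
#' `"A+B (p1)/C (p2)"` dialect parsed by [parse_genotype_row()].
#'
#' @param file CSV path.
#' @return data.frame with `label`, `row_text`.
#' @export
read_genotype_rows <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("label", "row_text") %in% names(d))) {
    stop("genotype CSV needs columns label, row_text")
  }
  d
}

#' Write a trajectory as a multi-model PDB
#'
#' One `MODEL`/`ENDMDL` block per frame, fixed-width `ATOM` records.
#'
#' @param traj Trajectory data.frame (`frame`, `atom`, `resno`, `resname`,
#'   `chain`, `x`, `y`, `z`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (f in sort(unique(traj$frame))) {
    fr <- traj[traj$frame == f, , drop = FALSE]
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(fr)), substr(fr$atom, 1, 4), substr(fr$resname, 1, 3),
      substr(fr$chain, 1, 1), fr$resno, fr$x, fr$y, fr$z, 1, 0)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB trajectory
#'
#' Parses `MODEL`/`ENDMDL` blocks via `bio3d::read.pdb` into the package's
#' trajectory data.frame.
#'
#' @param file PDB path.
#' @return Trajectory data.frame (`frame`, `atom`, `resno`, `resname`,
#'   `chain`, `x`, `y`, `z`).
#' @export
read_pdb_trajectory <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  at <- pdb$atom
  xyz <- pdb$xyz                       # one row per model
  n_frames <- nrow(xyz)
  if (is.null(n_frames)) {
    xyz <- matrix(xyz, nrow = 1)
    n_frames <- 1
  }
  frames <- lapply(seq_len(n_frames), function(f) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    data.frame(frame = f, atom = at$elety, resno = at$resno,
               resname = at$resid, chain = at$chain,
               x = co[, 1], y = co[, 2], z = co[, 3])
  })
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  out
}

#' Read a per-frame coordinate CSV trajectory
#'
#' Columns: `frame`, `atom`, `resno`, `resname`, `x`, `y`, `z` (optional
#' `chain`, filled with `"A"` when absent).
#'
#' @param file CSV path.
#' @return Trajectory data.frame.
#' @export
read_trajectory_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("frame", "atom", "resno", "resname", "x", "y", "z")
  if (!all(req %in% names(d))) {
    stop("trajectory CSV needs columns ", paste(req, collapse = ", "))
  }
  if (!"chain" %in% names(d)) d$chain <- "A"
  d[, c("frame", "atom", "resno", "resname", "chain", "x", "y", "z")]
}
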