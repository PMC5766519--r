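# Minimal CHARMM-dialect DCD writer. Coordinates are stored as float32,
# one fixed-length Fortran record per Cartesian component per frame, which
# is the layout read back by bio3d::read.dcd. No unit cell is written.

#' Write a trajectory as a CHARMM/NAMD DCD file
#'
#' Coordinates are truncated to 32-bit floats (the format's precision);
#' a round-trip through [load_trajectory()] therefore agrees with the
#' source to float32 precision, not exactly. Output is deterministic:
#' identical trajectories produce byte-identical files.
#'
#' @param traj a [trajectory].
#' @param path output file.
#' @export
write_trajectory_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  n <- traj$n_frames
  natoms <- traj$n_atoms
  icntrl <- integer(20)
  icntrl[1] <- n          # number of frames
  icntrl[2] <- 1L         # first step
  icntrl[3] <- 1L         # save interval
  icntrl[4] <- n          # total steps
  icntrl[20] <- 24L       # CHARMM version stamp
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  title <- formatC("Written by h12assay", width = -80)
  writeBin(80L + 4L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(80L + 4L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(natoms), con, size = 4)
  writeBin(4L, con, size = 4)
  nb <- 4L * natoms
  for (f in seq_len(n)) {
    for (d in 1:3) {
      writeBin(nb, con, size = 4)
      writeBin(as.numeric(traj$coords[f, , d]), con, size = 4)
      writeBin(nb, con, size = 4)
    }
  }
  invisible(path)
}
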