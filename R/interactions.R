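# Per-frame geometric detection and persistence statistics for the
# mechanistic interaction signatures: hydrogen bonds and salt bridges
# (distance + angle rule), hydrophobic contacts (minimum heavy-atom
# distance) and aromatic pi-stacking (ring-centroid distance + inter-plane
# angle).

#' Hydrogen-bond geometric parameters
#'
#' The acceptance rule is `d(donor, acceptor) <= d_max` and deviation of
#' the D-H...A angle from linearity `<= theta_max`; the default 35 degrees
#' is interpreted as that maximum deviation (i.e. the angle at the
#' hydrogen must be >= 145 degrees), the common convention of
#' trajectory-analysis tools. With `heavy_only = TRUE` the angular term is
#' skipped (distance-only detection for topologies without hydrogens);
#' results are then flagged in the output.
#'
#' @param d_max donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param theta_max maximum deviation from linearity, degrees, in (0, 90).
#' @param heavy_only skip the angular criterion.
#' @return Object of class `hbond_params`.
#' @export
hbond_params <- function(d_max = 3.3, theta_max = 35, heavy_only = FALSE) {
  if (d_max <= 0) stop("d_max must be > 0")
  if (theta_max <= 0 || theta_max >= 90) stop("theta_max must be in (0, 90)")
  structure(list(d_max = d_max, theta_max = theta_max,
                 heavy_only = heavy_only),
            class = "hbond_params")
}

#' Define a named interaction to monitor
#'
#' Selections are lists understood by [select_atoms()] (`chain`, `resno`,
#' `name`). For H-bonds/salt bridges, `a` is the donor heavy atom
#' selection, `h` its hydrogen(s) (paired with the donors by order) and
#' `b` the acceptor selection; multi-atom sites (e.g. the two carboxylate
#' oxygens Od1/Od2) are OR-combined into the one labelled interaction.
#' For contacts, `a`/`b` are the two heavy-atom groups; for pi-stacking,
#' the two ring atom sets (>= 3 atoms each).
#'
#' @param kind `"hbond"`, `"salt_bridge"`, `"hydrophobic_contact"` or
#'   `"pi_stack"`.
#' @param label human-readable label, e.g. `"E380-H377"`.
#' @param a,b,h atom selections (lists of `select_atoms()` arguments).
#' @return Object of class `interaction_spec`.
#' @export
interaction_spec <- function(kind = c("hbond", "salt_bridge",
                                      "hydrophobic_contact", "pi_stack"),
                             label, a, b, h = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("hbond", "salt_bridge") && is.null(h))
    h <- NA  # resolved (and possibly rejected) at detection time
  structure(list(kind = kind, label = label, a = a, b = b, h = h),
            class = "interaction_spec")
}

resolve_sel <- function(top, sel, what, label) {
  idx <- do.call(select_atoms, c(list(top), sel, list(allow_empty = TRUE)))
  if (length(idx) == 0)
    stop("interaction '", label, "': ", what, " selection resolves to no atoms")
  idx
}

# expanded donor/H/acceptor index triplets for an hbond-like spec
hbond_triplets <- function(top, spec, params) {
  di <- resolve_sel(top, spec$a, "donor", spec$label)
  ai <- resolve_sel(top, spec$b, "acceptor", spec$label)
  hi <- NULL
  if (!params$heavy_only) {
    if (length(spec$h) == 1 && !is.list(spec$h) && is.na(spec$h))
      stop("interaction '", spec$label, "': no hydrogen selection given; ",
           "supply `h` or use hbond_params(heavy_only = TRUE) for ",
           "distance-only detection")
    hi <- do.call(select_atoms,
                  c(list(top), spec$h, list(allow_empty = TRUE)))
    if (length(hi) == 0)
      stop("interaction '", spec$label, "': hydrogen atom(s) missing from ",
           "the topology; use hbond_params(heavy_only = TRUE) for ",
           "distance-only detection")
    if (length(hi) != length(di))
      stop("interaction '", spec$label, "': donor and hydrogen selections ",
           "must pair up one-to-one (", length(di), " donors vs ",
           length(hi), " hydrogens)")
  }
  list(donors = di, hydrogens = hi, acceptors = ai)
}

hbond_frame_geom <- function(frame, tri, params) {
  for (k in seq_along(tri$donors)) {
    D <- frame[tri$donors[k], ]
    for (a in tri$acceptors) {
      A <- frame[a, ]
      d <- sqrt(sum((D - A)^2))
      if (d > params$d_max) next
      if (params$heavy_only) return(TRUE)
      H <- frame[tri$hydrogens[k], ]
      u <- D - H; v <- A - H
      cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      ang <- acos(min(1, max(-1, cosang))) * 180 / pi
      if ((180 - ang) <= params$theta_max) return(TRUE)
    }
  }
  FALSE
}

#' Evaluate the hydrogen-bond rule on one frame
#'
#' TRUE iff for any expanded donor/hydrogen/acceptor triplet the
#' donor-acceptor distance is at most `d_max` *and* the D-H...A angle
#' deviates from linearity by at most `theta_max`.
#'
#' @param frame `n_atoms x 3` coordinate matrix (one trajectory frame).
#' @param top matching [topology].
#' @param spec an [interaction_spec] of kind hbond/salt_bridge.
#' @param params [hbond_params].
#' @return Logical scalar.
#' @export
detect_hbond_frame <- function(frame, top, spec, params = hbond_params()) {
  stopifnot(inherits(spec, "interaction_spec"),
            spec$kind %in% c("hbond", "salt_bridge"))
  tri <- hbond_triplets(top, spec, params)
  hbond_frame_geom(as.matrix(frame), tri, params)
}

new_interaction_series <- function(label, kind, present, window,
                                   applicable = TRUE, flags = character(0)) {
  structure(list(label = label, kind = kind, present = present,
                 window = window, n_frames = length(window),
                 persistence = if (applicable) 100 * mean(present) else NA_real_,
                 applicable = applicable, flags = flags),
            class = "interaction_series")
}

#' @export
print.interaction_series <- function(x, ...) {
  cat("<interaction_series> ", x$label, " [", x$kind, "]: ",
      if (x$applicable) sprintf("%.1f%% of %d frames", x$persistence,
                                x$n_frames) else "n/a",
      if (length(x$flags)) paste0(" (", paste(x$flags, collapse = ","), ")")
      else "", "\n", sep = "")
  invisible(x)
}

#' Persistence of an interaction over a trajectory window
#'
#' Applies the per-frame detector of the spec's kind to every frame of
#' the window; persistence is `100 * formed / n_frames`.
#'
#' @param traj a [trajectory].
#' @param top matching [topology].
#' @param spec an [interaction_spec].
#' @param params [hbond_params] (H-bond kinds only).
#' @param window frame indices (default all).
#' @param ... cutoffs forwarded to [contact_persistence()] /
#'   [pi_stacking()] for the non-H-bond kinds.
#' @return An `interaction_series`.
#' @export
persistence <- function(traj, top, spec, params = hbond_params(),
                        window = NULL, ...) {
  stopifnot(inherits(traj, "trajectory"), inherits(spec, "interaction_spec"))
  if (is.null(window)) window <- seq_len(traj$n_frames)
  if (length(window) == 0) stop("empty analysis window")
  if (spec$kind %in% c("hbond", "salt_bridge")) {
    tri <- hbond_triplets(top, spec, params)
    present <- vapply(window, function(f) {
      frm <- traj$coords[f, , , drop = FALSE]
      dim(frm) <- dim(traj$coords)[2:3]
      hbond_frame_geom(frm, tri, params)
    }, logical(1))
    new_interaction_series(spec$label, spec$kind, present, window,
                           flags = if (params$heavy_only) "distance_only"
                                   else character(0))
  } else if (spec$kind == "hydrophobic_contact") {
    contact_persistence(traj, top, spec$a, spec$b, window = window,
                        label = spec$label, ...)
  } else {
    pi_stacking(traj, top, spec$a, spec$b, window = window,
                label = spec$label, ...)
  }
}

#' Hydrophobic-contact persistence between two atom groups
#'
#' A contact is present in a frame iff the minimum cross-group heavy-atom
#' distance is at most `cutoff`. This geometric proxy replaces force-field
#' interaction energies, which are out of scope.
#'
#' @param traj a [trajectory].
#' @param top matching [topology].
#' @param sel_a,sel_b atom selections (lists of [select_atoms()] args).
#' @param cutoff contact distance cutoff, Angstrom.
#' @param window frame indices (default all).
#' @param label label for the output series.
#' @return An `interaction_series`.
#' @export
contact_persistence <- function(traj, top, sel_a, sel_b, cutoff = 4.5,
                                window = NULL, label = "contact") {
  stopifnot(inherits(traj, "trajectory"))
  ia <- resolve_sel(top, sel_a, "group A", label)
  ib <- resolve_sel(top, sel_b, "group B", label)
  if (is.null(window)) window <- seq_len(traj$n_frames)
  if (length(window) == 0) stop("empty analysis window")
  present <- vapply(window, function(f) {
    A <- traj$coords[f, ia, , drop = FALSE]; dim(A) <- c(length(ia), 3)
    B <- traj$coords[f, ib, , drop = FALSE]; dim(B) <- c(length(ib), 3)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sqrt(max(0, min(d2))) <= cutoff
  }, logical(1))
  new_interaction_series(label, "hydrophobic_contact", present, window)
}

ring_geometry <- function(frame, idx, label) {
  X <- frame[idx, , drop = FALSE]
  centroid <- colMeans(X)
  Xc <- sweep(X, 2, centroid)
  sv <- svd(Xc)
  if (sv$d[2] < 1e-8)
    stop("ring '", label, "' is collinear: plane normal undefined")
  list(centroid = centroid, normal = sv$v[, 3])
}

#' Aromatic pi-stacking persistence between two rings
#'
#' Present in a frame iff the ring-centroid distance is at most
#' `d_centroid` and the acute angle between the best-fit ring planes is at
#' most `angle_max`. The defaults (5 Angstrom, 30 degrees) are pragmatic
#' stacking criteria, exposed as parameters.
#'
#' @param traj a [trajectory].
#' @param top matching [topology].
#' @param ring_a,ring_b ring atom selections (>= 3 atoms each).
#' @param d_centroid centroid distance cutoff, Angstrom.
#' @param angle_max maximum acute inter-plane angle, degrees.
#' @param window frame indices (default all).
#' @param label label for the output series.
#' @return An `interaction_series`.
#' @export
pi_stacking <- function(traj, top, ring_a, ring_b, d_centroid = 5.0,
                        angle_max = 30, window = NULL, label = "pi_stack") {
  stopifnot(inherits(traj, "trajectory"))
  ia <- resolve_sel(top, ring_a, "ring A", label)
  ib <- resolve_sel(top, ring_b, "ring B", label)
  if (length(ia) < 3 || length(ib) < 3)
    stop("pi-stacking rings need at least 3 atoms each ('", label, "')")
  if (is.null(window)) window <- seq_len(traj$n_frames)
  if (length(window) == 0) stop("empty analysis window")
  present <- vapply(window, function(f) {
    frm <- traj$coords[f, , , drop = FALSE]
    dim(frm) <- dim(traj$coords)[2:3]
    ga <- ring_geometry(frm, ia, label)
    gb <- ring_geometry(frm, ib, label)
    d <- sqrt(sum((ga$centroid - gb$centroid)^2))
    cosang <- abs(sum(ga$normal * gb$normal))
    ang <- acos(min(1, cosang)) * 180 / pi
    d <= d_centroid && ang <= angle_max
  }, logical(1))
  new_interaction_series(label, "pi_stack", present, window)
}

# built-in mechanistic signature list for one monomer chain; entries whose
# atoms are absent in the given topology are reported as not applicable
builtin_signatures <- function(ch) {
  sgn <- function(...) list(...)
  list(
    sgn(kind = "hbond", label = "E380-H377",
        a = list(chain = ch, resno = 377, name = c("ND1", "NE2")),
        h = list(chain = ch, resno = 377, name = c("HD1", "HE2")),
        b = list(chain = ch, resno = 380, name = c("OE1", "OE2"))),
    sgn(kind = "hbond", label = "D351-S537(OG)",
        a = list(chain = ch, resno = 537, name = "OG"),
        h = list(chain = ch, resno = 537, name = "HG"),
        b = list(chain = ch, resno = 351, name = c("OD1", "OD2"))),
    sgn(kind = "hbond", label = "E380-537(sidechain)",
        a = list(chain = ch, resno = 537, name = c("OG", "ND2", "OH")),
        h = list(chain = ch, resno = 537, name = c("HG", "HD21", "HH")),
        b = list(chain = ch, resno = 380, name = c("OE1", "OE2"))),
    sgn(kind = "hbond", label = "D351-bb537",
        a = list(chain = ch, resno = 537, name = "N"),
        h = list(chain = ch, resno = 537, name = "H"),
        b = list(chain = ch, resno = 351, name = c("OD1", "OD2"))),
    sgn(kind = "hbond", label = "D351-bb538",
        a = list(chain = ch, resno = 538, name = "N"),
        h = list(chain = ch, resno = 538, name = "H"),
        b = list(chain = ch, resno = 351, name = c("OD1", "OD2"))),
    sgn(kind = "hbond", label = "D351-bb539",
        a = list(chain = ch, resno = 539, name = "N"),
        h = list(chain = ch, resno = 539, name = "H"),
        b = list(chain = ch, resno = 351, name = c("OD1", "OD2"))),
    sgn(kind = "hbond", label = "D351-bb540",
        a = list(chain = ch, resno = 540, name = "N"),
        h = list(chain = ch, resno = 540, name = "H"),
        b = list(chain = ch, resno = 351, name = c("OD1", "OD2"))),
    sgn(kind = "hbond", label = "N348-536(O)",
        a = list(chain = ch, resno = 348, name = "ND2"),
        h = list(chain = ch, resno = 348, name = "HD21"),
        b = list(chain = ch, resno = 536, name = "O")),
    sgn(kind = "salt_bridge", label = "K529-D351",
        a = list(chain = ch, resno = 529, name = "NZ"),
        h = list(chain = ch, resno = 529, name = "HZ1"),
        b = list(chain = ch, resno = 351, name = c("OD1", "OD2"))),
    sgn(kind = "salt_bridge", label = "K531-E380",
        a = list(chain = ch, resno = 531, name = "NZ"),
        h = list(chain = ch, resno = 531, name = "HZ1"),
        b = list(chain = ch, resno = 380, name = c("OE1", "OE2"))),
    sgn(kind = "hydrophobic_contact", label = "536-pocket",
        a = list(chain = ch, resno = 536,
                 name = c("CD1", "CD2", "OE1", "NE2")),
        b = list(chain = ch, resno = c(383, 539, 540),
                 name = c("CZ2", "CH2", "CD1", "CD2"))),
    sgn(kind = "pi_stack", label = "Y537-H377",
        a = list(chain = ch, resno = 537,
                 name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
        b = list(chain = ch, resno = 377,
                 name = c("CG", "ND1", "CD2", "CE1", "NE2")))
  )
}

sel_resolves <- function(top, sel) {
  length(do.call(select_atoms,
                 c(list(top), sel, list(allow_empty = TRUE)))) > 0
}

#' Persistence panel of the built-in mechanistic signatures
#'
#' Evaluates, per monomer, the receptor's mechanistic interaction set:
#' the E380-H377 H-bond, the D351 contacts to the 537 side chain and to
#' the 537-540 backbone amides, the E380 contact of the mutated residue
#' 537, the N348-536 H-bond, the K529/K531 salt bridges, the hydrophobic
#' pocket around residue 536 (W383/L539/L540) and the Y537-H377
#' pi-stacking. Rows whose atoms are absent from the topology (e.g. the
#' serine Og in a non-Y537S isoform) are reported as not applicable
#' rather than 0%.
#'
#' @param top a [topology] (dimer or monomer).
#' @param traj matching [trajectory].
#' @param isoform,ligand labels echoed into the output table.
#' @param window frame indices (default all).
#' @param params [hbond_params].
#' @param extra optional list of additional [interaction_spec]s.
#' @return data.frame with columns `isoform`, `ligand`, `monomer`,
#'   `label`, `kind`, `persistence`, `n_frames`, `applicable`.
#' @export
signature_panel <- function(top, traj, isoform = "WT", ligand = NA,
                            window = NULL, params = hbond_params(),
                            extra = NULL) {
  stopifnot(inherits(top, "topology"), inherits(traj, "trajectory"))
  if (is.null(window)) window <- seq_len(traj$n_frames)
  rows <- list()
  for (ch in unique(top$atoms$chain)) {
    for (sg in builtin_signatures(ch)) {
      applicable <- sel_resolves(top, sg$a) && sel_resolves(top, sg$b) &&
        (is.null(sg$h) || sel_resolves(top, sg$h))
      if (applicable) {
        spec <- interaction_spec(sg$kind, sg$label, a = sg$a, b = sg$b,
                                 h = sg$h)
        ser <- persistence(traj, top, spec, params = params, window = window)
        pers <- ser$persistence
      } else {
        pers <- NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        isoform = isoform, ligand = ligand, monomer = ch,
        label = sg$label, kind = sg$kind, persistence = pers,
        n_frames = length(window), applicable = applicable,
        stringsAsFactors = FALSE)
    }
  }
  for (spec in extra) {
    stopifnot(inherits(spec, "interaction_spec"))
    ser <- persistence(traj, top, spec, params = params, window = window)
    rows[[length(rows) + 1]] <- data.frame(
      isoform = isoform, ligand = ligand, monomer = NA,
      label = spec$label, kind = spec$kind, persistence = ser$persistence,
      n_frames = length(window), applicable = TRUE,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
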