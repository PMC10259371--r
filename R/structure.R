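#' Atomic structure container
#'
#' A point-atom model: an m x 3 coordinate matrix in Angstrom with per-atom
#' electron counts.  Atom ordering is fixed and shared across an ensemble.
#'
#' @param coords m x 3 numeric matrix of positions (Angstrom).
#' @param weights Length-m positive numeric vector of electron counts.
#'   A scalar is recycled.
#' @param labels Optional character vector of atom labels.
#' @return An object of class `atomic_structure`.
#' @export
atomic_structure <- function(coords, weights = 6, labels = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) < 1) {
    stop_invalid("coords must be an m x 3 matrix with m > 0")
  }
  if (!all(is.finite(coords))) stop_invalid("coordinates must be finite")
  m <- nrow(coords)
  weights <- rep_len(as.numeric(weights), m)
  if (any(weights <= 0)) stop_invalid("weights must be positive")
  if (is.null(labels)) labels <- rep("X", m)
  structure(list(coords = coords, weights = weights,
                 labels = rep_len(labels, m)),
            class = "atomic_structure")
}

#' @export
print.atomic_structure <- function(x, ...) {
  cat(sprintf("atomic_structure: %d atoms, total electrons %.1f\n",
              nrow(x$coords), sum(x$weights)))
  invisible(x)
}

#' Toy two-arm molecule
#'
#' Builds a V-shaped point-atom molecule with two arm domains and a small
#' base, mimicking a chaperone-like protein whose two arm domains swing
#' about hinge residues.  The arms are asymmetric (different lengths) so
#' that the two conformational motions remain distinguishable in
#' projections.  Each arm is a slightly bowed arc of pseudo-atoms with
#' carbon-like weights.
#'
#' Arm A opens in the x-z plane toward +x; arm B toward -x but tilted so
#' its hinge rotation (about the x axis) sweeps the y-z plane.  The base
#' extends below the hinge point along -z.
#'
#' @param arm_atoms Atoms per arm (>= 3).
#' @param base_atoms Atoms in the base (>= 1).
#' @param arm_lengths Length-2 vector of arm lengths in Angstrom.
#' @param vee_angle Full opening angle of the V in degrees.
#' @param bow Out-of-line bow of each arm at mid-span, Angstrom.
#' @return An `atomic_structure` with labels `"armA"`, `"armB"`, `"base"`.
#' @examples
#' mol <- make_toy_two_arm()
#' table(mol$labels)
#' @export
make_toy_two_arm <- function(arm_atoms = 12, base_atoms = 6,
                             arm_lengths = c(30, 24), vee_angle = 60,
                             bow = 2) {
  if (arm_atoms < 3 || base_atoms < 1) {
    stop_invalid("need arm_atoms >= 3 and base_atoms >= 1")
  }
  if (any(arm_lengths <= 0)) stop_invalid("arm lengths must be positive")
  half <- deg2rad(vee_angle / 2)
  arm <- function(len, dir, perp) {
    t <- seq_len(arm_atoms) / arm_atoms * len
    sweep2 <- outer(t, dir) + outer(bow * t * (len - t) / len^2 * 4, perp)
    sweep2
  }
  dA <- c(sin(half), 0, cos(half))
  dB0 <- c(-sin(half), 0, cos(half))
  # tilt arm B slightly out of the x-z plane so the two motion planes differ
  tilt <- deg2rad(20)
  dB <- c(dB0[1], sin(tilt) * dB0[3], cos(tilt) * dB0[3])
  dB <- dB / sqrt(sum(dB^2))
  pA <- arm(arm_lengths[1], dA, c(0, 1, 0))
  pB <- arm(arm_lengths[2], dB, c(0, 0, 1) - dB * dB[3])
  pBase <- cbind(0, 0, -(seq_len(base_atoms)) * 1.5)
  coords <- rbind(pA, pB, pBase)
  labels <- c(rep("armA", arm_atoms), rep("armB", arm_atoms),
              rep("base", base_atoms))
  atomic_structure(coords, weights = 6, labels = labels)
}

#' Hinge specification for a rigid-domain rotation
#'
#' @param domain Integer vector of atom indices forming the rigid domain.
#' @param pivot Length-3 pivot point (Angstrom).
#' @param axis Length-3 rotation axis; normalized internally and must be
#'   non-degenerate.
#' @param max_angle Sweep range in degrees (default 28.5, inside the
#'   moderate-rotation regime where inter-state distance is nearly linear
#'   in angle).
#' @param steps Number of equispaced states along the sweep (>= 1).
#' @return An object of class `hinge_spec`.
#' @export
hinge_spec <- function(domain, pivot, axis, max_angle = 28.5, steps = 20) {
  domain <- as.integer(domain)
  if (length(domain) < 1 || any(domain < 1)) {
    stop_invalid("domain must be a non-empty set of positive atom indices")
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop_invalid("hinge axis must be nonzero")
  if (steps < 1) stop_invalid("steps must be >= 1")
  structure(list(domain = domain, pivot = as.numeric(pivot),
                 axis = as.numeric(axis) / nrm,
                 max_angle = max_angle, steps = as.integer(steps)),
            class = "hinge_spec")
}

#' Default hinges of the toy two-arm molecule
#'
#' CM_1 swings arm A about the y axis (motion in the x-z plane); CM_2
#' swings arm B about the x axis (motion in the y-z plane).  Both pivots
#' sit at the arm roots (the origin).
#'
#' @param structure A toy molecule from [make_toy_two_arm()].
#' @param max_angle,steps Sweep range (degrees) and step count per hinge.
#' @return List of two `hinge_spec` objects.
#' @export
toy_hinges <- function(structure, max_angle = 28.5, steps = 20) {
  list(
    hinge_spec(which(structure$labels == "armA"), c(0, 0, 0), c(0, 1, 0),
               max_angle, steps),
    hinge_spec(which(structure$labels == "armB"), c(0, 0, 0), c(1, 0, 0),
               max_angle, steps)
  )
}

# Rodrigues rotation matrix for unit axis u and angle (radians)
rotation_matrix <- function(u, angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c_ + s_ * ux + (1 - c_) * tcrossprod(u)
}

#' Rotate a rigid domain about its hinge
#'
#' Applies a rigid rotation by `angle` degrees about the hinge axis through
#' the pivot to the atoms in the hinge's domain; all other atoms are
#' unchanged.
#'
#' @param structure An `atomic_structure`.
#' @param hinge A `hinge_spec`.
#' @param angle Rotation angle in degrees.
#' @return The rotated `atomic_structure`.
#' @export
rotate_domain <- function(structure, hinge, angle) {
  m <- nrow(structure$coords)
  if (any(hinge$domain > m)) {
    stop_invalid("hinge domain refers to atoms beyond m = %d", m)
  }
  R <- rotation_matrix(hinge$axis, deg2rad(angle))
  sel <- hinge$domain
  x <- structure$coords[sel, , drop = FALSE]
  x <- sweep(x, 2, hinge$pivot)
  structure$coords[sel, ] <- sweep(x %*% t(R), 2, hinge$pivot, "+")
  structure
}

#' Sweep a state space of hinge rotations
#'
#' Exercises 1-3 hinge motions independently in all combinations of
#' equispaced angles from 0 to each hinge's `max_angle` inclusive,
#' producing `M_n = prod(steps)` conformers.  Ordering is CM_1-major (the
#' first hinge's index varies slowest), so for two 20-step hinges the CM_2
#' ground-truth sequence is states {1, 21, 41, ...} etc.
#'
#' @param base An `atomic_structure`; the state at all-zero angles equals
#'   `base` exactly.
#' @param hinges List of 1-3 `hinge_spec` objects with pairwise disjoint
#'   domains.
#' @return An object of class `conformer_ensemble` with `structures`
#'   (list), `cm_coords` (M x n matrix of 0-based step indices), `angles`
#'   (M x n, degrees), `base`, `hinges`.
#' @examples
#' mol <- make_toy_two_arm()
#' ens <- sweep_state_space(mol, toy_hinges(mol, steps = 4))
#' length(ens$structures)  # 16
#' @export
sweep_state_space <- function(base, hinges) {
  n <- length(hinges)
  if (n < 1 || n > 3) stop_invalid("need 1-3 hinges (got %d)", n)
  doms <- lapply(hinges, `[[`, "domain")
  if (n > 1) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (length(intersect(doms[[a]], doms[[b]]))) {
        stop_invalid("hinge domains %d and %d overlap", a, b)
      }
    }
  }
  steps <- vapply(hinges, `[[`, integer(1), "steps")
  idx_ax <- lapply(steps, function(s) seq_len(s) - 1L)
  cm <- as.matrix(expand.grid(rev(idx_ax), KEEP.OUT.ATTRS = FALSE))
  cm <- matrix(as.integer(cm[, rev(seq_len(n))]),
               ncol = n, dimnames = list(NULL, paste0("cm", seq_len(n))))
  ang <- vapply(seq_len(n), function(g) {
    inc <- if (steps[g] > 1) hinges[[g]]$max_angle / (steps[g] - 1) else 0
    cm[, g] * inc
  }, numeric(nrow(cm)))
  ang <- matrix(ang, ncol = n)
  structures <- lapply(seq_len(nrow(cm)), function(i) {
    s <- base
    for (g in seq_len(n)) {
      if (ang[i, g] != 0) s <- rotate_domain(s, hinges[[g]], ang[i, g])
    }
    s
  })
  structure(list(structures = structures, cm_coords = cm, angles = ang,
                 base = base, hinges = hinges, mask = "full"),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("conformer_ensemble: %d states, %d CMs, %d atoms each\n",
              length(x$structures), ncol(x$cm_coords),
              nrow(x$base$coords)))
  invisible(x)
}

#' Flatten an ensemble into a state-by-coordinate matrix
#'
#' @param ensemble A `conformer_ensemble`.
#' @return M x (3m) matrix; row i is state i's coordinates, atom-major.
#' @export
ensemble_matrix <- function(ensemble) {
  t(vapply(ensemble$structures, function(s) as.numeric(t(s$coords)),
           numeric(3 * nrow(ensemble$base$coords))))
}

# electrons per element for PDB-derived weights
.element_electrons <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16,
                        NA. = 11, MG = 12, CL = 17, K = 19, CA = 20,
                        MN = 25, FE = 26, ZN = 30, SE = 34)

#' Read an atomic structure from a PDB file
#'
#' Reads ATOM/HETATM records and assigns per-atom electron counts from a
#' built-in element table.
#'
#' @param path Path to a PDB file.
#' @return An `atomic_structure`.
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  el <- toupper(trimws(pdb$atom$elesy))
  el[el == "NA"] <- "NA."
  w <- .element_electrons[el]
  if (anyNA(w)) {
    bad <- unique(el[is.na(w)])
    stop_invalid("unknown element label(s): %s", paste(bad, collapse = ", "))
  }
  atomic_structure(cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z),
                   weights = as.numeric(w), labels = pdb$atom$elety)
}

#' Write an atomic structure to a PDB file
#'
#' Atoms are written as carbon ATOM records (the toy molecule uses
#' pseudo-atoms); coordinates round-trip at the format's 1e-3 Angstrom
#' precision.
#'
#' @param structure An `atomic_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  m <- nrow(structure$coords)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(structure$coords)),
                   type = rep("ATOM", m),
                   resno = seq_len(m),
                   resid = rep("GLY", m),
                   elety = rep("CA", m),
                   chain = rep("A", m),
                   elesy = rep("C", m))
  invisible(path)
}

#' Write an ensemble manifest
#'
#' JSON listing per-state CM step indices, angles and (optionally) file
#' paths of written PDB structures.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param path Output JSON path.
#' @param pdb_dir If non-NULL, also write one PDB per state into this
#'   directory and record the paths.
#' @return The manifest list, invisibly.
#' @export
write_ensemble_manifest <- function(ensemble, path, pdb_dir = NULL) {
  M <- length(ensemble$structures)
  files <- rep(NA_character_, M)
  if (!is.null(pdb_dir)) {
    dir.create(pdb_dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(pdb_dir, sprintf("state_%04d.pdb", seq_len(M)))
    for (i in seq_len(M)) write_pdb(ensemble$structures[[i]], files[i])
  }
  manifest <- list(
    n_states = M,
    n_cms = ncol(ensemble$cm_coords),
    states = lapply(seq_len(M), function(i) list(
      index = i,
      cm_coords = as.integer(ensemble$cm_coords[i, ]),
      angles_deg = as.numeric(ensemble$angles[i, ]),
      path = if (is.na(files[i])) NULL else files[i]
    ))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
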