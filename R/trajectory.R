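# Trajectory container: coordinates in nm, times in ps, atom table with
# author residue numbers and van der Waals radii.  PDB parsing/writing is
# delegated to bio3d; everything downstream works on this container only.

# Bondi van der Waals radii, nm
.vdw_radii <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152,
                S = 0.180, P = 0.180)
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974)

#' Construct a trajectory object
#'
#' @param coords Numeric array `frames x atoms x 3`, nanometres.
#' @param atoms Data frame with columns `name` (PDB atom name), `element`,
#'   `resno` (author residue number), `resname` (3-letter or 1-letter code).
#'   A `radius` column (nm) is added from the Bondi table if absent.
#' @param times Per-frame time stamps in ps (default `0, 1, ...`).
#' @return An object of class `reg_traj`.
#' @export
trajectory <- function(coords, atoms, times = NULL) {
  if (length(dim(coords)) == 2L)
    coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L,
            dim(coords)[2] == nrow(atoms))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (is.null(times)) times <- seq_len(dim(coords)[1]) - 1
  stopifnot(length(times) == dim(coords)[1])
  if (is.null(atoms$radius)) {
    known <- atoms$element %in% names(.vdw_radii)
    if (!all(known)) {
      warning("unknown element(s) ",
              paste(unique(atoms$element[!known]), collapse = ", "),
              "; using default radius 0.170 nm")
    }
    atoms$radius <- ifelse(known, .vdw_radii[atoms$element], 0.170)
  }
  if (is.null(atoms$mass)) {
    atoms$mass <- ifelse(atoms$element %in% names(.atomic_mass),
                         .atomic_mass[atoms$element], 12.011)
  }
  structure(list(coords = coords, atoms = atoms, times = as.numeric(times)),
            class = "reg_traj")
}

#' @export
print.reg_traj <- function(x, ...) {
  cat(sprintf("reg_traj: %d frame(s), %d atoms, residues %s-%s\n",
              n_frames(x), n_atoms(x),
              min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `reg_traj`.
#' @return Integer.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Number of atoms in a trajectory
#' @param traj A `reg_traj`.
#' @return Integer.
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Coordinates of one frame
#' @param traj A `reg_traj`.
#' @param i Frame index.
#' @return `atoms x 3` matrix (nm).
#' @export
frame_coords <- function(traj, i = 1L) {
  matrix(traj$coords[i, , ], ncol = 3L)
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' Each MODEL record becomes one frame.  Coordinates are converted from
#' Angstrom to nm; Bondi radii are attached by element at read time.
#'
#' @param path Path to a (multi-model) PDB file.
#' @param topology Optional `reg_topology`; if given, atom residue numbers
#'   are checked against it.
#' @param dt Time spacing between models, ps (default 1).
#' @return A `reg_traj`.
#' @export
read_ensemble <- function(path, topology = NULL, dt = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nat <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * nat)
    stop("atom count mismatch across MODEL records in ", path)
  el <- pdb$atom$elesy
  if (is.null(el) || all(!nzchar(trimws(el))))
    el <- substr(trimws(pdb$atom$elety), 1L, 1L)
  el <- trimws(el)
  atoms <- data.frame(
    name = trimws(pdb$atom$elety),
    element = el,
    resno = pdb$atom$resno,
    resname = trimws(pdb$atom$resid),
    stringsAsFactors = FALSE
  )
  if (!is.null(topology)) {
    extra <- setdiff(atoms$resno, topology$author_number)
    if (length(extra) > 0L)
      stop("atoms reference residues absent from topology: ",
           paste(unique(extra), collapse = ", "))
  }
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, nat, 3L))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
  }
  trajectory(coords, atoms, times = (seq_len(nf) - 1) * dt)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param traj A `reg_traj`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(traj, path) {
  nf <- n_frames(traj)
  nat <- n_atoms(traj)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * nat)
  for (f in seq_len(nf)) {
    xyz[f, ] <- as.numeric(t(frame_coords(traj, f))) * 10
  }
  resname <- traj$atoms$resname
  long <- nchar(resname) == 1L
  resname[long] <- .aa3[resname[long]]
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nat),
    resno = traj$atoms$resno,
    resid = resname,
    eleno = seq_len(nat),
    elety = traj$atoms$name,
    elesy = traj$atoms$element,
    chain = rep("A", nat)
  )
  invisible(path)
}

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

#' Select atoms and/or frames from a trajectory
#'
#' Subsets preserve atom order and compose: two successive selections are
#' equivalent to their conjunction.
#'
#' @param traj A `reg_traj`.
#' @param name Optional atom-name filter (character vector).
#' @param resno Optional author residue numbers to keep.
#' @param element Optional element filter.
#' @param frames Optional frame indices to keep.
#' @param stride Optional integer: keep every `stride`-th frame.
#' @return A `reg_traj` view.
#' @export
select_atoms <- function(traj, name = NULL, resno = NULL, element = NULL,
                         frames = NULL, stride = NULL) {
  keep <- rep(TRUE, n_atoms(traj))
  if (!is.null(name)) keep <- keep & traj$atoms$name %in% name
  if (!is.null(resno)) keep <- keep & traj$atoms$resno %in% resno
  if (!is.null(element)) keep <- keep & traj$atoms$element %in% element
  if (!any(keep)) stop("selection matches no atoms")
  fidx <- seq_len(n_frames(traj))
  if (!is.null(frames)) fidx <- fidx[fidx %in% frames]
  if (!is.null(stride)) fidx <- fidx[seq(1L, length(fidx), by = stride)]
  if (length(fidx) == 0L) stop("selection keeps no frames")
  trajectory(traj$coords[fidx, keep, , drop = FALSE],
             traj$atoms[keep, , drop = FALSE],
             times = traj$times[fidx])
}

#' Export a per-frame series as CSV
#'
#' @param series A `frame_series` (see [frame_series()]) or plain numeric
#'   vector.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  df <- data.frame(frame = seq_along(series),
                   value = as.numeric(series))
  lbl <- attr(series, "label")
  if (!is.null(lbl)) names(df)[2] <- lbl
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
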