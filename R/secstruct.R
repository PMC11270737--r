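# Kabsch-Sander secondary-structure assignment extended with a
# polyproline-II class (P) and a phosphorylated-residue class (X).
# Alphabet: H/G/I helices, E/B strands/bridges, T turn, S bend, P PPII,
# ~ coil, X phosphosite.

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic model of the CO...HN interaction:
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol with
#' distances in Angstrom; a hydrogen bond is assigned when
#' `E < -0.5` kcal/mol.
#'
#' @param r_on,r_ch,r_oh,r_cn Distances O-N, C-H, O-H, C-N in Angstrom.
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' ks_hbond_energy(2.9, 3.2, 1.9, 3.9)  # about -3.50
ks_hbond_energy <- function(r_on, r_ch, r_oh, r_cn) {
  0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Backbone atom indices per residue; amide H reconstructed at 0.1 nm along
# the reversed bisector when no H atom is present (prolines and the first
# residue have no donor).
.backbone_index <- function(traj) {
  resnos <- sort(unique(traj$atoms$resno))
  pick <- function(rn, nm) {
    i <- which(traj$atoms$resno == rn & traj$atoms$name == nm)
    if (length(i) == 0L) NA_integer_ else i[1L]
  }
  list(resnos = resnos,
       N = vapply(resnos, pick, integer(1), nm = "N"),
       CA = vapply(resnos, pick, integer(1), nm = "CA"),
       C = vapply(resnos, pick, integer(1), nm = "C"),
       O = vapply(resnos, pick, integer(1), nm = "O"),
       H = vapply(resnos, pick, integer(1), nm = "H"),
       code = vapply(resnos, function(rn)
         traj$atoms$resname[traj$atoms$resno == rn][1L], character(1)))
}

.reconstruct_h <- function(x, bb, r) {
  # r >= 2; bisector of N->C(prev) and N->CA, reversed, 0.1 nm
  N <- x[bb$N[r], ]
  u <- -(.unit(x[bb$C[r - 1L], ] - N) + .unit(x[bb$CA[r], ] - N))
  N + .unit(u) * 0.1
}

# Hydrogen-bond matrix for one frame: hb[i, j] TRUE when CO(i) accepts
# from NH(j).  |i - j| < 2 excluded.
.hbond_matrix <- function(x, bb) {
  n <- length(bb$resnos)
  Hpos <- matrix(NA_real_, n, 3L)
  for (r in 2:n) {
    code <- bb$code[r]
    if (code %in% c("P", "PRO")) next
    Hpos[r, ] <- if (!is.na(bb$H[r])) x[bb$H[r], ] else
      .reconstruct_h(x, bb, r)
  }
  Cx <- x[bb$C, , drop = FALSE]
  Ox <- x[bb$O, , drop = FALSE]
  Nx <- x[bb$N, , drop = FALSE]
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L || is.na(Hpos[j, 1L])) next
      # fast CA-CA prefilter (9 A as in canonical implementations)
      dca <- x[bb$CA[i], ] - x[bb$CA[j], ]
      if (sum(dca * dca) > 0.81) next
      r_on <- .vnorm(Ox[i, ] - Nx[j, ]) * 10
      r_ch <- .vnorm(Cx[i, ] - Hpos[j, ]) * 10
      r_oh <- .vnorm(Ox[i, ] - Hpos[j, ]) * 10
      r_cn <- .vnorm(Cx[i, ] - Nx[j, ]) * 10
      hb[i, j] <- ks_hbond_energy(r_on, r_ch, r_oh, r_cn) < -0.5
    }
  }
  hb
}

#' Backbone hydrogen-bond energy between two residues in a frame
#'
#' CO of the acceptor residue against NH of the donor residue, with the
#' amide H reconstructed when absent.
#'
#' @param traj A `reg_traj`.
#' @param donor,acceptor Author residue numbers (donor provides NH,
#'   acceptor provides CO).
#' @param frame Frame index.
#' @return Energy in kcal/mol (`Inf` when the donor has no amide H, i.e.
#'   proline or the chain start).
#' @export
hbond_energy <- function(traj, donor, acceptor, frame = 1L) {
  bb <- .backbone_index(traj)
  x <- frame_coords(traj, frame)
  i <- match(acceptor, bb$resnos)
  j <- match(donor, bb$resnos)
  stopifnot(!is.na(i), !is.na(j))
  if (j == 1L || bb$code[j] %in% c("P", "PRO")) return(Inf)
  Hj <- if (!is.na(bb$H[j])) x[bb$H[j], ] else .reconstruct_h(x, bb, j)
  ks_hbond_energy(.vnorm(x[bb$O[i], ] - x[bb$N[j], ]) * 10,
                  .vnorm(x[bb$C[i], ] - Hj) * 10,
                  .vnorm(x[bb$O[i], ] - Hj) * 10,
                  .vnorm(x[bb$C[i], ] - x[bb$N[j], ]) * 10)
}

# Assign one frame given the hbond matrix and dihedrals
.assign_frame <- function(hb, phi, psi, ca, ppii_tol = 29) {
  n <- nrow(hb)
  code <- rep("~", n)
  turn <- function(k) {
    t <- rep(FALSE, n)
    if (n > k) for (i in seq_len(n - k)) t[i] <- hb[i, i + k]
    t
  }
  t3 <- turn(3L); t4 <- turn(4L); t5 <- turn(5L)

  # bends: CA(i-2)->CA(i) vs CA(i)->CA(i+2) kink > 70 degrees
  if (n >= 5L) for (i in 3:(n - 2L)) {
    u <- ca[i, ] - ca[i - 2L, ]
    v <- ca[i + 2L, ] - ca[i, ]
    ang <- acos(max(-1, min(1, sum(.unit(u) * .unit(v))))) * 180 / pi
    if (ang > 70) code[i] <- "S"
  }
  # turns: interior residues of any n-turn
  for (k in c(3L, 4L, 5L)) {
    tk <- turn(k)
    for (i in which(tk)) {
      rng <- (i + 1L):(i + k - 1L)
      code[rng[code[rng] %in% c("~", "S")]] <- "T"
    }
  }
  # PPII: runs >= 2 inside +-tol of (-75, 145), lower priority than
  # helices/strands which overwrite below
  inp <- !is.na(phi) & !is.na(psi) &
    abs(wrap_angle(phi - (-75))) <= ppii_tol &
    abs(wrap_angle(psi - 145)) <= ppii_tol
  r <- rle(inp)
  ends <- cumsum(r$lengths)
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= 2L) {
      code[(ends[k] - r$lengths[k] + 1L):ends[k]] <- "P"
    }
  }
  # 5-turn (pi) helix: two consecutive 5-turns
  if (n >= 7L) for (i in 2:(n - 5L)) if (t5[i - 1L] && t5[i])
    code[i:(i + 4L)] <- "I"
  # 3-turn (3-10) helix
  if (n >= 5L) for (i in 2:(n - 3L)) if (t3[i - 1L] && t3[i])
    code[i:(i + 2L)] <- "G"
  # bridges / ladders
  bridge <- matrix(FALSE, n, n)
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L) next
      par <- (hb[i - 1L, j] && hb[j, i + 1L]) ||
        (hb[j - 1L, i] && hb[i, j + 1L])
      anti <- (hb[i, j] && hb[j, i]) ||
        (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (par || anti) bridge[i, j] <- TRUE
    }
  }
  has_bridge <- apply(bridge, 1L, any)
  for (i in which(has_bridge)) {
    js <- which(bridge[i, ])
    ladder <- any(vapply(js, function(j) {
      (i < n && any(bridge[i + 1L, c(j - 1L, j + 1L)[c(j - 1L, j + 1L) >= 1 &
                                       c(j - 1L, j + 1L) <= n]])) ||
        (i > 1L && any(bridge[i - 1L, c(j - 1L, j + 1L)[c(j - 1L, j + 1L) >= 1 &
                                         c(j - 1L, j + 1L) <= n]]))
    }, logical(1)))
    code[i] <- if (ladder) "E" else "B"
  }
  # 4-turn (alpha) helix, top priority
  if (n >= 6L) for (i in 2:(n - 4L)) if (t4[i - 1L] && t4[i])
    code[i:(i + 3L)] <- "H"
  code
}

#' Assign secondary structure for every frame
#'
#' Kabsch-Sander hydrogen-bond patterns give H/G/I helices and E/B
#' strand/bridge states; T marks turn interiors, S bends (CA kink > 70
#' degrees), and P marks polyproline-II runs (two or more consecutive
#' residues within +-29 degrees of (-75, 145)) not already claimed by a
#' helix or strand.  Phosphorylated residues are reported as their own
#' class X regardless of conformation.
#'
#' @param traj A `reg_traj` with backbone atoms.
#' @param topology Optional `reg_topology` supplying phosphosite flags.
#' @param ppii_tol Half-width (degrees) of the PPII dihedral window.
#' @return An `ss_assignment`: `frames x residues` character matrix,
#'   columns named by author residue number.
#' @export
assign_secstruct <- function(traj, topology = NULL, ppii_tol = 29) {
  bb <- .backbone_index(traj)
  n <- length(bb$resnos)
  if (n < 3L) {
    out <- matrix("~", n_frames(traj), n,
                  dimnames = list(NULL, bb$resnos))
    return(structure(out, class = c("ss_assignment", "matrix")))
  }
  dih <- compute_dihedrals(traj)
  nf <- n_frames(traj)
  out <- matrix("~", nf, n, dimnames = list(NULL, bb$resnos))
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    hb <- .hbond_matrix(x, bb)
    out[f, ] <- .assign_frame(hb, dih$phi[f, ], dih$psi[f, ],
                              x[bb$CA, , drop = FALSE], ppii_tol)
  }
  if (!is.null(topology)) {
    px <- as.character(topology$author_number[topology$is_phosphorylated])
    out[, colnames(out) %in% px] <- "X"
  }
  structure(out, class = c("ss_assignment", "matrix"))
}

#' Secondary-structure composition percentages
#'
#' Percentages over all residues and frames, either per code or folded
#' into the report classes Coils (~), Bridges (E+B), Helices (H+G+I),
#' PPII (P), Bend (S), Turn (T) and Phos. (X).  Classes sum to 100.
#'
#' @param assignment An `ss_assignment`.
#' @param by `"class"` (report table classes, default) or `"code"`.
#' @return Named numeric percentages.
#' @export
ss_composition <- function(assignment, by = c("class", "code")) {
  by <- match.arg(by)
  codes <- c("H", "G", "I", "E", "B", "T", "S", "P", "~", "X")
  tab <- table(factor(assignment, levels = codes))
  pct <- 100 * as.numeric(tab) / length(assignment)
  names(pct) <- codes
  if (by == "code") return(pct)
  c(Coils = unname(pct["~"]),
    Bridges = unname(pct["E"] + pct["B"]),
    Helices = unname(pct["H"] + pct["G"] + pct["I"]),
    PPII = unname(pct["P"]),
    Bend = unname(pct["S"]),
    Turn = unname(pct["T"]),
    Phos. = unname(pct["X"]))
}

#' Per-residue fraction of frames in a structure code
#'
#' @param assignment An `ss_assignment`.
#' @param code Single structure code (or class name as in
#'   [ss_composition()]).
#' @return Named numeric vector (one fraction in `[0, 1]` per residue).
#' @export
per_residue_fraction <- function(assignment, code) {
  class_map <- list(Coils = "~", Bridges = c("E", "B"),
                    Helices = c("H", "G", "I"), PPII = "P",
                    Bend = "S", Turn = "T", Phos. = "X")
  codes <- if (code %in% names(class_map)) class_map[[code]] else code
  colMeans(matrix(assignment %in% codes, nrow = nrow(assignment),
                  dimnames = dimnames(assignment)))
}

#' Flat-file export of per-frame structure strings
#'
#' @param assignment An `ss_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss_flat <- function(assignment, path) {
  lines <- apply(assignment, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}
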