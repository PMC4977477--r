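# Residues treated as hydrophobic when deriving per-residue flags.
.HYDROPHOBIC <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "CYS")

#' Construct a protein topology
#'
#' An immutable description of a protein chain modelled as a phi/psi torsional
#' linkage: the sequence, per-residue hydrophobicity flags, the native torsion
#' vector, and the native secondary-structure segments. Only the 2n backbone
#' torsions are flexible; bond lengths and angles are ideal constants.
#'
#' @param sequence character vector of three-letter residue codes (length n,
#'   n >= 2).
#' @param native_torsions numeric vector of 2n angles in degrees, residue-major
#'   (phi_1, psi_1, phi_2, psi_2, ...). Normalized to (-180, 180] on input.
#'   Terminal residues have no phi (first) or psi (last) dihedral; store the
#'   placeholder 180 there — those two positions are excluded from
#'   perturbation.
#' @param segments data frame with columns \code{label}, \code{kind}
#'   (\code{"helix"} or \code{"strand"}), \code{start}, \code{end} — 0-based
#'   half-open residue ranges, non-overlapping, within \code{[0, n)}. May be
#'   empty.
#' @param hydrophobic optional logical vector of length n; when \code{NULL},
#'   derived from the sequence using a standard hydrophobic residue table
#'   (ALA, VAL, LEU, ILE, MET, PHE, TRP, CYS).
#' @return An object of class \code{"protein_topology"}.
#' @export
#' @examples
#' topo <- protein_topology(rep("ALA", 4), rep(c(-57, -47), 4))
#' topo$n
protein_topology <- function(sequence, native_torsions, segments = NULL,
                             hydrophobic = NULL) {
  sequence <- toupper(as.character(sequence))
  n <- length(sequence)
  if (n < 2L) stop("a chain needs at least 2 residues")
  if (length(native_torsions) != 2L * n)
    stop(sprintf("native_torsions has length %d, expected 2n = %d",
                 length(native_torsions), 2L * n))
  if (is.null(hydrophobic)) hydrophobic <- sequence %in% .HYDROPHOBIC
  stopifnot(is.logical(hydrophobic), length(hydrophobic) == n)
  if (is.null(segments)) {
    segments <- data.frame(label = character(), kind = character(),
                           start = integer(), end = integer())
  }
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (nrow(segments)) {
    stopifnot(all(c("label", "kind", "start", "end") %in% names(segments)))
    if (!all(segments$kind %in% c("helix", "strand")))
      stop("segment kind must be 'helix' or 'strand'")
    if (any(segments$start < 0L) || any(segments$end > n) ||
        any(segments$start >= segments$end))
      stop("segments must be non-empty 0-based half-open ranges within [0, n)")
    seg <- segments[order(segments$start), , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$end[-nrow(seg)] > seg$start[-1L]))
      stop("segments overlap")
    segments <- seg
    rownames(segments) <- NULL
  }
  obj <- list(sequence = sequence, n = n,
              hydrophobic = hydrophobic,
              native_torsions = normalize_angle(native_torsions),
              segments = segments)
  class(obj) <- "protein_topology"
  obj
}

#' @export
print.protein_topology <- function(x, ...) {
  cat(sprintf("Protein topology: %d residues, %d flexible torsions\n",
              x$n, 2L * x$n - 2L))
  cat(sprintf("  hydrophobic residues: %d\n", sum(x$hydrophobic)))
  if (nrow(x$segments)) {
    for (i in seq_len(nrow(x$segments)))
      cat(sprintf("  segment %s: %s [%d, %d)\n", x$segments$label[i],
                  x$segments$kind[i], x$segments$start[i], x$segments$end[i]))
  } else cat("  no native segments annotated\n")
  invisible(x)
}

# Torsion indices (1-based into the 2n vector) that may be perturbed:
# everything except the undefined terminal phi_1 and psi_n placeholders.
flexible_torsion_indices <- function(topo) {
  setdiff(seq_len(2L * topo$n), c(1L, 2L * topo$n))
}

#' Construct a conformation
#'
#' A point in the 2n-dimensional torsion space, with optional cached energy.
#'
#' @param torsions numeric vector of 2n angles (degrees); normalized on input.
#' @param id unique character tag within a roadmap.
#' @param energy cached potential energy in kJ/mol (\code{NA} when unset;
#'   \code{Inf} marks an infeasible conformation).
#' @return An object of class \code{"conformation"}.
#' @export
conformation <- function(torsions, id, energy = NA_real_) {
  stopifnot(is.numeric(torsions), length(torsions) >= 4L,
            length(torsions) %% 2L == 0L)
  structure(list(id = as.character(id),
                 torsions = normalize_angle(torsions),
                 energy = energy),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("Conformation %s (%d torsions, energy %s)\n", x$id,
              length(x$torsions),
              if (is.na(x$energy)) "unset" else format(x$energy)))
  invisible(x)
}

#' Realize a conformation as 3-D coordinates
#'
#' Places the 6 atoms of every residue (N, H, CA, CB, C, O; glycine carries HA
#' in the CB slot) from ideal internal coordinates and the conformation's
#' phi/psi torsions, with the peptide bond held trans. The first residue is
#' laid down in a canonical frame (N at the origin, CA on +x, C in the
#' xy-plane), so coordinates are deterministic: identical torsions give
#' bitwise-identical output. Non-superposed RMSD between two realizations is
#' only meaningful through \code{\link{lrmsd}}.
#'
#' @param topo a \code{\link{protein_topology}}.
#' @param conf a \code{\link{conformation}} with 2n torsions (or a bare
#'   numeric torsion vector).
#' @return A 6n x 3 numeric matrix of class \code{"coordinate_set"} with
#'   attributes \code{atom} (atom names) and \code{residue} (1-based residue
#'   index per atom).
#' @export
#' @examples
#' topo <- protein_topology(rep("ALA", 3), rep(c(-57, -47), 3))
#' xyz <- forward_kinematics(topo, topo$native_torsions)
#' dim(xyz)
forward_kinematics <- function(topo, conf) {
  tors <- if (inherits(conf, "conformation")) conf$torsions else conf
  n <- topo$n
  if (length(tors) != 2L * n)
    stop(sprintf("torsion vector has length %d, expected %d",
                 length(tors), 2L * n))
  g <- .GEOM
  phi <- tors[seq(1L, 2L * n, by = 2L)]
  psi <- tors[seq(2L, 2L * n, by = 2L)]
  N <- CA <- C <- matrix(0, n, 3L)
  # canonical frame for residue 1
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_N_CA, 0, 0)
  th <- (180 - g$a_N_CA_C) * pi / 180
  C[1L, ] <- CA[1L, ] + g$b_CA_C * c(cos(th), sin(th), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                               g$b_C_N, g$a_CA_C_N, psi[i])
    CA[i + 1L, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1L, ],
                                g$b_N_CA, g$a_C_N_CA, g$omega)
    C[i + 1L, ] <- .place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                               g$b_CA_C, g$a_N_CA_C, phi[i + 1L])
  }
  xyz <- matrix(0, 6L * n, 3L)
  for (i in seq_len(n)) {
    H <- if (i == 1L)
      .place_atom(C[1L, ], CA[1L, ], N[1L, ], g$b_N_H, g$a_C_N_H, 180)
    else
      .place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ], g$b_N_H, g$a_C_N_H, 180)
    gly <- topo$sequence[i] == "GLY"
    CB <- .place_atom(C[i, ], N[i, ], CA[i, ],
                      if (gly) g$b_CA_HA else g$b_CA_CB,
                      g$a_N_CA_CB, g$d_CB)
    O <- .place_atom(N[i, ], CA[i, ], C[i, ],
                     g$b_C_O, g$a_CA_C_O, normalize_angle(psi[i] + 180))
    k <- (i - 1L) * 6L
    xyz[k + 1L, ] <- N[i, ]
    xyz[k + 2L, ] <- H
    xyz[k + 3L, ] <- CA[i, ]
    xyz[k + 4L, ] <- CB
    xyz[k + 5L, ] <- C[i, ]
    xyz[k + 6L, ] <- O
  }
  structure(xyz,
            atom = rep(.ATOM_NAMES, n),
            residue = rep(seq_len(n), each = 6L),
            class = c("coordinate_set", "matrix", "array"))
}

#' Recover phi/psi torsions from backbone coordinates
#'
#' Measures the backbone dihedrals of a coordinate set (or of bare N/CA/C
#' coordinate matrices) and returns the residue-major 2n torsion vector.
#' Terminal residues lacking a dihedral get the placeholder 180.
#'
#' @param N,CA,C n x 3 matrices of backbone atom coordinates.
#' @return numeric vector of 2n angles in (-180, 180].
#' @export
measure_torsions <- function(N, CA, C) {
  n <- nrow(N)
  stopifnot(nrow(CA) == n, nrow(C) == n, n >= 2L)
  phi <- rep(180, n)
  psi <- rep(180, n)
  for (i in 2L:n)
    phi[i] <- .dihedral(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
  for (i in 1L:(n - 1L))
    psi[i] <- .dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
  as.numeric(rbind(phi, psi))
}

# Extract N/CA/C submatrices from a coordinate_set.
.backbone_of <- function(coords) {
  at <- attr(coords, "atom")
  list(N = coords[at == "N", , drop = FALSE],
       CA = coords[at == "CA", , drop = FALSE],
       C = coords[at == "C", , drop = FALSE])
}

#' Perturb a conformation at selected torsions
#'
#' Each selected torsion is displaced by a uniform draw from
#' \code{[-magnitude, magnitude]} degrees and re-normalized; all other
#' positions are untouched. The returned conformation carries a fresh id and
#' an unset energy. Uses R's global RNG stream, so results are reproducible
#' under \code{set.seed}.
#'
#' @param conf a \code{\link{conformation}}.
#' @param indices 1-based torsion indices to perturb (non-empty, within
#'   \code{[1, 2n]}).
#' @param magnitude maximum displacement in degrees (> 0).
#' @param id id for the new conformation; by default derives one by suffixing
#'   the parent id.
#' @return A new \code{\link{conformation}}.
#' @export
perturb <- function(conf, indices, magnitude, id = NULL) {
  stopifnot(inherits(conf, "conformation"))
  if (length(indices) == 0L) stop("empty perturbation index set")
  m <- length(conf$torsions)
  indices <- as.integer(indices)
  if (any(indices < 1L) || any(indices > m) || anyDuplicated(indices))
    stop("perturbation indices must be unique and within [1, 2n]")
  if (!(magnitude > 0)) stop("magnitude must be > 0")
  tors <- conf$torsions
  tors[indices] <- tors[indices] +
    stats::runif(length(indices), -magnitude, magnitude)
  if (is.null(id)) id <- paste0(conf$id, "+")
  conformation(tors, id = id)
}

#' Read a native protein structure from a PDB file
#'
#' Parses ATOM records of the first chain (first model, with a notice, if the
#' file holds several), computes the native phi/psi torsions from the backbone
#' dihedrals, flags hydrophobic residues from a standard table, and collects
#' secondary-structure segments from HELIX/SHEET records when present.
#'
#' @param path path to a PDB file with complete N/CA/C backbone for every
#'   residue of the chain.
#' @return A \code{\link{protein_topology}}.
#' @export
read_native_pdb <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1L)
    message("multi-model file: using the first model")
  ch <- at$chain[1L]
  at <- at[at$chain == ch | is.na(at$chain), , drop = FALSE]
  resno <- unique(at$resno)
  n <- length(resno)
  if (n < 2L) stop("chain has fewer than 2 residues")
  bb <- array(NA_real_, dim = c(n, 3L, 3L))  # residue x atom(N,CA,C) x xyz
  seqv <- character(n)
  for (i in seq_len(n)) {
    rows <- at[at$resno == resno[i], , drop = FALSE]
    seqv[i] <- rows$resid[1L]
    for (j in seq_along(c("N", "CA", "C"))) {
      nm <- c("N", "CA", "C")[j]
      r <- rows[rows$elety == nm, , drop = FALSE]
      if (nrow(r) == 0L)
        stop(sprintf("residue %d (%s) is missing backbone atom %s",
                     resno[i], seqv[i], nm))
      bb[i, j, ] <- as.numeric(r[1L, c("x", "y", "z")])
    }
  }
  tors <- measure_torsions(bb[, 1L, , drop = TRUE] |> matrix(ncol = 3L),
                           bb[, 2L, , drop = TRUE] |> matrix(ncol = 3L),
                           bb[, 3L, , drop = TRUE] |> matrix(ncol = 3L))
  segments <- .segments_from_pdb(pdb, resno, ch)
  protein_topology(seqv, tors, segments = segments)
}

.segments_from_pdb <- function(pdb, resno, ch) {
  segs <- list()
  to_idx <- function(r) match(r, resno)  # 1-based; NA if outside chain
  h <- pdb$helix
  if (!is.null(h) && length(h$start)) {
    keep <- which(h$chain == ch | is.na(h$chain))
    for (k in seq_along(keep)) {
      i <- keep[k]
      s <- to_idx(as.integer(h$start[i])); e <- to_idx(as.integer(h$end[i]))
      if (!is.na(s) && !is.na(e))
        segs[[length(segs) + 1L]] <- data.frame(
          label = paste0("H", k), kind = "helix",
          start = s - 1L, end = e)  # half-open, 0-based
    }
  }
  s2 <- pdb$sheet
  if (!is.null(s2) && length(s2$start)) {
    keep <- which(s2$chain == ch | is.na(s2$chain))
    for (k in seq_along(keep)) {
      i <- keep[k]
      s <- to_idx(as.integer(s2$start[i])); e <- to_idx(as.integer(s2$end[i]))
      if (!is.na(s) && !is.na(e))
        segs[[length(segs) + 1L]] <- data.frame(
          label = paste0("E", k), kind = "strand",
          start = s - 1L, end = e)
    }
  }
  if (length(segs)) do.call(rbind, segs) else NULL
}

#' Write a topology's native structure to a PDB file
#'
#' Realizes the native torsions with \code{\link{forward_kinematics}} and
#' writes standard ATOM records plus HELIX/SHEET records for the annotated
#' native segments. The file round-trips through \code{\link{read_native_pdb}}.
#'
#' @param topo a \code{\link{protein_topology}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_native_pdb <- function(topo, path) {
  xyz <- forward_kinematics(topo, topo$native_torsions)
  con <- file(path, "w")
  on.exit(close(con))
  seg <- topo$segments
  nh <- 0L; ns <- 0L
  if (nrow(seg)) {
    for (i in seq_len(nrow(seg))) {
      s1 <- seg$start[i] + 1L          # 1-based first residue
      e1 <- seg$end[i]                  # 1-based last residue (half-open end)
      if (seg$kind[i] == "helix") {
        nh <- nh + 1L
        writeLines(sprintf(
          "HELIX  %3d %3s %3s %s %4d  %3s %s %4d  1%30s %5d",
          nh, sprintf("H%d", nh), topo$sequence[s1], "A", s1,
          topo$sequence[e1], "A", e1, "", e1 - s1 + 1L), con)
      } else {
        ns <- ns + 1L
        writeLines(sprintf(
          "SHEET  %3d %3s%2d %3s %s%4d  %3s %s%4d  0",
          ns, sprintf("S%d", ns), 1L, topo$sequence[s1], "A", s1,
          topo$sequence[e1], "A", e1), con)
      }
    }
  }
  at <- attr(xyz, "atom"); res <- attr(xyz, "residue")
  for (k in seq_len(nrow(xyz))) {
    writeLines(sprintf(
      "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      k, at[k], topo$sequence[res[k]], "A", res[k],
      xyz[k, 1L], xyz[k, 2L], xyz[k, 3L], 1, 0, substr(at[k], 1L, 1L)), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write conformations to a columnar text file
#'
#' One row per conformation: id, the 2n torsions, and the cached energy
#' (NA when unset). Tab-separated with a header.
#'
#' @param confs list of \code{\link{conformation}} objects.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_conformations <- function(confs, path) {
  stopifnot(length(confs) >= 1L)
  m <- length(confs[[1L]]$torsions)
  df <- data.frame(id = vapply(confs, function(cc) cc$id, character(1L)))
  tor <- t(vapply(confs, function(cc) cc$torsions, numeric(m)))
  colnames(tor) <- paste0("t", seq_len(m))
  df <- cbind(df, as.data.frame(tor))
  df$energy <- vapply(confs, function(cc) cc$energy, numeric(1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read conformations written by \code{\link{write_conformations}}
#'
#' @param path input file path.
#' @return list of \code{\link{conformation}} objects.
#' @export
read_conformations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  tcols <- grep("^t[0-9]+$", names(df))
  lapply(seq_len(nrow(df)), function(i) {
    conformation(as.numeric(df[i, tcols]), id = df$id[i],
                 energy = df$energy[i])
  })
}
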