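# Structure / trajectory containers and PDB I/O.
#
# A Structure is a list(atoms = data.frame, label) of class "Structure"; the
# atoms table carries chain, resid, resname, atom_name, element, x, y, z, occ
# and mass (a.m.u., from the element).  A Trajectory is a list(topology,
# frames, times) of class "Trajectory" whose frames are n_atoms x 3 matrices
# sharing the topology's atom order.

# Atomic masses (a.m.u.) for elements seen in protein heavy-atom models.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  CA = 40.078, "NA" = 22.990, CL = 35.45, K = 39.098
)

#' Atomic mass lookup
#'
#' Masses come from a built-in element table; an element absent from the
#' table is assigned 12.0 a.m.u. with a warning (treated as a generic heavy
#' atom).
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in a.m.u.
#' @export
element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- .element_masses[el]
  if (anyNA(m)) {
    bad <- unique(el[is.na(m)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; assigning mass 12.0")
    m[is.na(m)] <- 12.0
  }
  unname(m)
}

# Infer the element from a PDB atom name: strip digits/primes, first letter.
.infer_element <- function(atom_name) {
  nm <- gsub("[0-9'*\" ]", "", atom_name)
  el <- toupper(substr(nm, 1, 1))
  el[el == ""] <- "C"
  el
}

#' Construct a Structure from an atom table
#'
#' @param atoms data.frame with columns chain, resid, resname, atom_name,
#'   x, y, z and optionally element, occ.
#' @param label optional structure label.
#' @return an object of class `Structure`.
#' @export
new_structure <- function(atoms, label = "") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  need <- c("chain", "resid", "resname", "atom_name", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$element)) atoms$element <- .infer_element(atoms$atom_name)
  blank <- is.na(atoms$element) | trimws(atoms$element) == ""
  atoms$element[blank] <- .infer_element(atoms$atom_name[blank])
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  if (any(atoms$resid < 1)) stop("resid must be >= 1")
  key <- paste(atoms$chain, atoms$resid, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, resid, atom_name): ",
         key[duplicated(key)][1])
  atoms$mass <- suppressWarnings(element_mass(atoms$element))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure '%s': %d atoms, %d residues, chains %s\n",
              x$label, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Coordinate matrix of a Structure
#'
#' @param structure a `Structure`.
#' @return an n_atoms x 3 numeric matrix (x, y, z in Angstrom).
#' @export
coords <- function(structure) {
  m <- as.matrix(structure$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace the coordinates of a Structure
#'
#' @param structure a `Structure`.
#' @param xyz an n_atoms x 3 matrix.
#' @return the modified `Structure`.
#' @export
set_coords <- function(structure, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == nrow(structure$atoms), ncol(xyz) == 3)
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

# ---- PDB parsing ------------------------------------------------------------

.parse_pdb_atoms <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(sel)) return(NULL)
  ln <- lines[sel]
  icode <- trimws(substr(ln, 27, 27))
  if (any(icode != ""))
    stop("insertion codes are not supported (line ", sel[which(icode != "")[1]],
         " of ", path, ")")
  x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  resid <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))
  if (length(bad))
    stop("malformed ATOM/HETATM record at line ", sel[bad[1]], " of ", path)
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1
  df <- data.frame(
    chain = trimws(substr(ln, 22, 22)),
    resid = resid,
    resname = trimws(substr(ln, 18, 20)),
    atom_name = trimws(substr(ln, 13, 16)),
    altloc = trimws(substr(ln, 17, 17)),
    element = trimws(substr(ln, 77, 78)),
    x = x, y = y, z = z, occ = occ,
    stringsAsFactors = FALSE
  )
  df$chain[df$chain == ""] <- "A"
  df
}

# Alternate locations: keep the highest-occupancy conformer per
# (chain, resid, atom_name); ties resolved in favour of altloc 'A'
# (then alphabetical).
.resolve_altloc <- function(df) {
  if (all(df$altloc == "")) return(df)
  key <- paste(df$chain, df$resid, df$atom_name)
  ord <- order(key, -df$occ, df$altloc != "A", df$altloc)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$chain, df$resid, df$atom_name)), , drop = FALSE]
  df[order(as.integer(rownames(df))), , drop = FALSE]
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records in file order.  The element is taken from
#' columns 77-78 when present and inferred from the atom name otherwise.
#' When a record carries alternate locations, the highest-occupancy conformer
#' is kept (ties go to altLoc 'A').  Insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @param label structure label; defaults to the file name.
#' @return a `Structure`.
#' @export
read_structure <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  df <- .parse_pdb_atoms(lines, path)
  if (is.null(df) || !nrow(df))
    stop("no ATOM/HETATM records found in ", path, " (line 1)")
  df <- .resolve_altloc(df)
  df$altloc <- NULL
  rownames(df) <- NULL
  new_structure(df, label = label)
}

.format_pdb_line <- function(i, a) {
  nm <- a$atom_name[i]
  # Atom-name column convention: 1-letter elements start in column 14.
  nm_f <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000L, nm_f, a$resname[i], a$chain[i], a$resid[i],
          a$x[i], a$y[i], a$z[i], a$occ[i], 0, toupper(a$element[i]))
}

#' Write a structure to a PDB file
#'
#' @param structure a `Structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  lines <- vapply(seq_len(nrow(a)), .format_pdb_line, character(1), a = a)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Construct a Trajectory
#'
#' @param topology a `Structure` giving the atom identities.
#' @param frames list of n_atoms x 3 coordinate matrices.
#' @param times optional per-frame times (ns); defaults to 0, 1, 2, ...
#' @return an object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "Structure"), length(frames) >= 1L)
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    frames[[i]] <- as.matrix(frames[[i]])
    if (nrow(frames[[i]]) != n || ncol(frames[[i]]) != 3)
      stop("frame ", i, " has wrong dimensions (expected ", n, " x 3)")
    dimnames(frames[[i]]) <- NULL
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  stopifnot(length(times) == length(frames))
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms ('%s')\n",
              length(x$frames), nrow(x$topology$atoms), x$topology$label))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a trajectory as a Structure
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return a `Structure` with the frame's coordinates.
#' @export
frame_structure <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  s <- set_coords(traj$topology, traj$frames[[i]])
  s$label <- sprintf("%s[frame %d]", traj$topology$label, i)
  s
}

#' Read a trajectory
#'
#' Multi-model PDB (MODEL/ENDMDL) is the native dialect: the topology is
#' taken from the first model and every model must list the same atoms in
#' the same order.  A flat CSV dialect (columns frame, atom, x, y, z, with
#' `atom` indexing the supplied topology) is accepted for synthetic systems.
#'
#' @param path path to a multi-model PDB or CSV file.
#' @param dialect "pdb" or "csv".
#' @param topology required for the CSV dialect: the `Structure` the
#'   coordinate rows refer to.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, dialect = c("pdb", "csv"), topology = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    if (is.null(topology)) stop("the csv dialect requires a topology Structure")
    df <- utils::read.csv(path)
    need <- c("frame", "atom", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("csv trajectory must have columns ", paste(need, collapse = ", "))
    n <- nrow(topology$atoms)
    frames <- lapply(split(df, df$frame), function(d) {
      if (nrow(d) != n) stop("frame ", d$frame[1], " has ", nrow(d),
                             " atoms, topology has ", n)
      m <- matrix(NA_real_, n, 3)
      m[d$atom, ] <- as.matrix(d[, c("x", "y", "z")])
      m
    })
    return(new_trajectory(topology, frames[order(as.numeric(names(frames)))]))
  }
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (!length(model_starts)) {                 # single-model file: one frame
    s <- read_structure(path)
    return(new_trajectory(s, list(coords(s))))
  }
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  blocks <- lapply(seq_along(model_starts), function(k) {
    .parse_pdb_atoms(lines[model_starts[k]:model_ends[k]], path)
  })
  if (is.null(blocks[[1]]) || !nrow(blocks[[1]]))
    stop("model 1 contains no atoms in ", path)
  topo <- .resolve_altloc(blocks[[1]])
  topo$altloc <- NULL
  topo <- new_structure(topo, label = basename(path))
  n <- nrow(topo$atoms)
  frames <- lapply(seq_along(blocks), function(k) {
    b <- blocks[[k]]
    if (is.null(b) || nrow(b) != n)
      stop("model ", k, " has ", if (is.null(b)) 0 else nrow(b),
           " atoms; expected ", n)
    as.matrix(b[, c("x", "y", "z")])
  })
  new_trajectory(topo, frames)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    s <- set_coords(traj$topology, traj$frames[[i]])
    a <- s$atoms
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(vapply(seq_len(nrow(a)), .format_pdb_line, character(1), a = a), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
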