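# Internal length unit is nanometres throughout; PDB files carry Angstrom
# and are converted at the I/O boundary (exact factor 10).
NM_PER_ANGSTROM <- 0.1

#' Domain selection specification
#'
#' A named selection identifying one quasi-rigid domain: a chain, one or
#' more inclusive residue-number intervals, and an atom-name filter
#' (C-alpha only by default, the representation used for every center,
#' fit and principal-axis computation in this package).
#'
#' @param name Unique domain label, e.g. `"TCR_Valpha"`.
#' @param chain_id Single chain identifier as it appears in the PDB file.
#' @param residue_intervals List (or 2-column matrix) of inclusive
#'   `c(start, end)` integer pairs. Intervals must not overlap.
#' @param atom_filter Character vector of atom names to keep
#'   (default `"CA"`).
#'
#' @return An object of class `domain_spec`.
#' @examples
#' domain_spec("A1_helix", "A", list(c(50, 86)))
#' @export
domain_spec <- function(name, chain_id, residue_intervals,
                        atom_filter = "CA") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("domain_spec: 'name' must be a non-empty string")
  if (!is.character(chain_id) || length(chain_id) != 1L)
    stop("domain_spec: 'chain_id' must be a single string")
  if (is.matrix(residue_intervals))
    residue_intervals <- lapply(seq_len(nrow(residue_intervals)),
                                function(i) residue_intervals[i, ])
  iv <- lapply(residue_intervals, function(p) {
    p <- as.integer(p)
    if (length(p) != 2L || anyNA(p) || p[1] > p[2])
      stop("domain_spec '", name,
           "': each interval must be c(start, end) with start <= end")
    p
  })
  if (length(iv) == 0L)
    stop("domain_spec '", name, "': at least one residue interval required")
  ord <- order(vapply(iv, `[`, integer(1), 1L))
  iv <- iv[ord]
  if (length(iv) > 1L) {
    starts <- vapply(iv, `[`, integer(1), 1L)
    ends   <- vapply(iv, `[`, integer(1), 2L)
    if (any(starts[-1] <= ends[-length(ends)]))
      stop("domain_spec '", name, "': residue intervals overlap")
  }
  if (length(atom_filter) == 0L || !all(nzchar(atom_filter)))
    stop("domain_spec '", name, "': empty atom filter")
  structure(list(name = name, chain_id = chain_id,
                 residue_intervals = iv,
                 atom_filter = toupper(atom_filter)),
            class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  iv <- paste(vapply(x$residue_intervals,
                     function(p) paste0(p[1], "-", p[2]), character(1)),
              collapse = ", ")
  cat("<domain_spec> ", x$name, ": chain ", x$chain_id,
      ", residues ", iv, ", atoms {",
      paste(x$atom_filter, collapse = ","), "}\n", sep = "")
  invisible(x)
}

new_topology <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  needed <- c("chain_id", "resnum", "inscode", "resname", "atom_name",
              "element")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    stop("topology missing columns: ", paste(missing, collapse = ", "))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", nrow(x$atoms), " atoms, chains: ",
      paste(unique(x$atoms$chain_id), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x A `topology` or `trajectory` object.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) return(nrow(x$topology$atoms))
  if (inherits(x, "topology")) return(nrow(x$atoms))
  stop("n_atoms: unsupported object of class ", paste(class(x), collapse = "/"))
}

new_trajectory <- function(topology, coords, times) {
  stopifnot(inherits(topology, "topology"))
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("trajectory coords must be an (atoms x 3 x frames) array")
  na <- nrow(topology$atoms)
  if (dim(coords)[1] != na)
    stop("trajectory coords have ", dim(coords)[1],
         " atoms but topology has ", na)
  nf <- dim(coords)[3]
  if (nf < 1L) stop("trajectory must contain at least one frame")
  if (length(times) != nf)
    stop("trajectory times length (", length(times),
         ") != frame count (", nf, ")")
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("trajectory contains non-finite coordinates")
  if (nf > 1L && any(diff(times) <= 0))
    stop("trajectory frame times must be strictly increasing")
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", dim(x$coords)[3], " frames x ",
      dim(x$coords)[1], " atoms, t = [", format(x$times[1]), ", ",
      format(x$times[length(x$times)]), "] ns\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$coords)[3]
}

#' Extract one frame's coordinate matrix
#' @param traj A `trajectory`.
#' @param i Frame index (1-based).
#' @return Numeric atoms x 3 matrix, nm.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"))
  if (i < 1L || i > n_frames(traj))
    stop("frame index ", i, " out of range 1..", n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

# --- PDB fixed-column parsing -----------------------------------------------
# Columns follow the PDB v3.3 coordinate-record layout. Only ATOM/HETATM/
# MODEL/ENDMDL/TER/END are interpreted; everything else is passed over.

parse_pdb_atom_line <- function(line, lineno) {
  if (nchar(line) < 54)
    stop("PDB parse error at line ", lineno,
         ": ATOM/HETATM record shorter than coordinate fields")
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (anyNA(xyz))
    stop("PDB parse error at line ", lineno, ": non-numeric coordinates")
  resnum <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (is.na(resnum))
    stop("PDB parse error at line ", lineno, ": non-numeric residue number")
  occ <- suppressWarnings(as.numeric(substr(line, 55, 60)))
  list(record   = substr(line, 1, 6),
       atom_name = trimws(substr(line, 13, 16)),
       altloc   = substr(line, 17, 17),
       resname  = trimws(substr(line, 18, 20)),
       chain_id = substr(line, 22, 22),
       resnum   = resnum,
       inscode  = substr(line, 27, 27),
       x = xyz[1], y = xyz[2], z = xyz[3],
       occupancy = if (is.na(occ)) 1.0 else occ,
       element  = trimws(substr(line, 77, 78)))
}

SOLVENT_RESNAMES <- c("HOH", "WAT", "SOL", "NA", "CL", "K", "MG", "ZN",
                      "CA2", "SO4", "PO4", "GOL", "EDO")

read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  models <- list()
  current <- list()
  in_model <- FALSE
  saw_model_record <- FALSE
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1, 6)
    if (rec == "MODEL ") {
      saw_model_record <- TRUE
      in_model <- TRUE
      current <- list()
    } else if (rec == "ENDMDL") {
      in_model <- FALSE
      models[[length(models) + 1L]] <- current
      current <- list()
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      current[[length(current) + 1L]] <- parse_pdb_atom_line(lines[i], i)
    }
  }
  if (length(current) > 0L) {
    if (saw_model_record && !in_model)
      stop("PDB parse error: ATOM records after final ENDMDL in ", path)
    models[[length(models) + 1L]] <- current
  }
  if (length(models) == 0L || all(vapply(models, length, integer(1)) == 0L))
    stop("no ATOM records found in ", path)
  models[vapply(models, length, integer(1)) > 0L]
}

atoms_to_frame <- function(atoms, keep_hetatm = FALSE) {
  rec <- vapply(atoms, `[[`, character(1), "record")
  resname <- vapply(atoms, `[[`, character(1), "resname")
  keep <- rec == "ATOM  " |
    (keep_hetatm & rec == "HETATM" & !(resname %in% SOLVENT_RESNAMES))
  atoms <- atoms[keep]
  if (length(atoms) == 0L)
    stop("empty atom selection after filtering HETATM/solvent records")
  df <- data.frame(
    chain_id  = vapply(atoms, `[[`, character(1), "chain_id"),
    resnum    = vapply(atoms, `[[`, integer(1),  "resnum"),
    inscode   = vapply(atoms, `[[`, character(1), "inscode"),
    resname   = vapply(atoms, `[[`, character(1), "resname"),
    atom_name = vapply(atoms, `[[`, character(1), "atom_name"),
    altloc    = vapply(atoms, `[[`, character(1), "altloc"),
    occupancy = vapply(atoms, `[[`, numeric(1),  "occupancy"),
    element   = vapply(atoms, `[[`, character(1), "element"),
    stringsAsFactors = FALSE)
  xyz <- cbind(vapply(atoms, `[[`, numeric(1), "x"),
               vapply(atoms, `[[`, numeric(1), "y"),
               vapply(atoms, `[[`, numeric(1), "z"))
  # altLoc resolution: keep the highest-occupancy location per atom site;
  # ties keep the first encountered.
  site_key <- paste(df$chain_id, df$resnum, df$inscode, df$atom_name,
                    sep = "\r")
  if (anyDuplicated(site_key)) {
    keep_idx <- logical(nrow(df))
    for (k in split(seq_len(nrow(df)), site_key)) {
      if (length(k) == 1L) { keep_idx[k] <- TRUE; next }
      best <- k[which.max(df$occupancy[k])]
      keep_idx[best] <- TRUE
    }
    # preserve original atom order
    df <- df[keep_idx, , drop = FALSE]
    xyz <- xyz[keep_idx, , drop = FALSE]
  }
  df$altloc <- NULL
  df$occupancy <- NULL
  list(atoms = df, xyz = xyz * NM_PER_ANGSTROM)
}

#' Read a reference structure from a PDB file
#'
#' Parses the first model of a PDB file into a topology plus a single
#' coordinate frame. Coordinates are converted from Angstrom to nm.
#' Alternate locations are resolved to the highest-occupancy copy (ties:
#' first encountered); HETATM records (waters, ions, ligands) are excluded
#' by default.
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @param keep_hetatm Keep non-solvent HETATM records (default `FALSE`).
#' @return A list with elements `topology` (class `topology`) and
#'   `coords` (atoms x 3 matrix, nm).
#' @export
read_structure <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  models <- read_pdb_models(path)
  fr <- atoms_to_frame(models[[1L]], keep_hetatm = keep_hetatm)
  list(topology = new_topology(fr$atoms), coords = fr$xyz)
}

#' Read a (multi-model PDB) trajectory
#'
#' Reads one or more multi-model PDB files and concatenates their models,
#' in file order, into a single trajectory bound to `topology`. Each model
#' must contain exactly the topology's atom count. Frame times are
#' assigned as `k * dt_ns` for k = 1..n unless `times` is supplied.
#'
#' @param paths Character vector of multi-model PDB paths.
#' @param topology The `topology` the frames are bound to.
#' @param dt_ns Frame spacing in ns used to synthesise times
#'   (default 0.04 ns, i.e. one frame per 40 ps).
#' @param times Optional explicit frame times (ns), overriding `dt_ns`.
#' @param keep_hetatm Keep non-solvent HETATM records (default `FALSE`).
#' @return A `trajectory`.
#' @export
read_trajectory <- function(paths, topology, dt_ns = 0.04, times = NULL,
                            keep_hetatm = FALSE) {
  stopifnot(inherits(topology, "topology"))
  na <- nrow(topology$atoms)
  frames <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("trajectory file not found: ", p)
    models <- read_pdb_models(p)
    for (m in models) {
      fr <- atoms_to_frame(m, keep_hetatm = keep_hetatm)
      idx <- length(frames) + 1L
      if (nrow(fr$xyz) != na)
        stop("frame ", idx, " (file ", p, "): atom count ",
             nrow(fr$xyz), " does not match topology (", na, ")")
      frames[[idx]] <- fr$xyz
    }
  }
  nf <- length(frames)
  coords <- array(unlist(frames, use.names = FALSE), dim = c(na, 3L, nf))
  if (is.null(times)) times <- seq_len(nf) * dt_ns
  new_trajectory(topology, coords, times)
}

#' Resolve a domain specification to atom indices
#'
#' Returns the (topology-ordered) indices of atoms matching the spec's
#' chain, residue intervals and atom-name filter. Residues missing from an
#' interval (e.g. crystal-structure gaps) are skipped with a warning; an
#' entirely empty selection is an error, never silently accepted.
#'
#' @param topology A `topology`.
#' @param spec A `domain_spec`.
#' @return Integer vector of atom indices in topology order.
#' @export
select_domain <- function(topology, spec) {
  stopifnot(inherits(topology, "topology"), inherits(spec, "domain_spec"))
  at <- topology$atoms
  if (!spec$chain_id %in% at$chain_id)
    stop("domain '", spec$name, "': chain '", spec$chain_id,
         "' not present in topology")
  in_interval <- rep(FALSE, nrow(at))
  for (iv in spec$residue_intervals)
    in_interval <- in_interval | (at$resnum >= iv[1] & at$resnum <= iv[2])
  sel <- which(at$chain_id == spec$chain_id & in_interval &
                 toupper(at$atom_name) %in% spec$atom_filter)
  if (length(sel) == 0L)
    stop("domain '", spec$name, "': selection is empty (chain ",
         spec$chain_id, ", atoms ", paste(spec$atom_filter, collapse = ","),
         ")")
  wanted <- unlist(lapply(spec$residue_intervals,
                          function(iv) iv[1]:iv[2]))
  got <- unique(at$resnum[sel])
  absent <- setdiff(wanted, got)
  if (length(absent) > 0L)
    warning("domain '", spec$name, "': ", length(absent),
            " residue(s) in the requested intervals have no matching atom ",
            "(e.g. ", absent[1], "); skipped")
  sel
}

#' One-letter sequence of a chain's residues
#'
#' Convenience accessor: the amino-acid sequence of one chain, read off
#' the C-alpha atoms in topology order.
#'
#' @param topology A `topology`.
#' @param chain_id Chain identifier.
#' @return Single string of one-letter codes (`X` for non-standard).
#' @export
chain_sequence <- function(topology, chain_id) {
  aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  at <- topology$atoms
  ca <- at[at$chain_id == chain_id & toupper(at$atom_name) == "CA", ]
  if (nrow(ca) == 0L) stop("no C-alpha atoms on chain '", chain_id, "'")
  one <- aa3to1[ca$resname]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

format_pdb_atom <- function(serial, name, resname, chain, resnum, inscode,
                            xyz_angstrom, element) {
  # Atom-name column convention: names of <4 chars start in column 14.
  nm <- if (nchar(name) >= 4L) substr(name, 1, 4) else
    formatC(paste0(" ", name), width = -4)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, substr(resname, 1, 3), substr(chain, 1, 1),
          resnum %% 10000L, inscode,
          xyz_angstrom[1], xyz_angstrom[2], xyz_angstrom[3],
          1.0, 0.0, element)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; coordinates converted nm to Angstrom
#' at the standard 3-decimal precision, so a read/write round trip
#' reproduces coordinates to 5e-5 nm.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  at <- traj$topology$atoms
  nf <- n_frames(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f, drop = TRUE] / NM_PER_ANGSTROM
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    lines <- vapply(seq_len(nrow(at)), function(i) {
      format_pdb_atom(i, at$atom_name[i], at$resname[i], at$chain_id[i],
                      at$resnum[i], at$inscode[i], xyz[i, ], at$element[i])
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a single structure (one frame) as a PDB file
#' @param topology A `topology`.
#' @param coords Atoms x 3 coordinate matrix (nm).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, coords, path) {
  traj <- new_trajectory(topology, array(coords, dim = c(nrow(coords), 3L, 1L)),
                         times = 0.0)
  at <- topology$atoms
  xyz <- coords / NM_PER_ANGSTROM
  lines <- vapply(seq_len(nrow(at)), function(i) {
    format_pdb_atom(i, at$atom_name[i], at$resname[i], at$chain_id[i],
                    at$resnum[i], at$inscode[i], xyz[i, ], at$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Keep every k-th frame of a trajectory
#'
#' Used to thin a densely written trajectory to the analysis stride
#' (e.g. 0.2 ns analysis samples from 0.04 ns frames: `every = 5`).
#'
#' @param traj A `trajectory`.
#' @param every Positive integer; keep frames `every, 2*every, ...`.
#' @return A `trajectory`.
#' @export
thin_trajectory <- function(traj, every) {
  stopifnot(inherits(traj, "trajectory"))
  every <- as.integer(every)
  if (is.na(every) || every < 1L) stop("'every' must be a positive integer")
  if (every == 1L) return(traj)
  idx <- seq(every, n_frames(traj), by = every)
  if (length(idx) == 0L) stop("stride larger than trajectory length")
  new_trajectory(traj$topology,
                 traj$coords[, , idx, drop = FALSE],
                 traj$times[idx])
}
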