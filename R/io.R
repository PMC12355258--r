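# Readers and writers. Internal coordinates are nm; PDB and XYZ files store
# Angstrom and are converted at the boundary. GRO files are already nm.
#
# Molecule boundaries are not encoded by GRO, and only weakly by PDB, so both
# readers apply the same convention: a new molecule starts whenever the
# residue number fails to increase (our writers restart residue numbering at
# 1 for every molecule) or, in PDB, when the chain letter changes or a TER
# record intervenes.

#' Read a structure file
#'
#' Parses a PDB, GRO or XYZ file into a topology plus a single coordinate
#' frame. PDB coordinates (Angstrom) are converted to nm.
#'
#' @param path file path.
#' @param format one of `"pdb"`, `"gro"`, `"xyz"`; default guesses from the
#'   file extension.
#' @return list with elements `topology` ([new_topology()]) and `frame`
#'   ([new_frame()]). XYZ and PDB files without box information get a large
#'   pseudo-box (1000 nm) recorded in the frame.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    pdb = read_pdb_structure(path),
    gro = read_gro_structure(path),
    xyz = read_xyz_structure(path),
    stop("unsupported structure format: ", format)
  )
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "gro") return("gro")
  if (ext == "xyz") return("xyz")
  if (ext == "dcd") return("dcd")
  stop("cannot guess format from extension '.", ext,
       "'; pass `format` explicitly")
}

#' Read a trajectory file
#'
#' Reads a multi-model PDB, multi-frame XYZ, or (via the bio3d package, when
#' installed) binary DCD trajectory. Frames are returned in file order; when
#' the file carries no time information, times default to the frame index in
#' ps. Atom counts must match the supplied topology.
#'
#' @param path file path.
#' @param topology `topology` describing every frame.
#' @param format `"pdb"` (multi-model), `"xyz"`, `"dcd"`, or `"auto"`.
#' @param box fallback orthorhombic box (nm) for formats that do not store
#'   one (XYZ, DCD without unit cell).
#' @return an `md_trajectory`.
#' @export
read_trajectory <- function(path, topology, format = c("auto", "pdb", "xyz", "dcd"),
                            box = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  frames <- switch(format,
    pdb = read_pdb_frames(path),
    xyz = read_xyz_frames(path, box),
    dcd = read_dcd_frames(path, box),
    stop("unsupported trajectory format: ", format)
  )
  if (length(frames) == 0L) stop("trajectory file contains no frames: ", path)
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$coords) != na) {
      stop(sprintf("frame %d has %d atoms but topology has %d",
                   i, nrow(frames[[i]]$coords), na))
    }
  }
  new_trajectory(topology, frames)
}

## ---- GRO ------------------------------------------------------------------

read_gro_structure <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO file (fewer than 3 lines): ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1L) {
    stop("malformed GRO atom-count line 2: '", lines[2], "'")
  }
  if (length(lines) < 2L + natoms + 1L) {
    stop("GRO file truncated: expected ", natoms, " atom lines")
  }
  at <- lines[3:(2 + natoms)]
  resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
  resname <- trimws(substr(at, 6, 10))
  name <- trimws(substr(at, 11, 15))
  x <- suppressWarnings(as.numeric(substr(at, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(at, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(at, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) stop("malformed GRO atom record at line ", 2L + bad[1])
  boxline <- strsplit(trimws(lines[2L + natoms + 1L]), "\\s+")[[1]]
  box <- suppressWarnings(as.numeric(boxline))
  if (length(box) < 3L || anyNA(box[1:3])) {
    stop("malformed GRO box line: '", lines[2L + natoms + 1L], "'")
  }
  if (length(box) > 3L && any(abs(box[4:length(box)]) > 1e-9)) {
    stop("triclinic boxes are not supported (off-diagonal box elements present)")
  }
  mol <- infer_molecules(resid, chain = NULL)
  top <- new_topology(data.frame(
    name = name, residue_id = resid, residue_name = resname,
    molecule_id = mol, stringsAsFactors = FALSE))
  list(topology = top,
       frame = new_frame(cbind(x, y, z), box[1:3], time = 0))
}

#' Write a GRO file
#'
#' @param topology,frame system to write; coordinates in nm.
#' @param path output path.
#' @export
write_gro <- function(topology, frame, path) {
  lines <- c("generated by ppnetmap", sprintf("%5d", n_atoms(topology)))
  resid <- local_residue_numbers(topology)
  at <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                resid %% 100000L,
                substr(topology$residue_name, 1, 5),
                substr(topology$name, 1, 5),
                seq_len(n_atoms(topology)) %% 100000L,
                frame$coords[, 1], frame$coords[, 2], frame$coords[, 3])
  box <- sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3])
  writeLines(c(lines, at, box), path)
  invisible(path)
}

# Residue numbering restarted at 1 within each molecule, so readers can
# recover molecule boundaries from resid resets.
local_residue_numbers <- function(topology) {
  out <- integer(n_atoms(topology))
  for (m in unique(topology$molecule_id)) {
    idx <- topology$molecule_id == m
    out[idx] <- match(topology$residue_id[idx], unique(topology$residue_id[idx]))
  }
  out
}

infer_molecules <- function(resid, chain = NULL, ter_before = NULL) {
  n <- length(resid)
  newmol <- logical(n)
  newmol[1] <- TRUE
  if (n > 1L) {
    prev <- resid[-n]; cur <- resid[-1]
    newres <- cur != prev
    newmol[-1] <- newres & (cur <= prev)
    if (!is.null(chain)) newmol[-1] <- newmol[-1] | (chain[-1] != chain[-n])
  }
  if (!is.null(ter_before)) newmol[ter_before] <- TRUE
  cumsum(newmol)
}

## ---- PDB ------------------------------------------------------------------

read_pdb_structure <- function(path) {
  parsed <- parse_pdb(path)
  m <- parsed$models[[1]]
  top <- new_topology(data.frame(
    name = parsed$name, residue_id = parsed$resid,
    residue_name = parsed$resname, molecule_id = parsed$molecule_id,
    stringsAsFactors = FALSE))
  list(topology = top, frame = new_frame(m$coords, m$box, time = 0))
}

read_pdb_frames <- function(path) {
  parsed <- parse_pdb(path)
  lapply(seq_along(parsed$models), function(i) {
    m <- parsed$models[[i]]
    new_frame(m$coords, m$box, time = if (is.na(m$time)) i - 1 else m$time)
  })
}

# Fixed-width ATOM/HETATM parser handling MODEL/ENDMDL, TER and CRYST1.
# bio3d::read.pdb covers single structures but drops per-model CRYST1/REMARK
# time metadata we rely on for trajectories, so the record walk is done here;
# bio3d serves as a cross-check in the tests.
parse_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in PDB file: ", path)
  box <- c(1000, 1000, 1000)
  cry <- which(rec == "CRYST1")
  if (length(cry)) {
    cl <- lines[cry[1]]
    abc <- suppressWarnings(as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                                         substr(cl, 25, 33))))
    ang <- suppressWarnings(as.numeric(c(substr(cl, 34, 40), substr(cl, 41, 47),
                                         substr(cl, 48, 54))))
    if (anyNA(abc)) stop("malformed CRYST1 record at line ", cry[1])
    if (!anyNA(ang) && any(abs(ang - 90) > 1e-6)) {
      stop("triclinic boxes are not supported (CRYST1 angles != 90)")
    }
    box <- abc / 10
  }
  model_starts <- which(rec == "MODEL ")
  n_models <- max(1L, length(model_starts))
  # atom metadata from the first model's records
  first_end <- if (length(model_starts) >= 2L) model_starts[2] - 1L else length(lines)
  sel1 <- which(is_atom & seq_along(lines) <= first_end)
  al <- lines[sel1]
  name <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 21))
  chain <- substr(al, 22, 22)
  resid <- suppressWarnings(as.integer(substr(al, 23, 26)))
  if (anyNA(resid)) {
    stop("malformed PDB residue number at line ", sel1[which(is.na(resid))[1]])
  }
  ter_lines <- which(rec == "TER   " | rec == "TER")
  ter_before <- findInterval(ter_lines, sel1) + 1L
  ter_before <- ter_before[ter_before <= length(sel1)]
  mol <- infer_molecules(resid, chain = chain, ter_before = ter_before)
  natoms <- length(sel1)
  atom_idx <- which(is_atom)
  if (length(atom_idx) %% natoms != 0L) {
    stop(sprintf("PDB models have inconsistent atom counts (total %d, first model %d)",
                 length(atom_idx), natoms))
  }
  parse_xyz_cols <- function(ls) {
    x <- suppressWarnings(as.numeric(substr(ls, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ls, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ls, 47, 54)))
    if (anyNA(x) || anyNA(y) || anyNA(z)) stop("malformed PDB coordinate record")
    cbind(x, y, z) / 10
  }
  models <- vector("list", length(atom_idx) %/% natoms)
  for (i in seq_along(models)) {
    idx <- atom_idx[((i - 1L) * natoms + 1L):(i * natoms)]
    models[[i]] <- list(coords = parse_xyz_cols(lines[idx]), box = box, time = NA_real_)
  }
  # REMARK time annotation written by write_pdb_trajectory
  tm <- which(startsWith(lines, "REMARK   time_ps"))
  if (length(tm) == length(models)) {
    tvals <- suppressWarnings(as.numeric(sub("^REMARK   time_ps\\s*", "", lines[tm])))
    if (!anyNA(tvals)) for (i in seq_along(models)) models[[i]]$time <- tvals[i]
  }
  list(name = name, resname = resname, resid = resid, molecule_id = mol,
       models = models)
}

#' Write a (multi-model) PDB file
#'
#' Writes one MODEL per frame, a CRYST1 record for the box, TER records at
#' molecule boundaries and a `REMARK time_ps` line per model so that frame
#' times survive a round trip. Coordinates are converted nm to Angstrom.
#'
#' @param topology system topology.
#' @param frames a single `md_frame` or list of frames.
#' @param path output path.
#' @export
write_pdb_trajectory <- function(topology, frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  resid <- local_residue_numbers(topology)
  mol <- topology$molecule_id
  chain <- LETTERS[((match(mol, unique(mol)) - 1L) %% 26L) + 1L]
  con <- file(path, "w")
  on.exit(close(con))
  box <- frames[[1]]$box * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90), con)
  nm <- topology$name
  nm4 <- ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), substr(nm, 1, 4))
  last_of_mol <- c(mol[-1] != mol[-length(mol)], TRUE)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf("REMARK   time_ps %.6f", f$time), con)
    xyz <- f$coords * 10
    recs <- sprintf("ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                    seq_len(n_atoms(topology)) %% 100000L, nm4,
                    substr(topology$residue_name, 1, 4), chain,
                    resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3])
    out <- character(0)
    for (j in seq_along(recs)) {
      out <- c(out, recs[j])
      if (last_of_mol[j]) out <- c(out, "TER")
    }
    writeLines(out, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- XYZ ------------------------------------------------------------------

read_xyz_structure <- function(path) {
  frames <- read_xyz_frames(path, box = NULL)
  lines <- readLines(path, n = 2L + count_xyz_atoms(path))
  natoms <- count_xyz_atoms(path)
  at <- strsplit(trimws(lines[3:(2 + natoms)]), "\\s+")
  name <- vapply(at, `[[`, character(1), 1L)
  top <- new_topology(data.frame(name = name, residue_id = 1L,
                                 residue_name = "UNK", molecule_id = 1L,
                                 stringsAsFactors = FALSE))
  list(topology = top, frame = frames[[1]])
}

count_xyz_atoms <- function(path) {
  n <- suppressWarnings(as.integer(trimws(readLines(path, n = 1L))))
  if (is.na(n) || n < 1L) stop("malformed XYZ atom-count line in ", path)
  n
}

# XYZ comment line may carry "box 5.0 5.0 5.0" (nm) and/or "time 10.0" (ps);
# coordinates are Angstrom per XYZ convention.
read_xyz_frames <- function(path, box = NULL) {
  lines <- readLines(path)
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms)) stop("malformed XYZ atom-count line ", i)
    if (i + 1L + natoms > length(lines)) stop("XYZ file truncated at line ", i)
    comment <- lines[i + 1L]
    fbox <- box %||% parse_xyz_keyval(comment, "box")
    ftime <- parse_xyz_keyval(comment, "time")
    toks <- strsplit(trimws(lines[(i + 2L):(i + 1L + natoms)]), "\\s+")
    co <- t(vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      if (anyNA(v)) stop("malformed XYZ coordinate record")
      v
    }, numeric(3))) / 10
    fidx <- fidx + 1L
    frames[[fidx]] <- new_frame(co, fbox %||% c(1000, 1000, 1000),
                                time = if (is.null(ftime)) fidx - 1 else ftime[1])
    i <- i + 2L + natoms
  }
  frames
}

parse_xyz_keyval <- function(comment, key) {
  m <- regmatches(comment, regexec(paste0(key, "\\s+([-0-9.eE ]+)"), comment))[[1]]
  if (length(m) < 2L) return(NULL)
  as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
}

#' Write an XYZ trajectory
#'
#' Coordinates are written in Angstrom; the comment line records the box (nm)
#' and time (ps) so round trips preserve both.
#'
#' @param topology system topology (atom names become XYZ element labels).
#' @param frames a single frame or list of frames.
#' @param path output path.
#' @export
write_xyz <- function(topology, frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  lab <- gsub("\\s", "_", topology$name)
  for (f in frames) {
    writeLines(sprintf("%d", n_atoms(topology)), con)
    writeLines(sprintf("box %.6f %.6f %.6f time %.6f",
                       f$box[1], f$box[2], f$box[3], f$time), con)
    xyz <- f$coords * 10
    writeLines(sprintf("%-5s %14.6f %14.6f %14.6f",
                       lab, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

## ---- DCD (optional, via bio3d) -------------------------------------------

read_dcd_frames <- function(path, box = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading DCD requires the 'bio3d' package")
  }
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  lapply(seq_len(nrow(xyz)), function(i) {
    co <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
    new_frame(co, box %||% c(1000, 1000, 1000), time = i - 1)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
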