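# Internal units throughout: nm, ps, amu, elementary charge.

SPECIES_LEVELS <- c("PROTEIN", "POLYMER", "WATER", "ION")

#' Construct a molecular topology
#'
#' A topology is the static description of a system: one row per atom with
#' its name, element, mass (amu), partial charge (e), 1-based residue id,
#' residue name, molecule id and species tag. Coordinates live in frames
#' (see [new_frame()]), not in the topology.
#'
#' @param atoms data.frame with columns `name`, `element`, `mass`, `charge`,
#'   `residue_id`, `residue_name`, `molecule_id`, `species`. Missing
#'   `element` is inferred from the first letter of `name`; missing `mass`
#'   and `charge` default to 1 amu and 0 e; missing `species` must be filled
#'   later via [assign_species()].
#' @return An object of class `topology`: the validated data.frame with an
#'   `index` column (0-based internal atom index).
#' @export
new_topology <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (n == 0L) stop("topology must contain at least one atom")
  if (is.null(atoms$name)) stop("topology atoms need a 'name' column")
  if (is.null(atoms$element)) {
    atoms$element <- toupper(substr(gsub("[^A-Za-z].*$", "", atoms$name), 1, 1))
  }
  if (is.null(atoms$mass)) atoms$mass <- 1
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$residue_id)) atoms$residue_id <- 1L
  if (is.null(atoms$residue_name)) atoms$residue_name <- "UNK"
  if (is.null(atoms$molecule_id)) atoms$molecule_id <- 1L
  if (is.null(atoms$species)) atoms$species <- NA_character_
  if (any(atoms$mass <= 0)) stop("all atomic masses must be > 0")
  if (any(atoms$residue_id < 1L)) stop("residue_id must be >= 1")
  bad <- !is.na(atoms$species) & !(atoms$species %in% SPECIES_LEVELS)
  if (any(bad)) {
    stop("unknown species tag(s): ", paste(unique(atoms$species[bad]), collapse = ", "))
  }
  atoms$index <- seq_len(n) - 1L
  atoms$residue_id <- as.integer(atoms$residue_id)
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  structure(atoms, class = c("topology", "data.frame"))
}

#' @export
print.topology <- function(x, ...) {
  sp <- table(factor(x$species, levels = SPECIES_LEVELS))
  cat(sprintf("topology: %d atoms, %d molecules, %d residues\n",
              nrow(x), length(unique(x$molecule_id)),
              nrow(unique(x[, c("molecule_id", "residue_id")]))))
  cat("  species:", paste(sprintf("%s=%d", names(sp), sp), collapse = " "), "\n")
  invisible(x)
}

n_atoms <- function(topology) nrow(topology)

#' Construct a single trajectory frame
#'
#' @param coords numeric matrix, one row per atom, columns x/y/z in nm.
#' @param box orthorhombic box edge lengths in nm (length-3 numeric).
#' @param time frame time in ps.
#' @return An object of class `md_frame`.
#' @export
new_frame <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coordinates must be an N x 3 matrix")
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  if (length(box) != 3L) stop("box must give three orthorhombic edge lengths")
  if (any(!is.finite(box)) || any(box <= 0)) stop("box edge lengths must be positive")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(list(coords = coords, box = box, time = as.numeric(time)),
            class = "md_frame")
}

#' Construct a trajectory
#'
#' @param topology a [new_topology()] object shared by all frames.
#' @param frames list of [new_frame()] objects with strictly increasing times
#'   and atom counts matching the topology.
#' @return An object of class `md_trajectory`.
#' @export
new_trajectory <- function(topology, frames) {
  if (!inherits(topology, "topology")) stop("topology must be a 'topology' object")
  if (length(frames) == 0L) stop("trajectory must contain at least one frame")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "md_frame")) stop("frame ", i, " is not an 'md_frame'")
    if (nrow(f$coords) != na) {
      stop(sprintf("frame %d has %d atoms but topology has %d",
                   i, nrow(f$coords), na))
    }
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames), class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms, t = %g .. %g ps\n",
              length(x$frames), n_atoms(x$topology),
              x$frames[[1]]$time, x$frames[[length(x$frames)]]$time))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Select atoms from a topology
#'
#' Conjunctive atom selection: every supplied criterion must hold. Returns a
#' deterministic, ordered (by atom index) integer vector of 1-based row
#' indices into the topology, so repeated calls with the same predicate give
#' identical selections.
#'
#' @param topology a `topology`.
#' @param species species tag(s) to keep (e.g. `"PROTEIN"`).
#' @param residue_id residue ids to keep (vector or range).
#' @param residue_name residue names to keep.
#' @param name atom names to keep (exact match), or a regular expression when
#'   `name_regex = TRUE`.
#' @param molecule_id molecule ids to keep.
#' @param element element symbols to keep.
#' @param name_regex interpret `name` as a regular expression.
#' @return integer vector of 1-based atom row indices (possibly empty).
#' @export
select_atoms <- function(topology, species = NULL, residue_id = NULL,
                         residue_name = NULL, name = NULL, molecule_id = NULL,
                         element = NULL, name_regex = FALSE) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(species)) keep <- keep & topology$species %in% species
  if (!is.null(residue_id)) keep <- keep & topology$residue_id %in% residue_id
  if (!is.null(residue_name)) keep <- keep & topology$residue_name %in% residue_name
  if (!is.null(molecule_id)) keep <- keep & topology$molecule_id %in% molecule_id
  if (!is.null(element)) keep <- keep & topology$element %in% element
  if (!is.null(name)) {
    keep <- keep & if (name_regex) grepl(name, topology$name) else topology$name %in% name
  }
  which(keep)
}

#' Assign species tags by residue-name rules
#'
#' Tags every atom with one of PROTEIN, POLYMER, WATER or ION according to
#' its residue name. Built-in defaults cover the 20 standard amino acids
#' (PROTEIN), acrylate monomers `ACR`/`PAA` (POLYMER), common water names
#' (`SOL`, `HOH`, `WAT`, `TIP3`) and monatomic ions (`NA`, `CL`, `SOD`,
#' `CLA`, `K`, `MG`, `CA2`). User rules override the defaults. A residue
#' name covered by no rule is an error unless `default` is given.
#'
#' @param topology a `topology`.
#' @param rules named character vector `residue_name -> species`.
#' @param default fallback species for uncovered residue names (NULL = error).
#' @return the topology with its `species` column (re)assigned.
#' @export
assign_species <- function(topology, rules = NULL, default = NULL) {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "LYZ")
  base <- c(stats::setNames(rep("PROTEIN", length(aa)), aa),
            ACR = "POLYMER", PAA = "POLYMER",
            SOL = "WATER", HOH = "WATER", WAT = "WATER", TIP3 = "WATER",
            `NA` = "ION", CL = "ION", SOD = "ION", CLA = "ION",
            K = "ION", MG = "ION", CA2 = "ION")
  if (!is.null(rules)) {
    bad <- !(rules %in% SPECIES_LEVELS)
    if (any(bad)) stop("rules map to unknown species: ",
                       paste(unique(rules[bad]), collapse = ", "))
    base[names(rules)] <- rules
  }
  rn <- topology$residue_name
  sp <- unname(base[rn])
  if (anyNA(sp)) {
    if (is.null(default)) {
      stop("no species rule for residue name(s): ",
           paste(unique(rn[is.na(sp)]), collapse = ", "),
           " (supply `rules` or `default`)")
    }
    sp[is.na(sp)] <- default
  }
  topology$species <- sp
  topology
}

#' Minimum-image distance in an orthorhombic box
#'
#' Euclidean distance between two points measured to the nearest periodic
#' image, the convention used by every distance-based analysis in this
#' package.
#'
#' @param a,b points (length-3 numeric or N x 3 matrices), nm.
#' @param box orthorhombic edge lengths, nm.
#' @return distance(s) in nm; never exceeds half the box diagonal.
#' @export
minimum_image_distance <- function(a, b, box) {
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  if (any(box <= 0)) stop("box edge lengths must be positive")
  if (is.matrix(a) || is.matrix(b)) {
    a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
    d <- a - b[rep_len(seq_len(nrow(b)), nrow(a)), , drop = FALSE]
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    sqrt(rowSums(d * d))
  } else {
    d <- a - b
    d <- d - box * round(d / box)
    sqrt(sum(d * d))
  }
}

# Minimum-image displacement vectors (rows of `a` minus rows of `b`).
min_image_disp <- function(a, b, box) {
  d <- a - b
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# Full minimum-image distance matrix between coordinate sets A (n x 3) and
# B (m x 3); vectorized per dimension. Used by every pair analysis.
pair_distance_matrix <- function(A, B, box) {
  n <- nrow(A); m <- nrow(B)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# Unwrap a molecule across periodic boundaries: each atom is moved to the
# periodic image nearest the first atom. Valid for molecules smaller than
# half the box in every direction.
unwrap_coords <- function(coords, box) {
  ref <- coords[1, ]
  d <- sweep(coords, 2, ref)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  sweep(d, 2, ref, "+")
}
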