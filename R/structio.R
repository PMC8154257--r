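## Structure I/O: PDB reading/writing, ligand/receptor splitting.
##
## Poses are plain data frames (class "molecule_pose") with one row per
## atom, kept in the input Cartesian frame. No superposition is performed
## anywhere in the package: poses are assumed pre-aligned in a common
## receptor frame, as is standard when rescoring docked poses.

#' Construct a molecule pose
#'
#' A pose is an ordered set of atoms of one molecule (or complex) in a fixed
#' Cartesian frame.
#'
#' @param element Character vector of element symbols.
#' @param xyz Numeric matrix (n x 3) of coordinates in Angstrom.
#' @param serial Integer atom serial numbers (default `seq_len(n)`).
#' @param name PDB atom names.
#' @param resname Residue names.
#' @param chain Chain identifiers.
#' @param resno Residue numbers.
#' @param is_hetero Logical; `TRUE` for HETATM-style records.
#' @param label Pose identifier (e.g. `"3SW7_min"`).
#' @param extra_elements Named integer vector of atomic numbers for
#'   pseudo-element symbols (see [make_single_zeta_pair()]).
#' @return An object of class `molecule_pose`: a data frame with columns
#'   `serial`, `name`, `resname`, `chain`, `resno`, `x`, `y`, `z`,
#'   `element`, `atomic_number`, `is_hetero`.
#' @export
molecule_pose <- function(element, xyz, serial = NULL, name = element,
                          resname = "LIG", chain = "A", resno = 1L,
                          is_hetero = TRUE, label = "pose",
                          extra_elements = NULL) {
  xyz <- as.matrix(xyz)
  if (length(element) < 1L) .stopf("a pose needs at least one atom")
  if (ncol(xyz) != 3L || nrow(xyz) != length(element))
    .stopf("xyz must be an n x 3 matrix matching 'element'")
  if (!all(is.finite(xyz))) .stopf("all coordinates must be finite")
  if (is.null(serial)) serial <- seq_along(element)
  if (anyDuplicated(xyz) > 0L)
    .stopf("pose '%s' has atoms with identical coordinates", label)
  pose <- data.frame(
    serial = as.integer(serial),
    name = as.character(name),
    resname = as.character(resname),
    chain = as.character(chain),
    resno = as.integer(resno),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = as.character(element),
    atomic_number = atomic_number(element, extra_elements),
    is_hetero = as.logical(is_hetero),
    stringsAsFactors = FALSE
  )
  attr(pose, "label") <- label
  class(pose) <- c("molecule_pose", "data.frame")
  pose
}

#' @export
print.molecule_pose <- function(x, ...) {
  cat(sprintf("molecule_pose '%s': %d atoms (%s)\n",
              pose_label(x), nrow(x),
              paste(names(sort(-table(x$element))), collapse = " ")))
  invisible(x)
}

#' Pose label accessor
#' @param pose A `molecule_pose`.
#' @return The pose's label string.
#' @export
pose_label <- function(pose) attr(pose, "label") %||% "pose"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coordinate matrix of a pose
#' @param pose A `molecule_pose`.
#' @return Numeric n x 3 matrix in Angstrom.
#' @export
pose_xyz <- function(pose) cbind(x = pose$x, y = pose$y, z = pose$z)

## resolve element symbols for atoms whose element column is blank, from
## PDB atom names; bio3d::atom2ele covers standard names, the fallback
## strips leading digits/primes and takes the leading letters.
.element_from_name <- function(name) {
  vapply(name, function(nm) {
    el <- tryCatch(bio3d::atom2ele(nm), error = function(e) NA_character_)
    if (!is.na(el) && el != "") return(el)
    clean <- sub("^[0-9']+", "", nm)
    first <- regmatches(clean, regexpr("^[A-Za-z]", clean))
    if (length(first) == 1L) return(toupper(first))
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read one pose from a PDB file
#'
#' Reads all `ATOM` and `HETATM` records of one MODEL. Elements are taken
#' from the element column when present, otherwise resolved from atom
#' names. Crystallographic waters (`HOH`/`WAT`/`DOD`) are excluded by
#' default; the receptor density including or excluding waters is therefore
#' the caller's choice.
#'
#' @param path PDB file path.
#' @param model 1-based MODEL index for multi-model files.
#' @param keep_waters Keep water residues (default `FALSE`).
#' @param altloc `"best"` keeps the highest-occupancy alternate location
#'   (occupancy ties broken by altloc letter order); a single letter keeps
#'   that altloc (plus non-alternate atoms). Use [list_altlocs()] to extract
#'   each alternate conformation as its own pose.
#' @param extra_elements Named integer vector of atomic numbers for
#'   non-standard element symbols.
#' @param label Pose label; defaults to the file base name.
#' @return A [molecule_pose()].
#' @export
read_pose <- function(path, model = 1L, keep_waters = FALSE,
                      altloc = "best", extra_elements = NULL,
                      label = NULL) {
  if (!file.exists(path)) .stopf("PDB file not found: %s", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) .stopf("cannot parse PDB file %s: %s",
                               path, conditionMessage(e)))
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models)
    .stopf("model index %d out of range (file has %d model(s))",
           model, n_models)
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)

  ## altloc filtering
  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- rep(TRUE, nrow(at))
  if (identical(altloc, "best")) {
    has_alt <- alt != ""
    if (any(has_alt)) {
      key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "|")
      occ <- at$o
      occ[is.na(occ)] <- 1
      for (k in unique(key[has_alt])) {
        idx <- which(key == k & has_alt)
        if (length(idx) > 1L) {
          best <- idx[order(-occ[idx], alt[idx])][1L]
          keep[setdiff(idx, best)] <- FALSE
        }
      }
    }
  } else {
    keep <- alt == "" | alt == altloc
  }
  if (!keep_waters) keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!any(keep)) .stopf("no atoms left in %s after filtering", path)

  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]

  element <- at$elesy
  blank <- is.na(element) | trimws(element) == ""
  element[!blank] <- trimws(element[!blank])
  if (any(blank)) element[blank] <- .element_from_name(at$elety[blank])
  bad <- is.na(element)
  if (any(bad))
    .stopf("cannot resolve element for atom(s): %s",
           paste(sprintf("%d/%s", at$eleno[bad], at$elety[bad]),
                 collapse = ", "))
  ## normalise case ("CL" -> "Cl") for standard elements
  element <- ifelse(
    paste0(toupper(substr(element, 1, 1)),
           tolower(substr(element, 2, 2))) %in% .ELEMENTS,
    paste0(toupper(substr(element, 1, 1)), tolower(substr(element, 2, 2))),
    element)

  molecule_pose(
    element = element, xyz = xyz, serial = at$eleno, name = at$elety,
    resname = at$resid, chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, is_hetero = at$type == "HETATM",
    label = label %||% sub("\\.(pdb|ent)$", "", basename(path),
                           ignore.case = TRUE),
    extra_elements = extra_elements
  )
}

#' List alternate-location identifiers in a PDB file
#'
#' @param path PDB file path.
#' @return Sorted character vector of altloc letters (possibly empty).
#'   Pass each to `read_pose(altloc = )` to extract the corresponding
#'   conformation as its own pose.
#' @export
list_altlocs <- function(path) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  alt <- pdb$atom$alt
  sort(unique(alt[!is.na(alt) & alt != ""]))
}

#' Write a pose to a PDB file
#'
#' Coordinates are written at PDB precision (3 decimals), so a write/read
#' round trip reproduces them to 1e-3 Angstrom.
#'
#' @param pose A [molecule_pose()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pose <- function(pose, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(pose_xyz(pose))),
    type = ifelse(pose$is_hetero, "HETATM", "ATOM"),
    resno = pose$resno, resid = pose$resname, eleno = pose$serial,
    elety = pose$name, chain = pose$chain,
    elesy = pose$element,
    o = rep(1, nrow(pose)), b = rep(0, nrow(pose))
  )
  invisible(path)
}

#' Split a complex into receptor and ligand
#'
#' Partitions a pose by a ligand selector. The split is exact and disjoint:
#' every non-water atom ends up in exactly one of the two parts.
#'
#' @param pose A [molecule_pose()] holding the whole complex.
#' @param resname,chain,serial_range Selection criteria combined with AND:
#'   residue name(s), chain id(s), and/or an inclusive serial `c(lo, hi)`
#'   range. At least one must be given.
#' @return A list with elements `receptor` and `ligand`, both
#'   [molecule_pose()] objects labelled from the input label.
#' @export
split_complex <- function(pose, resname = NULL, chain = NULL,
                          serial_range = NULL) {
  if (is.null(resname) && is.null(chain) && is.null(serial_range))
    .stopf("give at least one of resname, chain, serial_range")
  sel <- rep(TRUE, nrow(pose))
  if (!is.null(resname)) sel <- sel & pose$resname %in% resname
  if (!is.null(chain)) sel <- sel & pose$chain %in% chain
  if (!is.null(serial_range)) {
    stopifnot(length(serial_range) == 2L)
    sel <- sel & pose$serial >= serial_range[1] & pose$serial <= serial_range[2]
  }
  water <- pose$resname %in% c("HOH", "WAT", "DOD")
  sel <- sel & !water
  if (!any(sel)) .stopf("ligand selector matched no atoms")
  if (all(sel | water))
    .stopf("ligand selector matched every atom; cannot split the complex")
  lab <- pose_label(pose)
  list(
    receptor = .subset_pose(pose, !sel & !water, paste0(lab, "_receptor")),
    ligand = .subset_pose(pose, sel, paste0(lab, "_ligand"))
  )
}

.subset_pose <- function(pose, idx, label) {
  out <- pose[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- c("molecule_pose", "data.frame")
  out
}
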