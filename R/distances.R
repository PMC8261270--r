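#' Read a receptor structure from a PDB file
#'
#' Parses fixed-column ATOM records via bio3d. Only the first MODEL is
#' kept; alternate locations are resolved to altloc \code{A} when present,
#' otherwise to the highest-occupancy copy; HETATM records (waters, ions,
#' co-crystallized ligands) are excluded from the receptor unless requested.
#' Residue numbering is taken verbatim from the file.
#'
#' @param path PDB file path.
#' @param include_hetatm keep HETATM records as receptor atoms.
#' @return An object of class \code{"receptor_structure"}: a list with
#'   \code{atoms} (data frame: \code{residue_name}, \code{residue_number},
#'   \code{chain}, \code{atom_name}, \code{element}, \code{x}, \code{y},
#'   \code{z}) and \code{source}.
#' @export
read_receptor_pdb <- function(path, include_hetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
                  error = function(e)
                    stop("PDB parse error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (!include_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  # resolve altlocs within each (chain, residue, atom name)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  for (dup in unique(key[duplicated(key)])) {
    idx <- which(key == dup)
    pick <- idx[alt[idx] == "A"]
    if (!length(pick)) {
      occ <- at$o[idx]
      occ[is.na(occ)] <- 0
      pick <- idx[which.max(occ)]
    }
    keep[setdiff(idx, pick[1])] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  # fall back to the first letter of the atom name when the element column
  # is absent (common in modelling output)
  elem[blank] <- substr(gsub("[^A-Za-z].*", "", at$elety[blank]), 1, 1)
  atoms <- data.frame(residue_name = at$resid,
                      residue_number = as.integer(at$resno),
                      chain = ifelse(is.na(at$chain), "", at$chain),
                      atom_name = at$elety,
                      element = toupper(trimws(elem)),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  structure(list(atoms = atoms, source = path),
            class = "receptor_structure")
}

#' @export
print.receptor_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "residue_number")]))
  cat(sprintf("Receptor structure: %d atoms, %d residues (%s)\n",
              nrow(x$atoms), nres, x$source))
  invisible(x)
}

# build a ligand_pose from an element/coordinate table
.new_pose <- function(ligand_id, element, xyz, pose_rank, properties = list()) {
  if (!nrow(xyz)) stop(ligand_id, ": pose has no atoms")
  if (any(!is.finite(as.matrix(xyz))))
    stop(ligand_id, ": non-finite pose coordinates (malformed atom block?)")
  structure(list(ligand_id = ligand_id,
                 atoms = data.frame(element = toupper(element),
                                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                    stringsAsFactors = FALSE),
                 pose_rank = as.integer(pose_rank),
                 properties = properties),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("Ligand pose '%s' (rank %d): %d atoms\n", x$ligand_id,
              x$pose_rank, nrow(x$atoms)))
  invisible(x)
}

#' Read docked ligand poses from an SDF or PDB file
#'
#' A multi-record SDF (V2000) yields one pose per record in file order;
#' \code{pose_rank} is the 1-based file position, matching the convention
#' that docking programs write poses best-score first. SDF data fields
#' (e.g. \code{minimizedAffinity} from smina) are passed through verbatim in
#' each pose's \code{properties}; they are never computed here. A PDB pose
#' file yields a single pose from its first MODEL (ATOM and HETATM records).
#'
#' @param path pose file.
#' @param format \code{"sdf"}, \code{"pdb"}, or \code{"auto"} (by
#'   extension).
#' @param ligand_id identifier; defaults to the SDF record title when
#'   present, else the file name.
#' @return List of \code{"ligand_pose"} objects.
#' @export
read_ligand_poses <- function(path, format = c("auto", "sdf", "pdb"),
                              ligand_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "sdf"
  if (format == "pdb") {
    pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
                    error = function(e)
                      stop("PDB parse error in ", path, ": ",
                           conditionMessage(e), call. = FALSE))
    at <- pdb$atom
    elem <- at$elesy
    blank <- is.na(elem) | !nzchar(trimws(elem))
    elem[blank] <- substr(gsub("[^A-Za-z].*", "", at$elety[blank]), 1, 1)
    id <- if (is.null(ligand_id))
      sub("\\.[^.]*$", "", basename(path)) else ligand_id
    return(list(.new_pose(id, trimws(elem),
                          data.frame(at$x, at$y, at$z), 1L)))
  }
  sdf <- tryCatch(suppressMessages(ChemmineR::read.SDFset(path)),
                  error = function(e)
                    stop("SDF parse error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  out <- vector("list", length(sdf))
  for (r in seq_along(sdf)) {
    record <- sdf[[r]]
    ab <- ChemmineR::atomblock(record)
    if (is.null(ab) || !nrow(ab))
      stop(sprintf("%s: record %d has no atoms", path, r))
    elements <- gsub("_.*$", "", rownames(ab))
    if (any(!grepl("^[A-Za-z]{1,2}$", elements)))
      stop(sprintf("%s: record %d atom block malformed (counts mismatch?)",
                   path, r))
    title <- ChemmineR::header(record)[1]
    id <- if (!is.null(ligand_id)) ligand_id
      else if (length(title) && nzchar(trimws(title[1]))) trimws(title[1])
      else sub("\\.[^.]*$", "", basename(path))
    props <- as.list(ChemmineR::datablock(record))
    out[[r]] <- .new_pose(id, elements, as.data.frame(ab[, 1:3, drop = FALSE]),
                          r, props)
  }
  out
}

# coordinate matrix helpers with optional hydrogen filtering
.pose_coords <- function(pose, include_hydrogens) {
  at <- pose$atoms
  if (!include_hydrogens) at <- at[at$element != "H", , drop = FALSE]
  at
}

.receptor_coords <- function(receptor, include_hydrogens) {
  at <- receptor$atoms
  if (!include_hydrogens) at <- at[at$element != "H", , drop = FALSE]
  at
}

#' Minimum ligand-to-residue distance of a docked pose
#'
#' The global minimum Euclidean distance over all (ligand atom, receptor
#' atom) pairs, heavy atoms only by default. The nearest residue is the
#' residue owning the minimizing receptor atom; exact distance ties are
#' broken by lower residue number, then lower chain id.
#'
#' @param pose a \code{"ligand_pose"}.
#' @param receptor a \code{"receptor_structure"}.
#' @param include_hydrogens include hydrogen atoms on both sides (docked
#'   poses frequently lack them, so the default compares heavy-atom
#'   frameworks).
#' @return An object of class \code{"pose_distance_report"}: list with
#'   \code{ligand_id}, \code{pose_rank}, \code{nearest_residue} (list:
#'   \code{name}, \code{number}, \code{chain}), \code{min_distance} (Å),
#'   \code{ligand_atom} (list: \code{element}, \code{index}) and
#'   \code{residue_atom}.
#' @export
min_ligand_residue_distance <- function(pose, receptor,
                                        include_hydrogens = FALSE) {
  stopifnot(inherits(pose, "ligand_pose"),
            inherits(receptor, "receptor_structure"))
  lat <- .pose_coords(pose, include_hydrogens)
  rat <- .receptor_coords(receptor, include_hydrogens)
  if (!nrow(lat) || !nrow(rat))
    stop("no atoms left after hydrogen filtering")
  L <- as.matrix(lat[, c("x", "y", "z")])
  R <- as.matrix(rat[, c("x", "y", "z")])
  # squared distances of all pairs: |L|^2 + |R|^2 - 2 L.R
  d2 <- outer(rowSums(L^2), rowSums(R^2), "+") - 2 * tcrossprod(L, R)
  d2[d2 < 0] <- 0
  dmin2 <- min(d2)
  hit <- which(d2 <= dmin2, arr.ind = TRUE)   # exact ties only
  cand <- data.frame(li = hit[, 1], ri = hit[, 2],
                     resno = rat$residue_number[hit[, 2]],
                     chain = rat$chain[hit[, 2]])
  cand <- cand[order(cand$resno, cand$chain, cand$ri, cand$li), ]
  li <- cand$li[1]
  ri <- cand$ri[1]
  structure(list(ligand_id = pose$ligand_id, pose_rank = pose$pose_rank,
                 nearest_residue = list(name = rat$residue_name[ri],
                                        number = rat$residue_number[ri],
                                        chain = rat$chain[ri]),
                 min_distance = sqrt(dmin2),
                 ligand_atom = list(element = lat$element[li],
                                    index = as.integer(rownames(lat))[li] %||%
                                      li),
                 residue_atom = rat$atom_name[ri]),
            class = "pose_distance_report")
}

`%||%` <- function(a, b) if (is.null(a) || all(is.na(a))) b else a

#' @export
print.pose_distance_report <- function(x, ...) {
  cat(sprintf("%s (pose %d): %.3f Å to %s%d%s (%s ... %s)\n",
              x$ligand_id, x$pose_rank, x$min_distance,
              x$nearest_residue$name, x$nearest_residue$number,
              ifelse(nzchar(x$nearest_residue$chain),
                     paste0(":", x$nearest_residue$chain), ""),
              x$ligand_atom$element, x$residue_atom))
  invisible(x)
}

#' Distance between a named ligand/receptor atom pair
#'
#' Measures one specific contact, e.g. a ligand carbonyl oxygen against the
#' hydroxyl oxygen of a tyrosine. The receptor atom is selected either by
#' exact \code{atom_name}, or — the convenience mode — as the nearest atom
#' of a given \code{element} within the selected residue.
#'
#' @param pose a \code{"ligand_pose"}.
#' @param ligand_atom_index 1-based index into the pose's atom list.
#' @param receptor a \code{"receptor_structure"}.
#' @param residue_number,chain residue selector; \code{chain = NULL}
#'   matches any chain.
#' @param atom_name exact receptor atom name (e.g. \code{"OH"}), or
#'   \code{NULL} to use \code{element}.
#' @param element receptor element symbol; the nearest matching atom in the
#'   residue is used.
#' @return Distance in Å.
#' @export
atom_pair_distance <- function(pose, ligand_atom_index, receptor,
                               residue_number, chain = NULL,
                               atom_name = NULL, element = NULL) {
  stopifnot(inherits(pose, "ligand_pose"),
            inherits(receptor, "receptor_structure"))
  if (ligand_atom_index < 1 || ligand_atom_index > nrow(pose$atoms))
    stop("ligand atom index out of range")
  la <- as.numeric(pose$atoms[ligand_atom_index, c("x", "y", "z")])
  at <- receptor$atoms
  sel <- at$residue_number == residue_number
  if (!is.null(chain)) sel <- sel & at$chain == chain
  if (!any(sel)) stop("no residue matches number ", residue_number)
  at <- at[sel, , drop = FALSE]
  if (!is.null(atom_name)) {
    at <- at[at$atom_name == atom_name, , drop = FALSE]
    if (!nrow(at)) stop("no atom named '", atom_name, "' in residue ",
                        residue_number)
  } else if (!is.null(element)) {
    at <- at[at$element == toupper(element), , drop = FALSE]
    if (!nrow(at)) stop("no ", element, " atom in residue ", residue_number)
  }
  d <- sqrt(colSums((t(as.matrix(at[, c("x", "y", "z")])) - la)^2))
  min(d)
}

#' Mean of nearest-residue distances over a ligand set
#'
#' Arithmetic mean of the per-ligand minimum distances, reported to 3
#' decimal places (the conventional precision for contact tables).
#'
#' @param reports list of \code{"pose_distance_report"} objects, or a
#'   numeric vector of distances in Å.
#' @return Mean distance in Å, rounded to 3 decimals.
#' @export
mean_nearest_distance <- function(reports) {
  if (!length(reports)) stop("no distance reports")
  d <- if (is.numeric(reports)) reports
    else vapply(reports, function(r) r$min_distance, numeric(1))
  round(mean(d), 3)
}

#' Nearest-residue distance table for a ligand panel
#'
#' Runs [min_ligand_residue_distance()] for every ligand and assembles the
#' contact table: one row per ligand with its nearest residue and minimum
#' distance (Å, 3 decimals), plus the panel mean as an attribute. When a
#' ligand has several poses, \code{pose_selection} picks either the
#' top-ranked pose (\code{"best_rank"}, i.e. the docking program's best
#' score) or the pose with the smallest contact distance
#' (\code{"min_distance"}).
#'
#' @param receptor a \code{"receptor_structure"}.
#' @param poses list of \code{"ligand_pose"} objects (possibly several per
#'   ligand id).
#' @param pose_selection \code{"best_rank"} or \code{"min_distance"}.
#' @param include_hydrogens see [min_ligand_residue_distance()].
#' @return Data frame with columns \code{ligand}, \code{residue},
#'   \code{residue_number}, \code{chain}, \code{distance}; attributes
#'   \code{mean_distance} and \code{reports} (the full per-ligand report
#'   objects).
#' @export
pose_distance_table <- function(receptor, poses,
                                pose_selection = c("best_rank", "min_distance"),
                                include_hydrogens = FALSE) {
  pose_selection <- match.arg(pose_selection)
  stopifnot(length(poses) > 0)
  ids <- vapply(poses, function(p) p$ligand_id, character(1))
  reports <- list()
  for (id in unique(ids)) {
    grp <- poses[ids == id]
    reps <- lapply(grp, min_ligand_residue_distance, receptor = receptor,
                   include_hydrogens = include_hydrogens)
    pick <- if (pose_selection == "best_rank") {
      which.min(vapply(grp, function(p) p$pose_rank, integer(1)))
    } else {
      which.min(vapply(reps, function(r) r$min_distance, numeric(1)))
    }
    reports[[id]] <- reps[[pick]]
  }
  df <- data.frame(
    ligand = names(reports),
    residue = vapply(reports, function(r) r$nearest_residue$name, character(1)),
    residue_number = vapply(reports, function(r) r$nearest_residue$number,
                            integer(1)),
    chain = vapply(reports, function(r) r$nearest_residue$chain, character(1)),
    distance = round(vapply(reports, function(r) r$min_distance, numeric(1)), 3),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(df, "mean_distance") <- mean_nearest_distance(df$distance)
  attr(df, "reports") <- reports
  df
}
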