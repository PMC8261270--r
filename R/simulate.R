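# draw strictly positive intensities from a normal truncated at 0
# (inverse-CDF sampling, so no rejection loop)
.rtruncnorm_pos <- function(n, mean, sd) {
  u <- stats::runif(n, stats::pnorm(0, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Simulate a class-labelled panel of sparse vibrational spectra
#'
#' Generates agonist / non-agonist spectra with the statistical structure
#' the information-gain analysis assumes: most corrals empty, a shared set
#' of background corrals occupied at the same rate in both classes, and a
#' few planted corrals whose occupancy probability differs between classes
#' (the known ground truth). Each occupied corral receives one mode at a
#' wavenumber drawn uniformly within the corral's interval, so corralling
#' the simulated spectra recovers the planted occupancy pattern exactly;
#' intensities are drawn from a normal truncated at zero.
#'
#' The defaults mirror a 53 + 53 ligand panel with roughly 430 of 800
#' corrals occupied per class and three planted corrals with an occupancy
#' gap of 0.6 between classes.
#'
#' @param n_per_class molecules per class.
#' @param planted data frame with columns \code{feature} (corral index),
#'   \code{p_agonist} and \code{p_nonagonist} (occupancy probabilities).
#' @param background_corrals number of background corrals, drawn at random
#'   from the corrals not planted.
#' @param background_occupancy shared per-molecule occupancy probability of
#'   each background corral.
#' @param intensity_mean,intensity_sd parameters of the (0-truncated)
#'   normal intensity distribution.
#' @param scheme a [corral_scheme()].
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @return An object of class \code{"cimvf_sim"}: list with \code{spectra}
#'   (list of [vib_spectrum()]), \code{labels} (factor,
#'   \code{agonist}/\code{non-agonist}), \code{truth} (planted table and
#'   background corral indices) and \code{config}.
#' @examples
#' sim <- simulate_spectra(n_per_class = 5, seed = 42)
#' table(sim$labels)
#' @export
simulate_spectra <- function(n_per_class = 53,
                             planted = data.frame(
                               feature = c(230L, 241L, 601L),
                               p_agonist = 0.9, p_nonagonist = 0.3),
                             background_corrals = 428,
                             background_occupancy = 0.25,
                             intensity_mean = 5, intensity_sd = 2,
                             scheme = corral_scheme(), seed = NULL) {
  stopifnot(n_per_class >= 1, inherits(scheme, "corral_scheme"))
  planted$feature <- as.integer(planted$feature)
  if (nrow(planted)) {
    if (any(planted$feature < 1 | planted$feature > scheme$n_corrals))
      stop("planted corral outside the corral scheme")
    if (anyDuplicated(planted$feature)) stop("duplicate planted corrals")
    if (any(planted$p_agonist < 0 | planted$p_agonist > 1 |
            planted$p_nonagonist < 0 | planted$p_nonagonist > 1))
      stop("occupancy probabilities must lie in [0, 1]")
  }
  free <- setdiff(seq_len(scheme$n_corrals), planted$feature)
  if (background_corrals > length(free))
    stop("not enough corrals left for the background set")
  if (!is.null(seed)) set.seed(seed)
  background <- sort(sample(free, background_corrals))
  lab <- c("agonist", "non-agonist")
  spectra <- list()
  labels <- character(0)
  for (cls in 1:2) {
    p_planted <- if (cls == 1) planted$p_agonist else planted$p_nonagonist
    for (m in seq_len(n_per_class)) {
      id <- sprintf("%s%03d", c("AGO", "NAG")[cls], m)
      occ_planted <- planted$feature[stats::runif(nrow(planted)) < p_planted]
      occ_bg <- background[stats::runif(length(background)) <
                             background_occupancy]
      occ <- c(occ_planted, occ_bg)
      rng <- feature_range(occ, scheme)
      w <- stats::runif(length(occ), rng[, "low"], rng[, "high"])
      i <- .rtruncnorm_pos(length(occ), intensity_mean, intensity_sd)
      spectra[[id]] <- vib_spectrum(w, i, id, source = "simulated")
      labels <- c(labels, lab[cls])
    }
  }
  structure(list(spectra = spectra,
                 labels = factor(labels, levels = lab),
                 truth = list(planted = planted, background = background),
                 config = list(n_per_class = n_per_class,
                               background_corrals = background_corrals,
                               background_occupancy = background_occupancy,
                               intensity_mean = intensity_mean,
                               intensity_sd = intensity_sd,
                               seed = seed),
                 scheme = scheme),
            class = "cimvf_sim")
}

#' @export
print.cimvf_sim <- function(x, ...) {
  cat(sprintf("Simulated ligand panel: %d molecules (%s)\n",
              length(x$spectra),
              paste(sprintf("%d %s", table(x$labels), levels(x$labels)),
                    collapse = ", ")))
  cat(sprintf("  planted corrals: %s\n",
              paste(feature_label(x$truth$planted$feature), collapse = ", ")))
  cat(sprintf("  background corrals: %d at occupancy %.2f\n",
              length(x$truth$background), x$config$background_occupancy))
  invisible(x)
}

#' Write a simulated panel to spectrum tables plus a manifest
#'
#' Emits one two-column spectrum table per molecule and a manifest CSV
#' (\code{molecule_id}, \code{spectrum_path}, \code{label}) binding spectra
#' to labels — the same file layout [run_descriptor_stage()] consumes.
#'
#' @param sim a [simulate_spectra()] result.
#' @param dir output directory (created if missing).
#' @return Path of the manifest file, invisibly.
#' @export
write_sim_panel <- function(sim, dir) {
  stopifnot(inherits(sim, "cimvf_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(sim$spectra)
  files <- paste0(ids, ".tsv")
  for (k in seq_along(ids))
    write_spectrum_table(sim$spectra[[k]], file.path(dir, files[k]))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(molecule_id = ids, spectrum_path = files,
                              label = as.character(sim$labels)),
                   manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

# fixed-column PDB ATOM record emitter
.pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z, element) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, resid, chain, resno, x, y, z, 1.0, 0.0, element)
}

# minimal V2000 SDF record emitter; atoms are joined by a chain of single
# bonds purely to keep the record well-formed (no chemistry is implied)
.sdf_record <- function(title, element, xyz) {
  n <- nrow(xyz)
  bonds <- if (n > 1)
    sprintf("%3d%3d  1  0  0  0  0", seq_len(n - 1), seq_len(n - 1) + 1L)
  else character(0)
  c(title, "  cimvf synthetic pose generator", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, length(bonds)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            xyz[, 1], xyz[, 2], xyz[, 3], element),
    bonds, "M  END", "$$$$")
}

#' Simulate a receptor/pose fixture with known nearest contact
#'
#' Builds a small synthetic receptor (one target residue plus decoy
#' residues) and a docked ligand pose such that the minimum
#' ligand-to-residue heavy-atom distance is exactly \code{target_distance},
#' attained between the ligand's first atom and a designated atom of the
#' target residue; every decoy residue is placed strictly farther away
#' (rejection-resampled, erroring after 100 attempts). The fixture is
#' written as PDB (receptor) and SDF (pose) text and re-read through the
#' package's standard parsers, so what is returned is exactly what the file
#' formats preserve. Coordinates are rounded to 3 decimals (PDB precision),
#' so \code{target_distance} should be given at 3 decimals or fewer.
#'
#' @param n_residues total residues including the target.
#' @param target_residue index (1-based) of the target residue.
#' @param target_distance the planted minimum distance, Å (> 0).
#' @param target_name,target_atom,target_element residue name, atom name
#'   and element of the designated contact atom.
#' @param resno_start first residue number (numbering is preserved verbatim
#'   through the PDB round trip).
#' @param n_ligand_atoms atoms in the ligand pose (first atom is the
#'   contact oxygen).
#' @param jitter_sd coordinate jitter (Å) of decoy-residue atoms.
#' @param ligand_id identifier written to the SDF title line.
#' @param dir directory for the emitted files; a fresh temporary directory
#'   by default.
#' @param seed integer seed.
#' @return An object of class \code{"pose_fixture"}: list with
#'   \code{receptor}, \code{pose} (parsed back from the emitted files),
#'   \code{receptor_path}, \code{pose_path} and \code{truth} (list:
#'   \code{residue_name}, \code{residue_number}, \code{chain},
#'   \code{distance}).
#' @examples
#' fx <- simulate_pose_fixture(target_distance = 3.26, seed = 1)
#' min_ligand_residue_distance(fx$pose, fx$receptor)$min_distance
#' @export
simulate_pose_fixture <- function(n_residues = 6, target_residue = 4,
                                  target_distance = 3.26,
                                  target_name = "TYR", target_atom = "OH",
                                  target_element = "O", resno_start = 248,
                                  n_ligand_atoms = 8, jitter_sd = 0.3,
                                  ligand_id = "ligand", dir = NULL,
                                  seed = NULL) {
  stopifnot(n_residues >= 1, target_residue >= 1,
            target_residue <= n_residues, n_ligand_atoms >= 1,
            jitter_sd >= 0)
  if (!is.numeric(target_distance) || target_distance <= 0)
    stop("'target_distance' must be strictly positive")
  d <- round(target_distance, 3)
  if (abs(d - target_distance) > 1e-9)
    warning(sprintf("target distance rounded to PDB precision: %.3f", d))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dir)) dir <- tempfile("pose_fixture_")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  # ligand: contact oxygen at the origin, carbons strictly on the -x side
  lx <- round(cbind(stats::runif(n_ligand_atoms - 1, -2.5, -0.5),
                    stats::runif(n_ligand_atoms - 1, -1, 1),
                    stats::runif(n_ligand_atoms - 1, -1, 1)), 3)
  ligand_xyz <- rbind(c(0, 0, 0), lx)
  ligand_elem <- c("O", rep("C", n_ligand_atoms - 1))

  decoy_names <- c("LEU", "PHE", "VAL", "ILE", "ALA", "SER", "THR", "MET")
  backbone <- c("N", "CA", "C", "O")
  atoms <- list()
  for (r in seq_len(n_residues)) {
    resno <- resno_start + r - 1L
    if (r == target_residue) {
      # backbone parked behind the contact atom (x >= d + 1.5, so farther
      # than d from every ligand atom, all of which have x <= 0)
      bb <- round(cbind(stats::runif(4, d + 1.5, d + 3.5),
                        stats::runif(4, -1, 1), stats::runif(4, -1, 1)), 3)
      atoms[[r]] <- data.frame(
        name = c(backbone, target_atom), resid = target_name, resno = resno,
        x = c(bb[, 1], d), y = c(bb[, 2], 0), z = c(bb[, 3], 0),
        element = c("N", "C", "C", "O", target_element))
    } else {
      ok <- FALSE
      for (attempt in 1:100) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        centre <- u * (d + 8 + stats::runif(1, 0, 2))
        xyz <- round(sweep(matrix(stats::rnorm(12, 0, jitter_sd), 4), 2,
                           centre, "+"), 3)
        gap <- min(sqrt(pmax(outer(rowSums(xyz^2), rowSums(ligand_xyz^2), "+") -
                               2 * tcrossprod(xyz, ligand_xyz), 0)))
        if (gap > d + 0.5) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place decoy residue ", r,
                    " outside the target margin after 100 attempts")
      atoms[[r]] <- data.frame(
        name = backbone, resid = decoy_names[(r - 1) %% length(decoy_names) + 1],
        resno = resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        element = c("N", "C", "C", "O"))
    }
  }
  at <- do.call(rbind, atoms)
  receptor_path <- file.path(dir, "receptor.pdb")
  writeLines(c(vapply(seq_len(nrow(at)), function(k)
    .pdb_atom_line(k, at$name[k], at$resid[k], "A", at$resno[k],
                   at$x[k], at$y[k], at$z[k], at$element[k]), character(1)),
    "END"), receptor_path)
  pose_path <- file.path(dir, "ligand.sdf")
  writeLines(.sdf_record(ligand_id, ligand_elem, ligand_xyz), pose_path)

  receptor <- read_receptor_pdb(receptor_path)
  pose <- read_ligand_poses(pose_path, format = "sdf")[[1]]
  report <- min_ligand_residue_distance(pose, receptor)
  target_resno <- resno_start + target_residue - 1L
  if (abs(report$min_distance - d) > 1e-9 ||
      report$nearest_residue$number != target_resno)
    stop("internal error: fixture does not realize its planted contact")
  structure(list(receptor = receptor, pose = pose,
                 receptor_path = receptor_path, pose_path = pose_path,
                 truth = list(residue_name = target_name,
                              residue_number = target_resno,
                              chain = "A", distance = d)),
            class = "pose_fixture")
}

#' @export
print.pose_fixture <- function(x, ...) {
  cat(sprintf("Synthetic pose fixture: contact %s%d at %.3f Å (%s, %s)\n",
              x$truth$residue_name, x$truth$residue_number,
              x$truth$distance, basename(x$receptor_path),
              basename(x$pose_path)))
  invisible(x)
}
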