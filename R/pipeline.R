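#' Descriptor stage: manifest of spectra to descriptor matrix
#'
#' Reads every spectrum named in a manifest, corrals it, and writes the
#' panel descriptor matrix (\code{descriptors.csv} + scheme sidecar) and
#' the label table (\code{labels.csv}) into \code{out_dir}. Any spectrum
#' failing validation aborts the stage with a message listing the offending
#' molecules; modes outside the corral range are dropped and counted in the
#' returned log.
#'
#' @param manifest path to a manifest CSV (see [read_manifest()]).
#' @param out_dir output directory, created if missing.
#' @param scheme a [corral_scheme()].
#' @param drop_imaginary passed to the spectrum readers.
#' @return Invisibly, a list with \code{matrix_path}, \code{labels_path},
#'   \code{n_molecules} and \code{n_dropped_modes}.
#' @export
run_descriptor_stage <- function(manifest, out_dir, scheme = corral_scheme(),
                                 drop_imaginary = FALSE) {
  mf <- read_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spectra <- list()
  failures <- character(0)
  for (k in seq_len(nrow(mf))) {
    sp <- tryCatch(
      if (grepl("\\.(log|out)$", mf$spectrum_path[k], ignore.case = TRUE))
        read_gamess_log(mf$spectrum_path[k], mf$molecule_id[k],
                        drop_imaginary)
      else
        read_spectrum_table(mf$spectrum_path[k], mf$molecule_id[k],
                            drop_imaginary),
      error = function(e) conditionMessage(e))
    if (is.character(sp)) {
      failures <- c(failures, sprintf("%s: %s", mf$molecule_id[k], sp))
    } else {
      spectra[[mf$molecule_id[k]]] <- sp
    }
  }
  if (length(failures))
    stop("descriptor stage aborted; invalid spectra:\n  ",
         paste(failures, collapse = "\n  "))
  n_dropped <- 0L
  withCallingHandlers(
    m <- cimvf_matrix(spectra, scheme),
    warning = function(w) {
      n_dropped <<- n_dropped + 1L
      invokeRestart("muffleWarning")
    })
  matrix_path <- file.path(out_dir, "descriptors.csv")
  write_cimvf_matrix(m, matrix_path)
  labels_path <- file.path(out_dir, "labels.csv")
  utils::write.csv(data.frame(molecule_id = mf$molecule_id,
                              label = as.character(mf$label)),
                   labels_path, row.names = FALSE, quote = FALSE)
  invisible(list(matrix_path = matrix_path, labels_path = labels_path,
                 n_molecules = nrow(m), n_dropped_modes = n_dropped))
}

#' Information-gain stage: descriptor matrix to feature and LOOCV reports
#'
#' Fits the information-gain model and writes the informative-feature table
#' (\code{features.tsv}: feature, wavenumber range, presence frequency, IG
#' in bits, with the class entropy in a header comment), the per-class mean
#' intensity profiles (\code{mean_profiles.csv}) and the leave-one-out
#' cross-validation report (\code{loocv.json}: accuracy, confusion table,
#' per-fold predictions).
#'
#' @param matrix_path path to a descriptor CSV written by
#'   [write_cimvf_matrix()] (the scheme sidecar must sit next to it).
#' @param labels_path path to a labels CSV (\code{molecule_id},
#'   \code{label}).
#' @param out_dir output directory, created if missing.
#' @param discretizer,classifier,selection see [loocv_cimvf()].
#' @return Invisibly, a list with the fitted model, the LOOCV result and
#'   the report paths.
#' @export
run_ig_stage <- function(matrix_path, labels_path, out_dir,
                         discretizer = c("presence", "split"),
                         classifier = c("1nn", "vote"),
                         selection = c("fold", "global")) {
  discretizer <- match.arg(discretizer)
  classifier <- match.arg(classifier)
  selection <- match.arg(selection)
  m <- read_cimvf_matrix(matrix_path)
  lab_df <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (!nrow(m)) stop("empty descriptor matrix")
  idx <- match(rownames(m), lab_df$molecule_id)
  if (anyNA(idx)) stop("labels missing for: ",
                       paste(rownames(m)[is.na(idx)], collapse = ", "))
  labels <- factor(lab_df$label[idx])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- cimvf_fit(m, labels, discretizer)
  inf <- summary(fit)$informative
  features_path <- file.path(out_dir, "features.tsv")
  con <- file(features_path, "w")
  writeLines(sprintf("# class entropy H(C) = %.6f bits", fit$entropy), con)
  utils::write.table(
    data.frame(feature = inf$feature,
               wavenumber = sprintf("%g-%g", inf$range_low, inf$range_high),
               frequency = inf$frequency,
               ig_bits = sprintf("%.6f", inf$ig_bits)),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  profiles <- sapply(levels(labels), function(cl)
    mean_intensity_profile(m, labels, cl))
  profiles_path <- file.path(out_dir, "mean_profiles.csv")
  utils::write.csv(data.frame(feature = colnames(m), profiles,
                              check.names = FALSE),
                   profiles_path, row.names = FALSE, quote = FALSE)
  cv <- loocv_cimvf(m, labels, classifier, discretizer, selection)
  loocv_path <- file.path(out_dir, "loocv.json")
  jsonlite::write_json(
    list(accuracy = cv$accuracy,
         classifier = classifier, discretizer = discretizer,
         selection = selection,
         class_entropy_bits = fit$entropy,
         confusion = as.data.frame(cv$confusion),
         n_fallback_folds = cv$n_fallback,
         predictions = data.frame(
           molecule_id = cv$predictions$molecule_id,
           truth = as.character(cv$predictions$truth),
           predicted = as.character(cv$predictions$predicted),
           n_features = cv$predictions$n_features)),
    loocv_path, auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, loocv = cv, features_path = features_path,
                 profiles_path = profiles_path, loocv_path = loocv_path))
}

#' Distance stage: receptor and pose files to a contact table
#'
#' Parses the receptor and each pose file, computes per-ligand nearest
#' residues and minimum distances, and writes \code{distances.tsv} (one row
#' per ligand, distances in Å to 3 decimals, a final \code{mean} row) and a
#' per-pose JSON detail record (\code{distances.json}). A pose file that
#' fails to parse is skipped with a warning and counted in the result.
#'
#' @param receptor_pdb receptor PDB path.
#' @param pose_files character vector of SDF/PDB pose files.
#' @param out_dir output directory, created if missing.
#' @param pose_selection,include_hydrogens see [pose_distance_table()].
#' @return Invisibly, a list with the contact table, \code{mean_distance},
#'   \code{n_skipped} and the report paths.
#' @export
run_distance_stage <- function(receptor_pdb, pose_files, out_dir,
                               pose_selection = c("best_rank", "min_distance"),
                               include_hydrogens = FALSE) {
  pose_selection <- match.arg(pose_selection)
  receptor <- read_receptor_pdb(receptor_pdb)
  poses <- list()
  n_skipped <- 0L
  for (pf in pose_files) {
    ps <- tryCatch(read_ligand_poses(pf), error = function(e) {
      warning("skipping unparseable pose file ", pf, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(ps)) n_skipped <- n_skipped + 1L else poses <- c(poses, ps)
  }
  if (!length(poses)) stop("no parseable pose files")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- pose_distance_table(receptor, poses, pose_selection,
                             include_hydrogens)
  table_path <- file.path(out_dir, "distances.tsv")
  out <- data.frame(ligand = c(tab$ligand, "mean"),
                    residue = c(sprintf("%s%d", tab$residue,
                                        tab$residue_number), ""),
                    distance = sprintf("%.3f", c(tab$distance,
                                                 attr(tab, "mean_distance"))))
  utils::write.table(out, table_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  reports <- attr(tab, "reports")
  json_path <- file.path(out_dir, "distances.json")
  jsonlite::write_json(
    lapply(reports, function(r)
      list(ligand_id = r$ligand_id, pose_rank = r$pose_rank,
           nearest_residue = r$nearest_residue,
           min_distance = r$min_distance,
           ligand_atom = r$ligand_atom, residue_atom = r$residue_atom)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(table = tab, mean_distance = attr(tab, "mean_distance"),
                 n_skipped = n_skipped, table_path = table_path,
                 json_path = json_path))
}

#' Run the full analysis pipeline
#'
#' Chains the descriptor, information-gain and (optionally) distance stages
#' into one deterministic run. The effective configuration is echoed to
#' \code{config.json} in the output directory so a run is self-describing;
#' reruns with identical inputs and configuration produce byte-identical
#' outputs.
#'
#' @param manifest spectrum manifest CSV.
#' @param out_dir output directory.
#' @param receptor_pdb,pose_files optional distance-stage inputs; both must
#'   be given to run the stage.
#' @param step,range_low,range_high corral scheme parameters (cm^-1).
#' @param discretizer,classifier,selection see [run_ig_stage()].
#' @param pose_selection,include_hydrogens see [run_distance_stage()].
#' @param drop_imaginary see [run_descriptor_stage()].
#' @return Invisibly, a list with each stage's result.
#' @export
run_pipeline <- function(manifest, out_dir, receptor_pdb = NULL,
                         pose_files = NULL, step = 5, range_low = 0,
                         range_high = 4000,
                         discretizer = c("presence", "split"),
                         classifier = c("1nn", "vote"),
                         selection = c("fold", "global"),
                         pose_selection = c("best_rank", "min_distance"),
                         include_hydrogens = FALSE, drop_imaginary = FALSE) {
  discretizer <- match.arg(discretizer)
  classifier <- match.arg(classifier)
  selection <- match.arg(selection)
  pose_selection <- match.arg(pose_selection)
  scheme <- corral_scheme(step, range_low, range_high)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(step = step, range_low = range_low, range_high = range_high,
         discretizer = discretizer, classifier = classifier,
         selection = selection, pose_selection = pose_selection,
         include_hydrogens = include_hydrogens,
         drop_imaginary = drop_imaginary),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  desc <- run_descriptor_stage(manifest, out_dir, scheme, drop_imaginary)
  ig <- run_ig_stage(desc$matrix_path, desc$labels_path, out_dir,
                     discretizer, classifier, selection)
  dist <- NULL
  if (!is.null(receptor_pdb) && length(pose_files))
    dist <- run_distance_stage(receptor_pdb, pose_files, out_dir,
                               pose_selection, include_hydrogens)
  invisible(list(descriptors = desc, ig = ig, distances = dist))
}
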