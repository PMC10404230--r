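#' Assemble a viewer-style analysis bundle on disk
#'
#' Writes the complete analysis record in the layout interactive QTL
#' viewers consume — genotype probabilities, LOCO kinship, marker map,
#' and a dataset block (mRNA annotations, sample annotations, covariate
#' info and matrix, the expression matrix used for mapping, datatype,
#' display name, annotation tag, and the LOD peak table) — as a
#' directory of plain-text tables plus a JSON manifest recording the
#' configuration, seed and package version. Invariants are validated
#' before anything is written.
#'
#' @param dir Output directory.
#' @param genoprobs `founder_probs`.
#' @param kinship `kinship_set` with LOCO matrices.
#' @param map Marker map.
#' @param expression Samples x genes expression matrix used for mapping.
#' @param covariates Covariate table.
#' @param annotations Gene annotation table (`gene_id`, `chromosome`,
#'   `tss_bp`, optionally `symbol`, `strand`).
#' @param peaks Classified peak table (all LODs must exceed the
#'   threshold).
#' @param config Run configuration list.
#' @param display_name Dataset display name.
#' @param annotation_tag Provenance of gene annotations (e.g. an Ensembl
#'   version, or `"synthetic"`).
#' @return The bundle directory, invisibly.
#' @export
assemble_bundle <- function(dir, genoprobs, kinship, map, expression,
                            covariates, annotations, peaks, config,
                            display_name = "synthetic striatum-style eQTL",
                            annotation_tag = "synthetic") {
  validate_bundle_elements(genoprobs, kinship, map, expression, covariates,
                           annotations, peaks, config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_founder_probs(genoprobs, file.path(dir, "genoprobs"))
  kdir <- file.path(dir, "kinship")
  if (!dir.exists(kdir)) dir.create(kdir)
  write_matrix_tsv(kinship$overall, file.path(kdir, "overall.tsv"))
  for (ch in names(kinship$loco))
    write_matrix_tsv(kinship$loco[[ch]], file.path(kdir, paste0("loco_", ch, ".tsv")))
  write_marker_map(map, file.path(dir, "markers.tsv"))
  ddir <- file.path(dir, "dataset")
  if (!dir.exists(ddir)) dir.create(ddir)
  write_table_tsv(annotations, file.path(ddir, "annot_mrna.tsv"))
  write_table_tsv(covariates, file.path(ddir, "annot_samples.tsv"))
  write_table_tsv(
    data.frame(covariate = c("sex", "generation"),
               type = "factor", role = "additive"),
    file.path(ddir, "covar_info.tsv"))
  write_matrix_tsv(covariate_design(covariates), file.path(ddir, "covar_matrix.tsv"))
  write_matrix_tsv(expression, file.path(ddir, "data.tsv"))
  write_peaks(peaks, file.path(ddir, "lod_peaks.tsv"))
  jsonlite::write_json(
    list(format = "analysis_bundle", version = 1L,
         datatype = "mRNA", display_name = display_name,
         annotation_tag = annotation_tag,
         lod_threshold = config$lod_threshold,
         cis_window_bp = config$cis_window_bp,
         seed = config$seed,
         package_version = as.character(utils::packageVersion("mosaiceqtl")),
         config = config),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

validate_bundle_elements <- function(genoprobs, kinship, map, expression,
                                     covariates, annotations, peaks, config) {
  elements <- list(genoprobs = genoprobs, kinship = kinship, map = map,
                   expression = expression, covariates = covariates,
                   annotations = annotations, peaks = peaks, config = config)
  missing <- names(elements)[vapply(elements, is.null, logical(1))]
  if (length(missing))
    stop("bundle validation: missing element(s): ",
         paste(missing, collapse = ", "))
  ids <- fp_samples(genoprobs)
  for (nm in c("overall")) {
    if (!identical(rownames(kinship$overall), ids))
      stop("bundle validation: sample ids of kinship do not match genoprobs")
  }
  mism <- function(a, b) paste(utils::head(setdiff(union(a, b), intersect(a, b)), 5),
                               collapse = ", ")
  if (!identical(rownames(expression), ids))
    stop("bundle validation: sample ids of data do not match genoprobs: ",
         mism(rownames(expression), ids))
  if (!identical(covariates$sample_id, ids))
    stop("bundle validation: sample ids of covar.matrix do not match genoprobs: ",
         mism(covariates$sample_id, ids))
  thr <- config$lod_threshold
  if (nrow(peaks) && any(peaks$lod <= thr))
    stop("bundle validation: lod.peaks contains peaks at or below the threshold ", thr)
  invisible(TRUE)
}

#' Load and re-validate an analysis bundle
#'
#' @param dir Bundle directory written by [assemble_bundle()].
#' @return List with the reloaded elements and manifest.
#' @export
read_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  if (!identical(man$format, "analysis_bundle")) stop("not an analysis bundle: ", dir)
  genoprobs <- read_founder_probs(file.path(dir, "genoprobs"))
  kdir <- file.path(dir, "kinship")
  loco_files <- list.files(kdir, pattern = "^loco_")
  kinship <- list(overall = read_matrix_tsv(file.path(kdir, "overall.tsv")),
                  loco = lapply(loco_files, function(f) read_matrix_tsv(file.path(kdir, f))))
  names(kinship$loco) <- sub("^loco_(.*)\\.tsv$", "\\1", loco_files)
  class(kinship) <- "kinship_set"
  map <- read_marker_map(file.path(dir, "markers.tsv"))
  ddir <- file.path(dir, "dataset")
  out <- list(
    genoprobs = genoprobs, kinship = kinship, map = map,
    annotations = read_table_tsv(file.path(ddir, "annot_mrna.tsv")),
    covariates = read_table_tsv(file.path(ddir, "annot_samples.tsv")),
    covar_matrix = read_matrix_tsv(file.path(ddir, "covar_matrix.tsv")),
    expression = read_matrix_tsv(file.path(ddir, "data.tsv")),
    peaks = read_peaks(file.path(ddir, "lod_peaks.tsv")),
    manifest = man)
  out$annotations$chromosome <- as.character(out$annotations$chromosome)
  validate_bundle_elements(out$genoprobs, out$kinship, out$map, out$expression,
                           out$covariates, out$annotations, out$peaks,
                           man$config)
  out
}
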