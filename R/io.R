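# Plain-text (TSV/JSON) input and output. All coordinates written by the
# package are 1-based bp with inclusive cis windows; tabular writers
# state this in a leading comment header. Doubles are serialized with
# %.17g so that write -> read round-trips are bit-exact.

COORD_HEADER <- "# coordinates: 1-based bp; cis windows inclusive"

fmt_num <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

write_tsv_precise <- function(df, path, header_comment = COORD_HEADER) {
  out <- df
  for (j in seq_along(out)) out[[j]] <- fmt_num(out[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(header_comment, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read a marker map as TSV
#'
#' @param map Marker map data frame.
#' @param path File path.
#' @return The path (write) or the validated map (read).
#' @export
write_marker_map <- function(map, path) {
  validate_marker_map(map)
  write_tsv_precise(map, path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  map <- read_tsv(path)
  map$chromosome <- as.character(map$chromosome)
  validate_marker_map(map)
  map
}

#' Write / read a samples x features numeric matrix as TSV
#'
#' First column `sample_id`, then one column per feature.
#'
#' @param mat Numeric matrix with sample-id rownames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(mat, path) {
  if (nrow(mat) == 0) stop("refusing to write a 0-sample matrix")
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_precise(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  if (nrow(df) == 0) stop("empty input: no samples in ", path)
  if (names(df)[1] != "sample_id") stop("malformed header: first column must be sample_id")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample ids: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' Write / read covariate and annotation tables as TSV
#'
#' @param df Data frame.
#' @param path File path.
#' @export
write_table_tsv <- function(df, path) write_tsv_precise(df, path)

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) read_tsv(path)

#' Write founder probabilities to a directory container
#'
#' A hierarchical single-container layout in plain text: a
#' `manifest.json` (chromosomes, dimensions, founder codes), `samples.tsv`
#' and `markers.tsv` index tables, and one `probs_<chrom>.tsv` per
#' chromosome with samples in rows and `<marker>.<founder>` columns.
#'
#' @param probs `founder_probs` object.
#' @param dir Container directory (created if needed).
#' @export
write_founder_probs <- function(probs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  map <- fp_map(probs)
  jsonlite::write_json(
    list(format = "founder_probs_container", version = 1L,
         chromosomes = names(probs), n_samples = dim(probs[[1]])[1],
         founders = founder_codes()),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  write_tsv_precise(data.frame(sample_id = fp_samples(probs)),
                    file.path(dir, "samples.tsv"))
  write_marker_map(map, file.path(dir, "markers.tsv"))
  for (ch in names(probs)) {
    a <- probs[[ch]]
    flat <- matrix(a, nrow = dim(a)[1])
    colnames(flat) <- as.vector(outer(dimnames(a)[[2]], dimnames(a)[[3]],
                                      function(f, m) paste(m, f, sep = ".")))
    rownames(flat) <- dimnames(a)[[1]]
    write_matrix_tsv(flat, file.path(dir, paste0("probs_", ch, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_founder_probs
#' @export
read_founder_probs <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  if (!identical(man$format, "founder_probs_container"))
    stop("not a founder_probs container: ", dir)
  map <- read_marker_map(file.path(dir, "markers.tsv"))
  samples <- read_tsv(file.path(dir, "samples.tsv"))$sample_id
  if (!length(samples)) stop("empty input: container has 0 samples")
  probs <- list()
  for (ch in man$chromosomes) {
    flat <- read_matrix_tsv(file.path(dir, paste0("probs_", ch, ".tsv")))
    mk <- map$marker_id[map$chromosome == ch]
    a <- array(flat, dim = c(nrow(flat), 8, length(mk)),
               dimnames = list(samples, founder_codes(), mk))
    # verify the column order matches marker-major, founder-minor layout
    expect <- as.vector(outer(founder_codes(), mk,
                              function(f, m) paste(m, f, sep = ".")))
    if (!identical(colnames(flat), expect))
      stop("probability columns out of order on chromosome ", ch)
    probs[[ch]] <- a
  }
  structure(probs, map = map, class = c("founder_probs", "list"))
}

#' Write / read an eQTL peak table as TSV
#'
#' Fixed 14-column layout: `gene_id`, `chromosome`, `peak_marker`,
#' `peak_bp`, `lod`, `cis_trans`, then the eight founder-effect columns
#' `eff_A` ... `eff_H`.
#'
#' @param peaks Peak table (missing effect columns are filled with NA).
#' @param path File path.
#' @export
write_peaks <- function(peaks, path) {
  cols <- c("gene_id", "chromosome", "peak_marker", "peak_bp", "lod",
            "cis_trans", paste0("eff_", founder_codes()))
  for (cc in setdiff(cols, names(peaks))) peaks[[cc]] <- rep(NA_real_, nrow(peaks))
  write_tsv_precise(peaks[, cols, drop = FALSE], path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  pk <- read_tsv(path)
  pk$chromosome <- as.character(pk$chromosome)
  if (ncol(pk) != 14) stop("peak table must have 14 columns, found ", ncol(pk))
  pk
}

#' Default run configuration
#'
#' The tunable thresholds of the pipeline in one list: LOD threshold
#' (peaks must exceed 7), cis window (2 Mb, inclusive), scale-free R^2
#' target (0.9), paraclique parameters (|0.5| edge threshold, seed >= 5,
#' final size >= 10, glom 0.2), module minimum size (30), mixup
#' acceptance correlation (0.8), and simulation scale.
#'
#' @param ... Overrides of the defaults.
#' @return Config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_samples = 192, n_genes = 120, n_filler_genes = 400, n_chromosomes = 3,
    chrom_length_mb = 100, markers_per_chromosome = 50,
    crossover_density = 30, prob_blur_alpha = 0.05,
    qtl_var_frac = 0.2, h2_polygenic = 0.4, p_qtl = 0.5,
    lod_threshold = 7, cis_window_bp = 2e6,
    soft_powers = 1:12, r2_target = 0.9,
    min_module_size = 30, cut_height = 0.99,
    paraclique_threshold = 0.5, min_seed = 5, min_size = 10, glom = 0.2,
    min_accept_r = 0.8, seed = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Write / read a run configuration (lossless JSON round-trip)
#'
#' @param config Config list.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if ("soft_powers" %in% names(cfg)) cfg$soft_powers <- as.integer(cfg$soft_powers)
  cfg
}
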