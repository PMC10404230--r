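#' Build a marker map with evenly spaced markers
#'
#' Creates a grid marker map: `markers_per_chromosome` markers per
#' chromosome, evenly spaced in bp from position 1 to the chromosome end,
#' with genetic positions derived at a fixed 0.5 cM/Mb.
#'
#' @param n_chromosomes Number of chromosomes (labelled `"1"`, `"2"`, ...).
#' @param chrom_length_mb Chromosome length in Mb (scalar or one per
#'   chromosome).
#' @param markers_per_chromosome Number of markers per chromosome (>= 2).
#' @param seed Accepted for interface uniformity with the other
#'   simulators; the grid map is deterministic.
#'
#' @return A data frame with columns `marker_id`, `chromosome`,
#'   `position_bp`, `position_cM`, sorted by chromosome then position.
#' @export
#' @examples
#' map <- make_marker_map(2, 100, 50)
#' head(map)
make_marker_map <- function(n_chromosomes, chrom_length_mb,
                            markers_per_chromosome, seed = NULL) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 2)
  if (any(chrom_length_mb <= 0)) stop("chromosome lengths must be positive")
  len <- rep_len(chrom_length_mb, n_chromosomes)
  maps <- lapply(seq_len(n_chromosomes), function(ci) {
    bp <- round(seq(1, len[ci] * 1e6, length.out = markers_per_chromosome))
    data.frame(
      marker_id = sprintf("c%d_m%03d", ci, seq_along(bp)),
      chromosome = as.character(ci),
      position_bp = as.integer(bp),
      position_cM = bp * CM_PER_BP,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  validate_marker_map(map)
  map
}

#' Validate a marker map
#'
#' Checks marker-id uniqueness and that positions are strictly increasing
#' in bp (and non-decreasing in cM) within each chromosome.
#'
#' @param map Marker map data frame.
#' @return The map, invisibly. Errors name the offending chromosome.
#' @export
validate_marker_map <- function(map) {
  need <- c("marker_id", "chromosome", "position_bp", "position_cM")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("marker map missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(map$marker_id))
    stop("duplicated marker ids: ",
         paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  if (any(map$position_bp < 0)) stop("negative bp positions")
  for (ch in unique(map$chromosome)) {
    sub <- map[map$chromosome == ch, ]
    if (any(diff(sub$position_bp) <= 0))
      stop("positions not strictly increasing in bp on chromosome ", ch)
    if (any(diff(sub$position_cM) < 0))
      stop("cM positions decreasing on chromosome ", ch)
  }
  invisible(map)
}

map_chromosomes <- function(map) unique(map$chromosome)

map_split <- function(map) split(map, factor(map$chromosome, levels = map_chromosomes(map)))
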