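#' Export eQTL gene sets (cis/trans, overall and per chromosome)
#'
#' Groups peak genes into the standard deposition sets: all cis genes,
#' all trans genes, and cis/trans sets per peak chromosome. Empty sets
#' are omitted; genes within a set are unique.
#'
#' @param peaks Classified peak table (with `cis_trans`).
#' @return Named list of character vectors of gene ids, with a
#'   `descriptions` attribute.
#' @export
export_gene_sets <- function(peaks) {
  stopifnot("cis_trans" %in% names(peaks))
  sets <- list()
  desc <- character(0)
  for (cls in c("cis", "trans")) {
    sel <- peaks[peaks$cis_trans == cls, , drop = FALSE]
    if (nrow(sel)) {
      nm <- paste0(cls, "-all")
      sets[[nm]] <- unique(sel$gene_id)
      desc[nm] <- paste("all", cls, "eQTL genes")
      for (ch in unique(sel$chromosome)) {
        nm2 <- paste0(cls, "-chr", ch)
        sets[[nm2]] <- unique(sel$gene_id[sel$chromosome == ch])
        desc[nm2] <- paste(cls, "eQTL genes with peak on chromosome", ch)
      }
    }
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets as a GMT file
#'
#' One line per set: name, description, then tab-separated gene ids.
#'
#' @param sets Named list of character vectors (names must be unique).
#' @param path Output path.
#' @param descriptions Optional named descriptions (default: taken from
#'   the `descriptions` attribute, else the set name).
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == ""))
    stop("gene sets must have unique non-empty names")
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file path.
#' @return Named list of gene-id vectors with a `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicated set names in GMT file")
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[`, character(1), 2), names(sets))
  sets
}
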