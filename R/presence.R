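#' Construct a presence-absence assemblage matrix
#'
#' Bundles a binary site-by-taxon matrix with site and taxon identifiers and
#' (optionally) per-site cell-center coordinates in decimal degrees. This is
#' the data object every model-fitting and lineage operation consumes.
#'
#' @param m binary matrix, sites in rows and taxa in columns; entries must be
#'   exactly 0 or 1.
#' @param site_ids character vector of unique site labels, one per row.
#'   Defaults to `rownames(m)` or `site_1 ... site_N`.
#' @param taxon_ids character vector of unique taxon labels, one per column.
#'   Defaults to `colnames(m)` or `taxon_1 ... taxon_G`.
#' @param coords optional data frame with columns `site_id`, `lat`, `lon`
#'   giving cell-center coordinates (degrees) for every site.
#' @return An object of class `presence_absence`: a list with elements `m`
#'   (integer matrix with dimnames), `site_ids`, `taxon_ids`, `coords`.
#' @examples
#' pa <- presence_absence(matrix(c(1, 0, 0, 1), 2, 2))
#' dim(pa$m)
#' @export
presence_absence <- function(m, site_ids = NULL, taxon_ids = NULL,
                             coords = NULL) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) {
    bad <- which(!(m %in% c(0, 1)))[1L]
    stop(sprintf(
      "presence matrix must be binary; entry [%d, %d] is %s",
      row(m)[bad], col(m)[bad], format(m[bad])
    ))
  }
  storage.mode(m) <- "integer"
  site_ids <- as.character(site_ids %||% rownames(m) %||%
    paste0("site_", seq_len(nrow(m))))
  taxon_ids <- as.character(taxon_ids %||% colnames(m) %||%
    paste0("taxon_", seq_len(ncol(m))))
  if (length(site_ids) != nrow(m)) stop("site_ids length != number of rows")
  if (length(taxon_ids) != ncol(m)) stop("taxon_ids length != number of columns")
  if (anyDuplicated(site_ids)) stop("duplicate site ids")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon ids")
  dimnames(m) <- list(site_ids, taxon_ids)
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    need <- c("site_id", "lat", "lon")
    if (!all(need %in% names(coords))) {
      stop("coords must have columns site_id, lat, lon")
    }
    if (!setequal(coords$site_id, site_ids)) {
      stop("coords site ids do not match matrix site ids")
    }
    coords <- coords[match(site_ids, coords$site_id), need]
    rownames(coords) <- NULL
  }
  structure(
    list(m = m, site_ids = site_ids, taxon_ids = taxon_ids, coords = coords),
    class = "presence_absence"
  )
}

#' @export
print.presence_absence <- function(x, ...) {
  cat(sprintf(
    "presence_absence: %d sites x %d taxa, fill %.3f%s\n",
    nrow(x$m), ncol(x$m), mean(x$m),
    if (is.null(x$coords)) "" else ", with coordinates"
  ))
  invisible(x)
}

#' @export
dim.presence_absence <- function(x) dim(x$m)

#' Read a presence-absence matrix from disk
#'
#' Supports two encodings: a dense CSV whose first column holds site ids and
#' whose header row holds taxon ids, or a sparse Matrix Market (`.mtx`) file
#' accompanied by two one-column id files (`<stem>.sites.txt`,
#' `<stem>.taxa.txt`, one id per line, rows then columns).
#'
#' @param path path to the `.csv` or `.mtx` file.
#' @param coords_path optional CSV with columns `site_id`, `lat`, `lon`.
#' @return A [presence_absence] object.
#' @export
read_presence_matrix <- function(path, coords_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    site_ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    taxon_ids <- colnames(m)
    for (j in seq_len(ncol(m))) {
      bad <- which(!(m[, j] %in% c(0, 1)))
      if (length(bad)) {
        stop(sprintf(
          "non-binary value %s at site '%s', taxon '%s'",
          format(m[bad[1L], j]), site_ids[bad[1L]], taxon_ids[j]
        ))
      }
    }
  } else if (ext == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    sites_file <- paste0(stem, ".sites.txt")
    taxa_file <- paste0(stem, ".taxa.txt")
    if (!file.exists(sites_file) || !file.exists(taxa_file)) {
      stop("MTX input requires id files ", sites_file, " and ", taxa_file)
    }
    site_ids <- readLines(sites_file)
    taxon_ids <- readLines(taxa_file)
  } else {
    stop("unsupported presence matrix format: .", ext)
  }
  coords <- NULL
  if (!is.null(coords_path)) {
    coords <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  }
  presence_absence(m, site_ids = site_ids, taxon_ids = taxon_ids,
                   coords = coords)
}

#' Write a presence-absence matrix to disk
#'
#' @param pa a [presence_absence] object.
#' @param path output path; `.csv` writes the dense encoding, `.mtx` the
#'   sparse encoding plus `<stem>.sites.txt` / `<stem>.taxa.txt` id files.
#' @param coords_path optional path for the site-coordinates CSV (written
#'   only when `pa` carries coordinates).
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(pa, path, coords_path = NULL) {
  stopifnot(inherits(pa, "presence_absence"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- data.frame(site_id = pa$site_ids, pa$m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(pa$m, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(pa$site_ids, paste0(stem, ".sites.txt"))
    writeLines(pa$taxon_ids, paste0(stem, ".taxa.txt"))
  } else {
    stop("unsupported presence matrix format: .", ext)
  }
  if (!is.null(coords_path) && !is.null(pa$coords)) {
    utils::write.csv(pa$coords, coords_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
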