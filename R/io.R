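#' Construct and validate a Section
#'
#' A Section is the spot-level container for one tissue section: spot ids,
#' spot-centre coordinates (µm, image convention: y grows downward), the spot
#' diameter, the spot x cell-type abundance matrix, and optionally an
#' annotation layer.
#'
#' @param section_id character scalar.
#' @param spot_ids character vector, no duplicates.
#' @param coords numeric matrix (n x 2, columns x/y in µm).
#' @param spot_diameter spot diameter in µm.
#' @param abundance numeric matrix, n x D, non-negative finite, with cell-type
#'   column names; rows aligned with `spot_ids`.
#' @param annotations optional `ect_annotations` layer.
#' @return validated object of class `ect_section`.
#' @export
new_section <- function(section_id, spot_ids, coords, spot_diameter,
                        abundance, annotations = NULL) {
  coords <- as.matrix(coords)
  colnames(coords) <- c("x", "y")
  obj <- structure(list(section_id = as.character(section_id),
                        spot_ids = as.character(spot_ids),
                        coords = coords,
                        spot_diameter = spot_diameter,
                        abundance = as.matrix(abundance),
                        annotations = annotations),
                   class = "ect_section")
  validate_section(obj)
}

#' @rdname new_section
#' @param x an `ect_section` to validate.
#' @export
validate_section <- function(x) {
  stopifnot(inherits(x, "ect_section"))
  n <- length(x$spot_ids)
  if (anyDuplicated(x$spot_ids))
    stop2("duplicate spot ids: ",
          paste(unique(x$spot_ids[duplicated(x$spot_ids)]), collapse = ", "))
  if (nrow(x$coords) != n || ncol(x$coords) != 2L)
    stop2("coords must be an n x 2 matrix aligned with spot_ids")
  if (!all(is.finite(x$coords))) stop2("non-finite spot coordinates")
  if (!is.numeric(x$spot_diameter) || x$spot_diameter <= 0)
    stop2("spot_diameter must be > 0")
  ab <- x$abundance
  if (nrow(ab) != n) stop2("abundance rows not aligned with spot_ids")
  if (is.null(colnames(ab)) || anyDuplicated(colnames(ab)))
    stop2("abundance must have unique cell-type column names")
  if (any(!is.finite(ab))) stop2("non-finite abundance values")
  if (any(ab < 0)) stop2("negative abundance values")
  if (!is.null(rownames(ab)) && !identical(rownames(ab), x$spot_ids))
    stop2("abundance row names disagree with spot_ids")
  rownames(x$abundance) <- x$spot_ids
  x
}

#' Construct an annotation layer
#'
#' @param features list of features; each a list with `label` (a compartment
#'   name) and `rings` (list of closed two-column coordinate matrices, µm).
#' @param vocabulary allowed labels; defaults to [ect_compartments()].
#' @return object of class `ect_annotations`.
#' @export
new_annotations <- function(features, vocabulary = ect_compartments()) {
  labels <- vapply(features, `[[`, "", "label")
  bad <- setdiff(unique(labels), vocabulary)
  if (length(bad))
    stop2("annotation labels outside the vocabulary: ", paste(bad, collapse = ", "))
  features <- lapply(features, function(f) {
    f$rings <- lapply(f$rings, function(r) {
      r <- as.matrix(r)
      if (nrow(r) < 4L) stop2("polygon ring with fewer than 3 distinct vertices")
      if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])  # close the ring
      if (any(!is.finite(r))) stop2("non-finite polygon coordinates")
      unname(r)
    })
    f
  })
  structure(list(features = features), class = "ect_annotations")
}

#' Read a Section from disk
#'
#' Reads a spot table (TSV: spot_id, x_um, y_um, section_id), an abundance
#' matrix (dense TSV with a spot_id first column and cell-type header, or
#' Matrix Market `.mtx` with `<path>.rows`/`<path>.cols` sidecar files), and
#' optionally a GeoJSON annotation file. Abundance rows are re-indexed to the
#' spot-table order.
#'
#' @param spot_path path to the spot TSV.
#' @param abundance_path path to the abundance TSV or MTX.
#' @param annotation_path optional path to a GeoJSON FeatureCollection.
#' @param spot_diameter spot diameter in µm.
#' @return an `ect_section`.
#' @export
read_section <- function(spot_path, abundance_path, annotation_path = NULL,
                         spot_diameter = 55) {
  spots <- read.delim(spot_path, check.names = FALSE,
                      colClasses = c(spot_id = "character"))
  need <- c("spot_id", "x_um", "y_um", "section_id")
  if (!all(need %in% names(spots)))
    stop2("spot table must have columns: ", paste(need, collapse = ", "))
  ab <- read_abundance(abundance_path)
  missing <- setdiff(rownames(ab), spots$spot_id)
  if (length(missing))
    stop2("abundance references spots absent from the spot table: ",
          paste(head(missing, 5L), collapse = ", "))
  missing2 <- setdiff(spots$spot_id, rownames(ab))
  if (length(missing2))
    stop2("spot table references spots absent from the abundance matrix: ",
          paste(head(missing2, 5L), collapse = ", "))
  ab <- ab[spots$spot_id, , drop = FALSE]
  ann <- if (!is.null(annotation_path)) read_annotations_geojson(annotation_path)
  new_section(section_id = spots$section_id[1L], spot_ids = spots$spot_id,
              coords = cbind(x = spots$x_um, y = spots$y_um),
              spot_diameter = spot_diameter, abundance = ab, annotations = ann)
}

read_abundance <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rows"))
    cn <- readLines(paste0(path, ".cols"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop2("MTX sidecar row/col files do not match the matrix dimensions")
    dimnames(m) <- list(rn, cn)
    m
  } else {
    df <- read.delim(path, check.names = FALSE,
                     colClasses = c(spot_id = "character"))
    if (names(df)[1L] != "spot_id") stop2("abundance TSV must start with spot_id")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$spot_id
    m
  }
}

#' Write a Section to disk
#'
#' Inverse of [read_section()]: writes the spot table and abundance matrix
#' (and annotations when present) in the formats `read_section()` accepts.
#'
#' @param section an `ect_section`.
#' @param spot_path,abundance_path,annotation_path output paths
#'   (`annotation_path` ignored when the section has no annotations).
#' @param sparse write the abundance as Matrix Market with sidecars.
#' @return invisibly, the paths written.
#' @export
write_section <- function(section, spot_path, abundance_path,
                          annotation_path = NULL, sparse = FALSE) {
  stopifnot(inherits(section, "ect_section"))
  spots <- data.frame(spot_id = section$spot_ids,
                      x_um = section$coords[, 1], y_um = section$coords[, 2],
                      section_id = section$section_id)
  write.table(spots, spot_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sparse) {
    if (!grepl("\\.mtx$", abundance_path))
      stop2("sparse abundance path must end in .mtx")
    Matrix::writeMM(Matrix::Matrix(section$abundance, sparse = TRUE),
                    abundance_path)
    writeLines(section$spot_ids, paste0(abundance_path, ".rows"))
    writeLines(colnames(section$abundance), paste0(abundance_path, ".cols"))
  } else {
    df <- data.frame(spot_id = section$spot_ids, section$abundance,
                     check.names = FALSE)
    write.table(df, abundance_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(section$annotations) && !is.null(annotation_path))
    write_annotations_geojson(section$annotations, annotation_path)
  invisible(c(spot_path, abundance_path, annotation_path))
}

#' Read / write annotation layers as GeoJSON
#'
#' RFC 7946 FeatureCollection; Polygon / MultiPolygon geometries with a
#' `label` property; coordinates in µm in the section frame.
#'
#' @param path file path.
#' @return for the reader, an `ect_annotations`.
#' @export
read_annotations_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop2("expected a GeoJSON FeatureCollection")
  feats <- lapply(gj$features, function(f) {
    geom <- f$geometry
    ringify <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ringify),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ringify)),
                            recursive = FALSE),
      stop2("unsupported geometry type: ", geom$type))
    list(label = f$properties$label, rings = rings)
  })
  new_annotations(feats)
}

#' @rdname read_annotations_geojson
#' @param layer an `ect_annotations`.
#' @export
write_annotations_geojson <- function(layer, path) {
  stopifnot(inherits(layer, "ect_annotations"))
  features <- lapply(layer$features, function(f) {
    coords <- lapply(f$rings, function(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
    list(type = "Feature",
         properties = list(label = f$label),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write pipeline artifacts and a run manifest
#'
#' Writes any of the pipeline's tabular artifacts (data.frames) as TSV into a
#' run directory together with a `manifest.tsv` listing each file, the
#' configuration hash and the seed.
#'
#' @param dir run directory (created if needed).
#' @param artifacts named list of data.frames; names become `<name>.tsv`.
#' @param config flat named list describing the run configuration.
#' @param seed the seed used for the run.
#' @return invisibly, the manifest data.frame.
#' @export
write_results <- function(dir, artifacts = list(), config = list(), seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop2("cannot create run directory: ", dir)
  files <- character(0)
  for (nm in names(artifacts)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    write.table(artifacts[[nm]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- data.frame(
    key = c("config_hash", "seed", if (length(files)) paste0("file_", seq_along(files))),
    value = c(config_hash(config), as.character(seed), files))
  write.table(manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
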