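#' Discretize a deconvolved abundance matrix into integer cell counts
#'
#' Converts posterior-quantile abundance estimates into integer pseudo-cell
#' counts per spot and cell type: values are rounded up (ceiling) for every
#' cell type except the declared cancer types, which are rounded down (floor).
#' Zeros stay zero under both rules.
#'
#' @param abundance numeric spot x cell-type matrix, non-negative.
#' @param cancer_types character vector of cancer cell-type names (subset of
#'   the matrix columns).
#' @return integer matrix of the same shape and dimnames.
#' @export
discretize_abundance <- function(abundance, cancer_types = character(0)) {
  abundance <- as.matrix(abundance)
  if (any(!is.finite(abundance)) || any(abundance < 0))
    stop2("abundance must be non-negative and finite")
  unknown <- setdiff(cancer_types, colnames(abundance))
  if (length(unknown))
    stop2("unknown cancer type(s): ", paste(unknown, collapse = ", "))
  counts <- ceiling(abundance)
  cancer <- colnames(abundance) %in% cancer_types
  if (any(cancer))
    counts[, cancer] <- floor(abundance[, cancer, drop = FALSE])
  storage.mode(counts) <- "integer"
  counts
}

#' Place pseudo-cells inside their spots
#'
#' Expands an integer spot x cell-type count matrix into a pseudo-single-cell
#' map: for each spot and type, `count` points are placed at the spot centre
#' plus an independent uniform offset within a disc of `jitter_radius` (40 µm
#' by default, inside the 55 µm spot footprint), so co-located cells do not
#' overplot.
#'
#' @param counts integer spot x cell-type matrix (e.g. from
#'   [discretize_abundance()]), rows aligned with the section's spots.
#' @param section an `ect_section` providing spot coordinates.
#' @param jitter_radius radius of the uniform jitter disc, µm; must not exceed
#'   the spot diameter.
#' @param seed integer seed for the jitter draws.
#' @return a `data.frame` of class `ect_cellmap` with columns cell_type, x_um,
#'   y_um, spot_id, section_id and attribute `jitter_radius`.
#' @export
place_pseudocells <- function(counts, section, jitter_radius = 40, seed = 1L) {
  stopifnot(inherits(section, "ect_section"))
  counts <- as.matrix(counts)
  if (nrow(counts) != length(section$spot_ids))
    stop2("counts rows not aligned with section spots")
  if (any(counts < 0)) stop2("negative pseudo-cell count")
  if (any(counts != floor(counts))) stop2("counts must be integers")
  if (jitter_radius < 0 || jitter_radius > section$spot_diameter)
    stop2("jitter_radius must be in [0, spot_diameter]")
  set.seed(seed %% 2147483647)
  n_cell <- sum(counts)
  spot_idx <- rep(rep(seq_len(nrow(counts)), times = ncol(counts)),
                  times = as.vector(counts))
  type_idx <- rep(rep(seq_len(ncol(counts)), each = nrow(counts)),
                  times = as.vector(counts))
  if (n_cell > 0) {
    # uniform over a disc: sqrt-radius times random angle
    r <- jitter_radius * sqrt(runif(n_cell))
    theta <- runif(n_cell, 0, 2 * pi)
    x <- section$coords[spot_idx, 1] + r * cos(theta)
    y <- section$coords[spot_idx, 2] + r * sin(theta)
  } else {
    x <- y <- numeric(0)
  }
  out <- data.frame(
    cell_type = colnames(counts)[type_idx],
    x_um = x, y_um = y,
    spot_id = section$spot_ids[spot_idx],
    section_id = rep(section$section_id, n_cell))
  attr(out, "jitter_radius") <- jitter_radius
  class(out) <- c("ect_cellmap", "data.frame")
  out
}

#' Build a pseudo-single-cell map for one section
#'
#' Convenience wrapper: [discretize_abundance()] then [place_pseudocells()].
#'
#' @inheritParams place_pseudocells
#' @inheritParams discretize_abundance
#' @param section an `ect_section`.
#' @return an `ect_cellmap` (see [place_pseudocells()]).
#' @export
build_cellmap <- function(section, cancer_types = character(0),
                          jitter_radius = 40, seed = 1L) {
  counts <- discretize_abundance(section$abundance, cancer_types)
  place_pseudocells(counts, section, jitter_radius = jitter_radius, seed = seed)
}

#' Combine per-section cell maps
#'
#' @param ... `ect_cellmap` objects (or a single list of them).
#' @return a single `ect_cellmap` with all rows.
#' @export
bind_cellmaps <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && !inherits(maps[[1L]], "data.frame"))
    maps <- maps[[1L]]
  out <- do.call(rbind, lapply(maps, as.data.frame))
  attr(out, "jitter_radius") <- attr(maps[[1L]], "jitter_radius")
  class(out) <- c("ect_cellmap", "data.frame")
  out
}
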