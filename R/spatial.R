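# chunked min distance from each row of A to the rows of B (both n x 2)
min_cross_dist <- function(A, B) {
  nb <- nrow(B)
  out <- numeric(nrow(A))
  chunk <- max(1L, floor(4e6 / nb))
  b2 <- rowSums(B^2)
  for (start in seq(1L, nrow(A), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(A))
    a <- A[idx, , drop = FALSE]
    d2 <- outer(rowSums(a^2), b2, "+") - 2 * tcrossprod(a, B)
    out[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Nearest-distance table between cell types
#'
#' For every pseudo-cell and every *other* cell type present in the same
#' section, the Euclidean distance to the nearest pseudo-cell of that type.
#' Sections are never pooled: distances are computed within each section and
#' a (reference cell, target type) row is emitted only when the target type
#' has at least one cell in that section.
#'
#' @param cellmap an `ect_cellmap` (one or several sections).
#' @return data.frame: section_id, cell_index (row index within the section's
#'   cell map), reference_type, target_type, nearest_distance (µm).
#' @export
nearest_distance_table <- function(cellmap) {
  if (nrow(cellmap) == 0L) stop2("empty cell map")
  res <- list()
  for (sid in unique(cellmap$section_id)) {
    cm <- cellmap[cellmap$section_id == sid, , drop = FALSE]
    xy <- cbind(cm$x_um, cm$y_um)
    types <- unique(cm$cell_type)
    by_type <- split(seq_len(nrow(cm)), cm$cell_type)
    for (tt in types) {
      tgt <- xy[by_type[[tt]], , drop = FALSE]
      ref_idx <- which(cm$cell_type != tt)
      if (!length(ref_idx)) next
      d <- min_cross_dist(xy[ref_idx, , drop = FALSE], tgt)
      res[[length(res) + 1L]] <- data.frame(
        section_id = sid, cell_index = ref_idx,
        reference_type = cm$cell_type[ref_idx],
        target_type = tt, nearest_distance = d)
    }
  }
  if (!length(res))
    return(data.frame(section_id = character(0), cell_index = integer(0),
                      reference_type = character(0), target_type = character(0),
                      nearest_distance = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rank cell types by median distance to an anchor type
#'
#' Pools all sections' rows targeting the anchor type and ranks each reference
#' type by its median nearest distance, ascending (closest first); ties broken
#' by type name.
#'
#' @param table a [nearest_distance_table()] result.
#' @param anchor_type target cell type to rank against (e.g. cancer cells).
#' @return data.frame: reference_type, median_distance, rank.
#' @export
rank_by_median_distance <- function(table, anchor_type) {
  rows <- table[table$target_type == anchor_type, , drop = FALSE]
  if (!nrow(rows)) stop2("anchor type absent from the distance table: ", anchor_type)
  med <- vapply(split(rows$nearest_distance, rows$reference_type),
                median, numeric(1))
  ord <- order(med, names(med))
  data.frame(reference_type = names(med)[ord],
             median_distance = unname(med)[ord],
             rank = seq_along(med))
}

#' Shannon diversity index of a composition
#'
#' H = -sum p_i log(p_i) over the positive parts, natural log, after internal
#' renormalization of non-negative input.
#'
#' @param fractions non-negative numeric vector with positive sum.
#' @return the Shannon index (nats).
#' @export
shannon_index <- function(fractions) {
  if (any(!is.finite(fractions)) || any(fractions < 0))
    stop2("fractions must be non-negative and finite")
  s <- sum(fractions)
  if (s <= 0) stop2("all-zero composition has no Shannon index")
  p <- fractions[fractions > 0] / s
  -sum(p * log(p))
}

#' Transfer annotation polygons to spots
#'
#' Assigns each spot a compartment label from the overlap of its circular
#' footprint (disc of the section's spot diameter) with the annotation
#' polygons. The label with the largest covered area fraction wins (majority
#' area), except that the cancer label is assigned outright whenever its
#' fraction exceeds `cancer_threshold` (default 0.30). Spots overlapping no
#' polygon are "unassigned". Area fractions are computed by a deterministic
#' equal-area quadrature of `n_points` points over the spot disc.
#'
#' @param layer an `ect_annotations`.
#' @param section an `ect_section`.
#' @param cancer_label label subject to the threshold exception.
#' @param cancer_threshold fraction in (0, 1).
#' @param n_points quadrature points per spot.
#' @return named character vector of labels, one per spot id.
#' @export
transfer_annotations <- function(layer, section,
                                 cancer_label = "Cancer cells",
                                 cancer_threshold = 0.30,
                                 n_points = 400L) {
  stopifnot(inherits(layer, "ect_annotations"), inherits(section, "ect_section"))
  if (cancer_threshold <= 0 || cancer_threshold >= 1)
    stop2("cancer_threshold must be in (0, 1)")
  feats <- layer$features
  labels <- vapply(feats, `[[`, "", "label")
  bbox <- t(vapply(feats, function(f) {
    xs <- unlist(lapply(f$rings, function(r) r[, 1]))
    ys <- unlist(lapply(f$rings, function(r) r[, 2]))
    c(min(xs), max(xs), min(ys), max(ys))
  }, numeric(4)))
  r_spot <- section$spot_diameter / 2
  out <- character(length(section$spot_ids))
  for (i in seq_along(section$spot_ids)) {
    cx <- section$coords[i, 1]; cy <- section$coords[i, 2]
    cand <- which(bbox[, 1] <= cx + r_spot & bbox[, 2] >= cx - r_spot &
                  bbox[, 3] <= cy + r_spot & bbox[, 4] >= cy - r_spot)
    if (!length(cand)) { out[i] <- "unassigned"; next }
    pts <- disc_quadrature(cx, cy, r_spot, n_points)
    frac <- numeric(0)
    for (lab in unique(labels[cand])) {
      inside <- rep(FALSE, n_points)
      for (fi in cand[labels[cand] == lab]) {
        in_feat <- rep(FALSE, n_points)
        for (ring in feats[[fi]]$rings)   # even-odd across rings (holes)
          in_feat <- xor(in_feat, points_in_ring(pts, ring))
        inside <- inside | in_feat
      }
      frac[lab] <- mean(inside)
    }
    out[i] <- if (!is.na(frac[cancer_label]) &&
                  frac[cancer_label] > cancer_threshold) {
      cancer_label
    } else if (all(frac == 0)) {
      "unassigned"
    } else {
      pos <- frac[frac > 0]
      names(pos)[order(-pos, names(pos))][1L]   # majority; ties lexicographic
    }
  }
  setNames(out, section$spot_ids)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test with exact p by exhaustive enumeration of all group
#' assignments when the combined sample size is at most `exact_max` (handles
#' ties exactly), and the normal approximation with tie correction and
#' continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_max enumeration cutoff on `length(x) + length(y)`.
#' @return list: statistic (rank sum of `x`), p_value, method.
#' @export
rank_sum_test <- function(x, y, exact_max = 20L) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx < 1L || ny < 1L) stop2("both samples must be non-empty")
  rk <- rank(c(x, y))
  w <- sum(rk[seq_len(nx)])
  if (n <= exact_max) {
    sets <- utils::combn(n, nx)
    ws <- colSums(matrix(rk[sets], nrow = nx))
    p <- min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
    list(statistic = w, p_value = p, method = "exact enumeration")
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(rk)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = w, p_value = 1,
                                 method = "normal approximation"))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    list(statistic = w, p_value = min(1, 2 * pnorm(-abs(z))),
         method = "normal approximation")
  }
}

#' Compartment enrichment of cell states (one-versus-all)
#'
#' For each annotated compartment and each member state of a parent cell type:
#' computes the per-section proportion of that state among the parent type's
#' pseudo-cells falling in the compartment, then tests the state's per-section
#' proportions against the pooled per-section proportions of all other member
#' states with a two-sided Wilcoxon rank-sum test ("one versus all").
#' Direction is enriched/depleted by median comparison. A pooled Fisher's
#' exact test of state counts across compartments is reported alongside.
#'
#' @param cellmap an `ect_cellmap` covering one or more sections.
#' @param spot_annotation named character vector: compartment label per spot id
#'   (e.g. from [transfer_annotations()], concatenated over sections).
#' @param member_states cell-type names forming the parent cell type.
#' @param min_sections minimum sections contributing to test a compartment.
#' @return list: `enrichment` (state, compartment, n_sections, median_prop,
#'   median_other, p_value, p_adj, direction), `pooled_fisher_p`, `counts`
#'   (state x compartment pooled cell counts), `skipped` (compartments with
#'   too few contributing sections).
#' @export
compartment_enrichment <- function(cellmap, spot_annotation, member_states,
                                   min_sections = 2L) {
  cells <- cellmap[cellmap$cell_type %in% member_states, , drop = FALSE]
  if (!nrow(cells)) stop2("no pseudo-cells of the requested states")
  cells$compartment <- unname(spot_annotation[cells$spot_id])
  cells <- cells[!is.na(cells$compartment) &
                 cells$compartment != "unassigned", , drop = FALSE]
  if (!nrow(cells)) stop2("no annotated pseudo-cells of the requested states")
  counts <- table(factor(cells$cell_type, levels = member_states),
                  cells$compartment)
  pooled_p <- if (nrow(counts) < 2L || ncol(counts) < 2L) NA_real_ else
    tryCatch(
      fisher.test(counts, hybrid = TRUE, workspace = 2e7)$p.value,
      error = function(e) {
        set.seed(1L)
        fisher.test(counts, simulate.p.value = TRUE, B = 10000L)$p.value
      })
  rows <- list(); skipped <- character(0)
  for (comp in colnames(counts)) {
    cc <- cells[cells$compartment == comp, , drop = FALSE]
    secs <- unique(cc$section_id)
    if (length(secs) < min_sections) {
      skipped <- c(skipped, comp)
      next
    }
    # per-section state proportions among the parent type in this compartment
    prop <- t(vapply(secs, function(s) {
      tab <- table(factor(cc$cell_type[cc$section_id == s],
                          levels = member_states))
      as.vector(tab / sum(tab))
    }, numeric(length(member_states))))
    colnames(prop) <- member_states
    for (st in member_states) {
      x <- prop[, st]
      y <- as.vector(prop[, setdiff(member_states, st), drop = FALSE])
      tst <- rank_sum_test(x, y)
      dir <- if (median(x) > median(y)) "enriched"
             else if (median(x) < median(y)) "depleted" else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        state = st, compartment = comp, n_sections = length(secs),
        median_prop = median(x), median_other = median(y),
        p_value = tst$p_value, direction = dir)
    }
  }
  enr <- if (length(rows)) do.call(rbind, rows) else
    data.frame(state = character(0), compartment = character(0),
               n_sections = integer(0), median_prop = numeric(0),
               median_other = numeric(0), p_value = numeric(0),
               direction = character(0))
  enr$p_adj <- stats::p.adjust(enr$p_value, method = "BH")
  rownames(enr) <- NULL
  list(enrichment = enr, pooled_fisher_p = pooled_p, counts = counts,
       skipped = skipped)
}
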