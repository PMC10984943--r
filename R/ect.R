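#' Mean cell-type composition per niche
#'
#' Converts each spot's abundance row to proportions and averages them per
#' niche, pooling spots across sections (unweighted).
#'
#' @param niche_labels named integer vector of niche labels keyed by spot id
#'   (covering every spot of `sections`).
#' @param sections list of `ect_section` sharing one cell-type list.
#' @return niche x cell-type matrix of mean proportions (rows sum to 1).
#' @export
niche_composition <- function(niche_labels, sections) {
  ct <- colnames(sections[[1L]]$abundance)
  ab <- do.call(rbind, lapply(sections, `[[`, "abundance"))
  miss <- setdiff(rownames(ab), names(niche_labels))
  if (length(miss))
    stop2("unlabeled spot(s): ", paste(head(miss, 5L), collapse = ", "))
  lab <- niche_labels[rownames(ab)]
  rs <- rowSums(ab)
  if (any(rs <= 0)) stop2("spot with zero total abundance has no composition")
  p <- ab / rs
  m <- rowsum(p, lab) / as.vector(table(lab))
  rownames(m) <- paste0("niche", rownames(m))
  colnames(m) <- ct
  m
}

#' Centre and scale a niche-composition matrix per cell type
#'
#' For each cell type (column), subtracts the mean over niches and divides by
#' the sample standard deviation over niches, as done for heatmap display and
#' co-occurrence clustering. Constant cell types are set to all-zero with a
#' warning.
#'
#' @param m niche x cell-type matrix with >= 2 niches.
#' @return matrix of the same shape; each non-constant column has mean 0 and
#'   sd 1.
#' @export
scale_composition <- function(m) {
  if (nrow(m) < 2L) stop2("scaling needs at least 2 niches")
  mu <- colMeans(m)
  s <- apply(m, 2L, sd)
  const <- s == 0
  if (any(const)) {
    warning("constant cell type(s) set to zero: ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    s[const] <- 1
  }
  out <- sweep(sweep(m, 2L, mu), 2L, s, `/`)
  out[, const] <- 0
  out
}

#' Cluster cell types into EcoCellTypes
#'
#' Agglomerative clustering of cell-type profiles across niches (columns of
#' the scaled matrix) with Euclidean distance and Ward linkage (Ward.D2:
#' squared distances inside the merge criterion). `k` may be an integer cut or
#' `"auto"`, which maximizes the mean silhouette width over
#' k in [2, min(15, D-1)]. ECT ids are numbered by dendrogram leaf order.
#'
#' @param scaled niche x cell-type matrix from [scale_composition()].
#' @param k integer number of groups, or `"auto"`.
#' @return list of class `ect_model`: `membership` (named integer vector,
#'   cell type -> ECT id), `n_ect`, `hclust`, `silhouette` (mean widths per
#'   candidate k when `k = "auto"`).
#' @export
cluster_ect <- function(scaled, k = "auto") {
  d <- ncol(scaled)
  if (d < 2L) stop2("need at least 2 cell types")
  profiles <- t(scaled)                     # cell types x niches
  dd <- dist(profiles)
  hc <- hclust(dd, method = "ward.D2")
  sil <- NULL
  if (identical(k, "auto")) {
    ks <- 2:min(15L, d - 1L)
    sil <- vapply(ks, function(kk) {
      cl <- cutree(hc, k = kk)
      mean(cluster::silhouette(cl, dd)[, "sil_width"])
    }, numeric(1))
    names(sil) <- ks
    k <- ks[which.max(sil)]
  } else {
    k <- as.integer(k)
    if (k < 1L || k > d) stop2("k must be in [1, number of cell types]")
  }
  raw <- cutree(hc, k = k)
  # renumber by dendrogram leaf order: first leaf's group becomes ECT 1
  leaf_groups <- raw[hc$order]
  map <- setNames(seq_along(unique(leaf_groups)), unique(leaf_groups))
  membership <- setNames(as.integer(map[as.character(raw)]), colnames(scaled))
  structure(list(membership = membership, n_ect = k, hclust = hc,
                 silhouette = sil),
            class = "ect_model")
}

#' Aggregate cell-type fractions into EcoCellType fractions
#'
#' ECT fraction = sum of the member cell types' fractions; row sums are
#' preserved exactly, so compositional rows stay compositional.
#'
#' @param fractions samples x cell-type matrix or data.frame of fractions.
#' @param membership named integer vector, cell type -> ECT id (e.g. from
#'   [cluster_ect()]).
#' @return samples x ECT matrix with columns `ECT<id>`.
#' @export
ect_fractions <- function(fractions, membership) {
  fr <- as.matrix(fractions)
  miss <- setdiff(names(membership), colnames(fr))
  if (length(miss))
    stop2("missing cell-type column(s): ", paste(miss, collapse = ", "))
  fr <- fr[, names(membership), drop = FALSE]
  out <- t(rowsum(t(fr), group = membership))
  colnames(out) <- paste0("ECT", colnames(out))
  out[, order(as.integer(sub("ECT", "", colnames(out)))), drop = FALSE]
}
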