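#' Helmert-type ILR contrast basis
#'
#' Fixed sequential-binary orthonormal contrast matrix for the isometric
#' log-ratio transform: (D-1) x D, rows orthonormal, each row orthogonal to
#' the all-ones vector.
#'
#' @param d number of compositional parts (>= 2).
#' @return (d-1) x d numeric matrix.
#' @export
ilr_basis <- function(d) {
  if (d < 2L) stop2("ILR needs at least 2 parts")
  basis <- matrix(0, d - 1L, d)
  for (i in seq_len(d - 1L)) {
    basis[i, seq_len(i)] <- 1 / sqrt(i * (i + 1))
    basis[i, i + 1L] <- -sqrt(i / (i + 1))
  }
  basis
}

#' Isometric log-ratio transform of abundance rows
#'
#' Adds a per-row pseudocount (a fixed fraction of the row mean, so the
#' transform is scale-invariant), converts to proportions, and maps each
#' D-part composition to (D-1) unconstrained coordinates with a fixed
#' Helmert-type orthonormal basis. Euclidean distance between ILR coordinates
#' equals the Aitchison distance between the compositions.
#'
#' @param x numeric matrix (spots x cell types) or a single row vector.
#' @param pseudocount_scale pseudocount as a fraction of the row mean (> 0).
#' @param basis optional precomputed [ilr_basis()].
#' @return matrix of ILR coordinates, n x (D-1).
#' @export
ilr_transform <- function(x, pseudocount_scale = 1e-3, basis = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  d <- ncol(x)
  if (d < 2L) stop2("ILR needs at least 2 parts")
  if (pseudocount_scale <= 0) stop2("pseudocount_scale must be > 0")
  if (any(x < 0)) stop2("abundances must be non-negative")
  basis <- basis %||% ilr_basis(d)
  eps <- pmax(rowMeans(x), .Machine$double.xmin) * pseudocount_scale
  xx <- x + eps
  p <- xx / rowSums(xx)
  lg <- log(p)
  out <- tcrossprod(lg, basis)
  rownames(out) <- rownames(x)
  out
}

# k smallest entries per row of a distance matrix (ties: first index), via
# repeated max.col on the negated matrix.
rowwise_knn <- function(d2, k) {
  idx <- matrix(0L, nrow(d2), k)
  for (j in seq_len(k)) {
    w <- max.col(-d2, ties.method = "first")
    idx[, j] <- w
    d2[cbind(seq_len(nrow(d2)), w)] <- Inf
  }
  idx
}

#' Batch-balanced k-nearest-neighbour graph
#'
#' Connects every spot to its `k` nearest neighbours (Euclidean distance in
#' the embedding) within *each* batch, including its own (self excluded), so
#' no batch dominates a spot's neighbourhood. When a batch has fewer members
#' than `k` (or `k + 1` for a spot's own batch) the count is capped with a
#' message. The directed edge set is symmetrized by union into a simple
#' undirected graph.
#'
#' @param embedding numeric matrix, spots x dims.
#' @param batch factor/character batch (section) label per spot.
#' @param k neighbours per batch (>= 1).
#' @return list of class `ect_bbknn`: `graph` (simple undirected igraph),
#'   `edges` (directed 2-column index matrix, pre-symmetrization), `k`,
#'   `batch`.
#' @export
batch_balanced_knn <- function(embedding, batch, k = 3L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (length(batch) != n) stop2("batch labels not aligned with embedding rows")
  if (k < 1L) stop2("k must be >= 1")
  batch <- as.character(batch)
  idx_by_batch <- split(seq_len(n), batch)
  short <- names(idx_by_batch)[vapply(idx_by_batch, length, 1L) <= k]
  if (length(short))
    message("batch(es) with <= k members; neighbour count capped: ",
            paste(short, collapse = ", "))
  q2 <- rowSums(embedding^2)
  from <- list(); to <- list()
  for (qb in names(idx_by_batch)) {
    qi <- idx_by_batch[[qb]]
    qe <- embedding[qi, , drop = FALSE]
    for (tb in names(idx_by_batch)) {
      ti <- idx_by_batch[[tb]]
      own <- identical(qb, tb)
      kk <- min(k, length(ti) - as.integer(own))
      if (kk < 1L) next
      d2 <- outer(q2[qi], q2[ti], "+") - 2 * tcrossprod(qe, embedding[ti, , drop = FALSE])
      if (own) d2[cbind(seq_along(qi), seq_along(ti))] <- Inf
      nb <- rowwise_knn(d2, kk)
      from[[length(from) + 1L]] <- rep(qi, kk)
      to[[length(to) + 1L]] <- ti[as.vector(nb)]
    }
  }
  edges <- cbind(unlist(from), unlist(to))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  structure(list(graph = g, edges = edges, k = k, batch = batch),
            class = "ect_bbknn")
}

#' Leiden community detection on a spot graph
#'
#' Leiden optimization of RBConfiguration modularity at the given resolution,
#' with `n_restarts` seeded restarts keeping the best-quality partition.
#' Labels are renumbered by descending community size.
#'
#' @param graph an igraph graph or an `ect_bbknn`.
#' @param resolution resolution parameter (> 0); default 0.6.
#' @param seed integer seed; restarts derive their seeds from it.
#' @param n_restarts number of seeded restarts.
#' @return integer community label per vertex (1 = largest).
#' @export
detect_niches <- function(graph, resolution = 0.6, seed = 1L, n_restarts = 10L) {
  if (inherits(graph, "ect_bbknn")) graph <- graph$graph
  if (!igraph::is_igraph(graph)) stop2("graph must be an igraph or ect_bbknn")
  if (igraph::vcount(graph) == 0L) stop2("empty graph")
  if (resolution <= 0) stop2("resolution must be > 0")
  best <- NULL; best_q <- -Inf
  for (s in derive_seeds(seed, n_restarts)) {
    set.seed(s)
    cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5L)
    memb <- igraph::membership(cl)
    q <- igraph::modularity(graph, memb, resolution = resolution)
    if (q > best_q) { best_q <- q; best <- memb }
  }
  renumber_by_size(as.integer(best))
}

#' Fit the cross-section niche model
#'
#' Full niche-identification pipeline on a list of sections: per-spot ILR
#' transform of cell-type compositions, batch-balanced kNN graph with the
#' section as batch, Leiden community detection, and per-niche centroids in
#' ILR space.
#'
#' @param sections list of `ect_section` objects sharing one cell-type list.
#' @param k_within_batch neighbours per batch in the graph (default 3).
#' @param resolution Leiden resolution (default 0.6).
#' @param pseudocount_scale see [ilr_transform()].
#' @param seed integer seed for community detection.
#' @param graph optional precomputed `ect_bbknn` for these sections (skips
#'   graph construction, e.g. when re-running Leiden with new seeds).
#' @return object of class `ect_niche_model`: cell_types, ilr basis and
#'   pseudocount scale, k, resolution, `embedding`, `batch`, `spot_ids`,
#'   `niche_labels` (named integer vector), `centroids` (niche x (D-1)),
#'   `graph`.
#' @export
fit_niche_model <- function(sections, k_within_batch = 3L, resolution = 0.6,
                            pseudocount_scale = 1e-3, seed = 1L, graph = NULL) {
  ct <- colnames(sections[[1L]]$abundance)
  for (s in sections)
    if (!identical(colnames(s$abundance), ct))
      stop2("sections disagree on cell types")
  ab <- do.call(rbind, lapply(sections, `[[`, "abundance"))
  batch <- unlist(lapply(sections, function(s)
    rep(s$section_id, length(s$spot_ids))))
  spot_ids <- unlist(lapply(sections, `[[`, "spot_ids"))
  basis <- ilr_basis(length(ct))
  emb <- ilr_transform(ab, pseudocount_scale, basis)
  if (is.null(graph))
    graph <- batch_balanced_knn(emb, batch, k_within_batch)
  labels <- detect_niches(graph, resolution = resolution, seed = seed)
  centroids <- rowsum(emb, labels) / as.vector(table(labels))
  structure(list(cell_types = ct, ilr_basis = basis,
                 pseudocount_scale = pseudocount_scale,
                 k_within_batch = k_within_batch, resolution = resolution,
                 embedding = emb, batch = batch, spot_ids = spot_ids,
                 niche_labels = setNames(labels, spot_ids),
                 centroids = centroids, graph = graph),
            class = "ect_niche_model")
}

#' Map niches onto new sections by nearest centroid
#'
#' New spots are ILR-transformed with the model's basis and pseudocount rule
#' and assigned the label of the nearest niche centroid (Euclidean distance in
#' ILR space); the assignment distance is reported as a confidence proxy.
#'
#' @param model an `ect_niche_model`.
#' @param new_sections list of `ect_section` with the model's cell types.
#' @return data.frame: spot_id, section_id, niche, centroid_distance.
#' @export
map_niches <- function(model, new_sections) {
  stopifnot(inherits(model, "ect_niche_model"))
  res <- lapply(new_sections, function(s) {
    ct <- colnames(s$abundance)
    if (!setequal(ct, model$cell_types) || !identical(ct, model$cell_types)) {
      extra <- setdiff(ct, model$cell_types)
      miss <- setdiff(model$cell_types, ct)
      if (length(extra) || length(miss))
        stop2("cell-type mismatch; only in new data: [",
              paste(extra, collapse = ", "), "]; only in model: [",
              paste(miss, collapse = ", "), "]")
      s$abundance <- s$abundance[, model$cell_types, drop = FALSE]
    }
    emb <- ilr_transform(s$abundance, model$pseudocount_scale, model$ilr_basis)
    d2 <- outer(rowSums(emb^2), rowSums(model$centroids^2), "+") -
      2 * tcrossprod(emb, model$centroids)
    nearest <- max.col(-d2, ties.method = "first")
    data.frame(spot_id = s$spot_ids, section_id = s$section_id,
               niche = as.integer(rownames(model$centroids) %||%
                                    seq_len(nrow(model$centroids)))[nearest],
               centroid_distance = sqrt(pmax(d2[cbind(seq_len(nrow(d2)),
                                                      nearest)], 0)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
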