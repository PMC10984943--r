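#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd cor quantile rgamma rnorm runif rexp rbinom
#'   hclust cutree as.dist dist fisher.test pchisq pnorm complete.cases
#'   setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dirichlet random deviates
#'
#' @param n number of draws.
#' @param alpha concentration vector (length D, all > 0).
#' @return n x D matrix of compositions (rows sum to 1).
#' @keywords internal
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# 32-bit FNV-1a over the raw bytes of a string; returned as 8 hex digits.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0x811c9dc5
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # h * m mod 2^32 split into 16-bit halves so doubles stay exact
    h1 <- h %/% 65536
    h <- (((h1 * m) %% 65536) * 65536 + (h %% 65536) * m) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Canonical key=value serialization of a flat list (sorted keys, 15 sig digits)
serialize_config <- function(config) {
  keys <- sort(names(config))
  vals <- vapply(keys, function(k) {
    v <- config[[k]]
    if (is.numeric(v)) paste(format(v, digits = 15, scientific = FALSE), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }, character(1))
  paste0(keys, "=", vals, collapse = "\n")
}

#' Hash a flat configuration list
#'
#' Deterministic 32-bit hash of a flat key=value representation; used in run
#' manifests so downstream artifacts can be matched to the configuration that
#' produced them.
#'
#' @param config named list of scalar/vector fields.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) fnv1a32(serialize_config(config))

# Deterministic equal-area ("sunflower") point layout inside a disc of radius r
# centred at (cx, cy). Each point carries equal weight 1/n.
disc_quadrature <- function(cx, cy, r, n = 400L) {
  j <- seq_len(n)
  rad <- r * sqrt((j - 0.5) / n)
  golden <- pi * (3 - sqrt(5))
  theta <- j * golden
  cbind(x = cx + rad * cos(theta), y = cy + rad * sin(theta))
}

# Even-odd ray-casting point-in-polygon for one ring.
# pts: n x 2 matrix; ring: m x 2 matrix (closed or open ring accepted).
points_in_ring <- function(pts, ring) {
  if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ]))
    ring <- ring[-nrow(ring), , drop = FALSE]
  m <- nrow(ring)
  inside <- rep(FALSE, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  j <- m
  for (i in seq_len(m)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Vertices of a regular hexagon (flat-topped when rot = 0) centred at (cx, cy)
# with circumradius r; returned as a closed ring.
hex_ring <- function(cx, cy, r, rot = pi / 6) {
  ang <- rot + seq(0, 2 * pi, length.out = 7L)
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# Adjusted Rand index between two label vectors (delegated).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Renumber labels as 1..K by decreasing group size (ties: first-seen order).
renumber_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- setNames(seq_along(tab), names(tab))
  as.integer(map[as.character(labels)])
}

# Derive a stream of child seeds (< 2^31) from one base seed.
derive_seeds <- function(seed, n, salt = 0L) {
  (as.numeric(seed) * 48271 + salt * 1009 + seq_len(n) * 63689) %% 2147483647
}
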