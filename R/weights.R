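#' k-nearest-neighbor row-standardized spatial weights
#'
#' Neighbors are the k nearest units by Euclidean distance between weighted
#' centroids, self excluded, with distance ties broken deterministically by
#' ascending `unit_id`. Each row of the weight matrix has exactly k entries
#' of 1/k; kNN asymmetry is preserved (no symmetrization), so downstream
#' estimators must not assume a symmetric W.
#'
#' @param centroids data frame with `unit_id`, `x_km`, `y_km`.
#' @param k number of neighbors (default 3); must satisfy `n > k`.
#' @return object of class `knn_weights`: `n`, `k`, `ids`, `nb` (n x k
#'   neighbor index matrix), `W` (sparse row-standardized matrix), and a
#'   cache environment for eigenvalues/traces.
#' @export
knn_weights <- function(centroids, k = 3L) {
  n <- nrow(centroids)
  if (n <= k) stop("knn_weights: need more units than neighbors (n > k)")
  stopifnot(k >= 1)
  ids <- centroids$unit_id
  id_rank <- rank(ids, ties.method = "first")
  x <- centroids$x_km; y <- centroids$y_km
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    ord <- order(d, id_rank)
    nb[i, ] <- ord[seq_len(k)]
  }
  W <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nb)),
                            x = 1 / k, dims = c(n, n))
  structure(list(n = n, k = k, ids = ids, nb = nb, W = W,
                 cache = new.env(parent = emptyenv())),
            class = "knn_weights")
}

#' @export
print.knn_weights <- function(x, ...) {
  cat(sprintf("<knn_weights> n = %d, k = %d, row-standardized (1/k entries)\n",
              x$n, x$k))
  invisible(x)
}

#' Spatial lag of a vector or matrix
#'
#' @param w a [knn_weights()] object.
#' @param x numeric vector or matrix conformable with `w`.
#' @return `W x` as a base vector/matrix.
#' @export
lag_spatial <- function(w, x) {
  stopifnot(inherits(w, "knn_weights"))
  r <- as.matrix(w$W %*% as.matrix(x))
  if (is.null(dim(x))) drop(r) else r
}

# eigenvalues of W (possibly complex; asymmetric kNN), memoized
w_eigenvalues <- function(w) {
  if (is.null(w$cache$ev))
    w$cache$ev <- eigen(as.matrix(w$W), only.values = TRUE)$values
  w$cache$ev
}

# tr(W^j)/n for j = 0..q, via eigenvalues (real parts; imaginary parts of
# conjugate-pair sums cancel), memoized
w_trace_ratios <- function(w, q) {
  key <- paste0("tr", q)
  if (is.null(w$cache[[key]])) {
    ev <- w_eigenvalues(w)
    w$cache[[key]] <- vapply(0:q, function(j) Re(sum(ev^j)) / w$n, numeric(1))
  }
  w$cache[[key]]
}

#' Moran's I
#'
#' Global spatial autocorrelation,
#' \deqn{I = \frac{n}{S_0} \frac{\tilde z^\top W \tilde z}{\tilde z^\top \tilde z}}
#' with \eqn{\tilde z} mean-centered and \eqn{S_0} the sum of all weights
#' (equal to n for row-standardized W).
#'
#' @param z numeric vector with positive variance.
#' @param w a [knn_weights()] object.
#' @return scalar Moran's I.
#' @export
morans_i <- function(z, w) {
  stopifnot(inherits(w, "knn_weights"), length(z) == w$n)
  zc <- z - mean(z)
  denom <- sum(zc^2)
  if (denom <= 0) stop("morans_i: z is constant (zero variance)")
  s0 <- sum(w$W)
  (w$n / s0) * sum(zc * lag_spatial(w, zc)) / denom
}

#' Write sparse weights as plain-text triples
#'
#' @param w a [knn_weights()] object.
#' @param path output path; one `unit_id, neighbor_id, weight` row per
#'   nonzero entry.
#' @return invisibly, `path`.
#' @export
write_weights <- function(w, path) {
  trip <- data.frame(unit_id = rep(w$ids, each = w$k),
                     neighbor_id = w$ids[as.vector(t(w$nb))],
                     weight = 1 / w$k, stringsAsFactors = FALSE)
  utils::write.csv(trip, path, row.names = FALSE)
  invisible(path)
}
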