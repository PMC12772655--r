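#' Fit a principal-component space on a feature table
#'
#' Features are z-score standardized (constant features dropped with a
#' warning), then the covariance of the standardized features is
#' eigendecomposed.  Component signs follow a deterministic convention
#' (the largest-magnitude loading of each component is positive).  The
#' retained dimensionality `m` is the smallest count whose cumulative
#' explained variance reaches the threshold.
#'
#' @param features numeric matrix or data frame (rows = measurements).
#' @param variance_threshold cumulative explained-variance target
#'   (default 0.95).
#' @param standardize z-score features first (default TRUE).
#' @return object of class `pc_space`: `rotation`, `var_frac`, `m`,
#'   `center`, `scale`, `features` (names used), `dropped`.
#' @export
fit_pca <- function(features, variance_threshold = 0.95, standardize = TRUE) {
  X <- as.matrix(features)
  if (nrow(X) < 2) stop("need at least 2 rows", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant features: ", length(dropped), " of ",
            ncol(X), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(X)
  scl <- if (standardize) sds else rep(1, ncol(X))
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation
  for (k in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) rot[, k] <- -rot[, k]
  }
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  m <- which(cumsum(var_frac) >= variance_threshold)[1]
  structure(list(rotation = rot, var_frac = var_frac, m = m,
                 center = ctr, scale = scl, features = colnames(X),
                 dropped = dropped,
                 variance_threshold = variance_threshold),
            class = "pc_space")
}

#' @export
print.pc_space <- function(x, ...) {
  cat(sprintf("<pc_space> %d features, m = %d components retain %.1f%% variance\n",
              length(x$features), x$m, 100 * sum(x$var_frac[seq_len(x$m)])))
  invisible(x)
}

#' Project feature rows into a fitted principal-component space
#'
#' @param features matrix/data frame containing (at least) the fitted
#'   feature columns, matched by name.
#' @param space a [fit_pca()] result.
#' @param ncomp number of components (default `space$m`).
#' @return numeric matrix, one projected point per row.
#' @export
project_pca <- function(features, space, ncomp = space$m) {
  X <- as.matrix(features)
  if (is.null(colnames(X)) && ncol(X) == length(space$features))
    colnames(X) <- space$features
  if (!all(space$features %in% colnames(X)))
    stop("feature names do not match the fitted space", call. = FALSE)
  X <- X[, space$features, drop = FALSE]
  Z <- sweep(sweep(X, 2, space$center, "-"), 2, space$scale, "/")
  Z %*% space$rotation[, seq_len(ncomp), drop = FALSE]
}

#' Within-cluster distances to the cluster centroid
#'
#' Euclidean distance of every point to its cluster centroid, summarized
#' per cluster as mean and SD.
#'
#' @param points numeric matrix (rows = points).
#' @param cluster_labels vector of labels, one per row.
#' @return data frame: `cluster`, `n`, `mean_distance`, `sd_distance`.
#' @export
within_cluster_distance <- function(points, cluster_labels) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(cluster_labels))
  if (nrow(points) == 0) stop("empty cluster: no points", call. = FALSE)
  labs <- unique(cluster_labels)
  out <- lapply(labs, function(l) {
    p <- points[cluster_labels == l, , drop = FALSE]
    if (nrow(p) == 0) stop("empty cluster '", l, "'", call. = FALSE)
    ctr <- colMeans(p)
    dist <- sqrt(rowSums(sweep(p, 2, ctr, "-")^2))
    data.frame(cluster = l, n = nrow(p), mean_distance = mean(dist),
               sd_distance = if (nrow(p) > 1) sd(dist) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cluster separability
#'
#' Ratio of the mean pairwise distance between cluster centroids to the
#' mean of the per-cluster mean within-cluster distances (all centroid
#' pairs equally weighted).
#'
#' @inheritParams within_cluster_distance
#' @return dimensionless scalar; `Inf` when all clusters are degenerate.
#' @export
separability <- function(points, cluster_labels) {
  points <- as.matrix(points)
  labs <- unique(cluster_labels)
  if (length(labs) < 2) stop("need at least 2 clusters", call. = FALSE)
  centroids <- t(vapply(labs, function(l)
    colMeans(points[cluster_labels == l, , drop = FALSE]),
    numeric(ncol(points))))
  pairs <- utils::combn(length(labs), 2)
  between <- mean(apply(pairs, 2, function(ij)
    sqrt(sum((centroids[ij[1], ] - centroids[ij[2], ])^2))))
  within <- mean(within_cluster_distance(points, cluster_labels)$mean_distance)
  if (within == 0) return(Inf)
  between / within
}

#' Nearest-centroid label recovery rate
#'
#' Fraction of points whose nearest cluster centroid carries their own
#' label; a purity measure of how well points cluster by lesion type.
#'
#' @inheritParams within_cluster_distance
#' @return fraction between 0 and 1.
#' @export
cluster_purity <- function(points, cluster_labels) {
  points <- as.matrix(points)
  labs <- unique(cluster_labels)
  centroids <- t(vapply(labs, function(l)
    colMeans(points[cluster_labels == l, , drop = FALSE]),
    numeric(ncol(points))))
  d2 <- vapply(seq_along(labs), function(k)
    rowSums(sweep(points, 2, centroids[k, ], "-")^2), numeric(nrow(points)))
  mean(labs[max.col(-d2)] == cluster_labels)
}
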