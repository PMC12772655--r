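# Texture feature families on discretized gray-level grids.  Matrices are
# built in C++ over the 13 unique distance-1 3D offsets (26-connectivity
# neighbourhoods for GLSZM/GLDM/NGTDM); directional features are averaged
# over directions.  Formulas follow the harmonized (IBSI-style)
# definitions; gray-level indices are 1-based bin labels, not HU.

xlog2 <- function(p) ifelse(p > 0, log2(p), 0)

#' Gray-level co-occurrence matrices
#'
#' Symmetrized GLCMs for each of the 13 unique distance-1 offsets.
#'
#' @param d a [discretize()] result.
#' @return list of `ng x ng` count matrices, one per direction.
#' @export
glcm_matrix <- function(d) {
  offs <- direction_offsets_13()
  counts <- cpp_glcm(as.integer(d$levels), as.integer(dim(d$levels)),
                     offs, d$ng)
  lapply(seq_len(nrow(offs)), function(k) {
    p <- matrix(counts[, , k], d$ng, d$ng)
    p + t(p)
  })
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) P <- diag(1, ng) # pathological; treated as constant
  p <- P / sum(P)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  k_sum <- 2:(2 * ng)
  pxy_sum <- vapply(k_sum, function(k) sum(p[i + j == k]), numeric(1))
  k_diff <- 0:(ng - 1)
  pxy_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  HX <- -sum(xlog2(px)); HY <- -sum(xlog2(py))
  HXY <- -sum(p * xlog2(p))
  HXY1 <- -sum(p * xlog2(outer(px, py)))
  HXY2 <- -sum(outer(px, py) * xlog2(outer(px, py)))
  DA <- sum(k_diff * pxy_diff)
  corr <- if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  mcc <- {
    if (ng == 1) 1 else {
      Q <- matrix(0, ng, ng)
      nzx <- px > 0
      for (ii in which(nzx)) {
        # Q(i1,i2) = sum_k p(i1,k) p(i2,k) / (px(i1) py(k))
        w <- ifelse(py > 0, p[ii, ] / (px[ii] * py), 0)
        Q[ii, ] <- as.numeric(p %*% w)
      }
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      if (length(ev) < 2) 1 else sqrt(max(ev[2], 0))
    }
  }
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = DA,
    DifferenceEntropy = -sum(pxy_diff * xlog2(pxy_diff)),
    DifferenceVariance = sum((k_diff - DA)^2 * pxy_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * pxy_sum),
    SumEntropy = -sum(pxy_sum * xlog2(pxy_sum)),
    SumSquares = sum((i - mux)^2 * p))
}

#' GLCM texture features (24), averaged over the 13 directions
#' @param d a [discretize()] result.
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(d) {
  mats <- glcm_matrix(d)
  rowMeans(vapply(mats, glcm_features_one,
                  numeric(24)))
}

#' Gray-level run-length matrices (per direction)
#' @param d a [discretize()] result.
#' @return list of `ng x max_run` count matrices.
#' @export
glrlm_matrix <- function(d) {
  offs <- direction_offsets_13()
  maxrun <- max(dim(d$levels))
  counts <- cpp_glrlm(as.integer(d$levels), as.integer(dim(d$levels)),
                      offs, d$ng, maxrun)
  lapply(seq_len(nrow(offs)), function(k)
    matrix(counts[, , k], d$ng, maxrun))
}

glrlm_features_one <- function(R, np) {
  ng <- nrow(R); nrl <- ncol(R)
  nr <- sum(R)
  i <- row(R); r <- col(R)
  p <- R / nr
  ri <- rowSums(R); rr <- colSums(R)
  mu_i <- sum(seq_len(ng) * rowSums(p))
  mu_r <- sum(seq_len(nrl) * colSums(p))
  c(ShortRunEmphasis = sum(R / col(R)^2) / nr,
    LongRunEmphasis = sum(R * col(R)^2) / nr,
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    RunLengthNonUniformity = sum(rr^2) / nr,
    RunLengthNonUniformityNormalized = sum(rr^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    RunVariance = sum(p * (r - mu_r)^2),
    RunEntropy = -sum(p * xlog2(p)),
    LowGrayLevelRunEmphasis = sum(R / row(R)^2) / nr,
    HighGrayLevelRunEmphasis = sum(R * row(R)^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(R / (row(R)^2 * col(R)^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(R * row(R)^2 / col(R)^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(R * col(R)^2 / row(R)^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(R * row(R)^2 * col(R)^2) / nr)
}

#' GLRLM texture features (16), averaged over the 13 directions
#' @param d a [discretize()] result.
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(d) {
  mats <- glrlm_matrix(d)
  rowMeans(vapply(mats, glrlm_features_one, numeric(16), np = d$n_voxels))
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level.
#'
#' @param d a [discretize()] result.
#' @return `ng x max_zone_size` count matrix.
#' @export
glszm_matrix <- function(d) {
  z <- cpp_glszm_zones(as.integer(d$levels), as.integer(dim(d$levels)))
  ns <- max(z$size)
  M <- matrix(0, d$ng, ns)
  for (k in seq_along(z$level))
    M[z$level[k], z$size[k]] <- M[z$level[k], z$size[k]] + 1
  M
}

size_zone_features <- function(M, np, prefix_small = "SmallArea",
                               prefix_large = "LargeArea",
                               size_name = "SizeZone", zone_name = "Zone") {
  ng <- nrow(M)
  nz <- sum(M)
  i <- row(M); s <- col(M)
  p <- M / nz
  gi <- rowSums(M); ss <- colSums(M)
  mu_i <- sum(seq_len(ng) * rowSums(p))
  mu_s <- sum(seq_len(ncol(M)) * colSums(p))
  vals <- c(sum(M / s^2) / nz,
            sum(M * s^2) / nz,
            sum(gi^2) / nz,
            sum(gi^2) / nz^2,
            sum(ss^2) / nz,
            sum(ss^2) / nz^2,
            nz / np,
            sum(p * (i - mu_i)^2),
            sum(p * (s - mu_s)^2),
            -sum(p * xlog2(p)),
            sum(M / i^2) / nz,
            sum(M * i^2) / nz,
            sum(M / (i^2 * s^2)) / nz,
            sum(M * i^2 / s^2) / nz,
            sum(M * s^2 / i^2) / nz,
            sum(M * i^2 * s^2) / nz)
  names(vals) <- c(paste0(prefix_small, "Emphasis"),
                   paste0(prefix_large, "Emphasis"),
                   "GrayLevelNonUniformity",
                   "GrayLevelNonUniformityNormalized",
                   paste0(size_name, "NonUniformity"),
                   paste0(size_name, "NonUniformityNormalized"),
                   paste0(zone_name, "Percentage"),
                   "GrayLevelVariance",
                   paste0(zone_name, "Variance"),
                   paste0(zone_name, "Entropy"),
                   "LowGrayLevelZoneEmphasis",
                   "HighGrayLevelZoneEmphasis",
                   paste0(prefix_small, "LowGrayLevelEmphasis"),
                   paste0(prefix_small, "HighGrayLevelEmphasis"),
                   paste0(prefix_large, "LowGrayLevelEmphasis"),
                   paste0(prefix_large, "HighGrayLevelEmphasis"))
  vals
}

#' GLSZM texture features (16)
#' @param d a [discretize()] result.
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(d) {
  size_zone_features(glszm_matrix(d), d$n_voxels)
}

#' Gray-level dependence matrix
#'
#' Dependence count k = 1 + number of 26-neighbours (in mask) whose level
#' differs from the centre by at most `alpha`.
#'
#' @param d a [discretize()] result.
#' @param alpha dependence tolerance in gray levels (default 0).
#' @return `ng x 27` count matrix (column k = dependence k).
#' @export
gldm_matrix <- function(d, alpha = 0) {
  M <- cpp_gldm(as.integer(d$levels), as.integer(dim(d$levels)), alpha)
  if (nrow(M) < d$ng) M <- rbind(M, matrix(0, d$ng - nrow(M), ncol(M)))
  M
}

#' GLDM texture features (14)
#' @param d a [discretize()] result.
#' @param alpha dependence tolerance (default 0).
#' @return named numeric vector of 14 features.
#' @export
gldm_features <- function(d, alpha = 0) {
  M <- gldm_matrix(d, alpha)
  nz <- sum(M)
  i <- row(M); k <- col(M)
  p <- M / nz
  gi <- rowSums(M); dk <- colSums(M)
  mu_i <- sum(seq_len(nrow(M)) * rowSums(p))
  mu_k <- sum(seq_len(ncol(M)) * colSums(p))
  c(SmallDependenceEmphasis = sum(M / k^2) / nz,
    LargeDependenceEmphasis = sum(M * k^2) / nz,
    GrayLevelNonUniformity = sum(gi^2) / nz,
    DependenceNonUniformity = sum(dk^2) / nz,
    DependenceNonUniformityNormalized = sum(dk^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    DependenceVariance = sum(p * (k - mu_k)^2),
    DependenceEntropy = -sum(p * xlog2(p)),
    LowGrayLevelEmphasis = sum(M / i^2) / nz,
    HighGrayLevelEmphasis = sum(M * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(M / (i^2 * k^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(M * i^2 / k^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(M * k^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(M * i^2 * k^2) / nz)
}

#' Neighbourhood gray-tone difference accumulators
#' @param d a [discretize()] result.
#' @return `ng x 2` matrix: column 1 voxel counts n_i, column 2 summed
#'   absolute differences s_i.
#' @export
ngtdm_matrix <- function(d) {
  cpp_ngtdm(as.integer(d$levels), as.integer(dim(d$levels)), d$ng)
}

#' NGTDM texture features (5)
#' @param d a [discretize()] result.
#' @return named numeric vector: Coarseness, Contrast, Busyness,
#'   Complexity, Strength.  Coarseness is capped at 1e6 for flat regions.
#' @export
ngtdm_features <- function(d) {
  A <- ngtdm_matrix(d)
  n_i <- A[, 1]; s_i <- A[, 2]
  N <- sum(n_i)
  p_i <- n_i / N
  act <- which(p_i > 0)
  ngp <- length(act)
  lv <- seq_len(d$ng)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p_i[act], p_i[act]) *
           outer(lv[act], lv[act], "-")^2) / (ngp * (ngp - 1))) *
      (sum(s_i) / N)
  } else 0
  busy_den <- sum(abs(outer(lv[act] * p_i[act], lv[act] * p_i[act], "-")))
  busyness <- if (ngp > 1 && busy_den > 0) sum(p_i * s_i) / busy_den else 0
  complexity <- if (ngp > 0) {
    num <- 0
    for (a in act) for (b in act)
      num <- num + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
        (p_i[a] + p_i[b])
    num / N
  } else 0
  strength <- if (sum(s_i) > 0) {
    num <- 0
    for (a in act) for (b in act)
      num <- num + (p_i[a] + p_i[b]) * (a - b)^2
    num / sum(s_i)
  } else 0
  c(Coarseness = min(coarseness, 1e6), Contrast = contrast,
    Busyness = busyness, Complexity = complexity, Strength = strength)
}
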