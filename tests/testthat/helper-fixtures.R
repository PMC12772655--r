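# Small fixtures built in code: toy phantom specs, digital shapes and
# brute-force texture-matrix oracles used across test files.

# a reduced single-lesion phantom (fast to rasterize)
toy_phantom_spec <- function(diameter = 80, height = 12,
                             lesion_diameter = 18,
                             lesion_type = "solid",
                             mean_intensity = -100) {
  les <- data.frame(lesion_id = 1L, lesion_type = lesion_type,
                    size_class = "small",
                    max_3d_diameter = lesion_diameter,
                    mean_intensity = mean_intensity, sector = "half",
                    phantom_id = 1L, sector_angle = 90,
                    stringsAsFactors = FALSE)
  list(phantom_id = 1L, diameter = diameter, height = height,
       ring_outer_diameter = diameter + 24,
       lesion_center_radius = diameter / 4, lesions = les,
       include_water_roi = TRUE)
}

no_texture <- list(parenchyma_sd = 0, lesion_sd = 0, corr_mm = 2,
                   highpass_mm = 8)

# digital ball mask on an isotropic grid
digital_ball <- function(radius_mm = 10, spacing = c(0.5, 0.5, 0.5),
                         margin = 2) {
  n <- ceiling(2 * (radius_mm + margin) / spacing) + 1
  ax <- lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * spacing[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  r2 <= radius_mm^2
}

# wrap an integer level array as a discretized_roi
as_droi <- function(levels, spacing = c(1, 1, 1)) {
  structure(list(levels = levels, ng = max(levels), bin_width = 1,
                 spacing = spacing, n_voxels = sum(levels > 0),
                 degenerate = max(levels) == min(levels[levels > 0])),
            class = "discretized_roi")
}

random_level_grid <- function(dims, ng, p_mask = 0.85) {
  arr <- array(sample(0:ng, prod(dims), replace = TRUE,
                      prob = c(1 - p_mask, rep(p_mask / ng, ng))),
               dim = dims)
  if (all(arr == 0)) arr[1] <- 1L
  arr
}

# ---- exhaustive brute-force oracles (independent of the C++ path) ----

bf_glcm <- function(arr, off, ng) {
  P <- matrix(0, ng, ng)
  dm <- dim(arr)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    li <- arr[x, y, z]
    if (li == 0) next
    for (s in c(1, -1)) {
      p2 <- c(x, y, z) + s * off
      if (any(p2 < 1) || any(p2 > dm)) next
      lj <- arr[p2[1], p2[2], p2[3]]
      if (lj == 0) next
      P[li, lj] <- P[li, lj] + 1
    }
  }
  P
}

bf_glrlm <- function(arr, off, ng, maxrun) {
  R <- matrix(0, ng, maxrun)
  dm <- dim(arr)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    li <- arr[x, y, z]
    if (li == 0) next
    prev <- c(x, y, z) - off
    if (all(prev >= 1) && all(prev <= dm) &&
        arr[prev[1], prev[2], prev[3]] == li) next
    len <- 1
    nxt <- c(x, y, z) + off
    while (all(nxt >= 1) && all(nxt <= dm) &&
           arr[nxt[1], nxt[2], nxt[3]] == li) {
      len <- len + 1
      nxt <- nxt + off
    }
    R[li, min(len, maxrun)] <- R[li, min(len, maxrun)] + 1
  }
  R
}

bf_glszm <- function(arr, ng) {
  dm <- dim(arr)
  seen <- array(FALSE, dim = dm)
  zones <- list()
  nbhd <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbhd <- nbhd[rowSums(abs(nbhd)) > 0, ]
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (seen[x, y, z] || arr[x, y, z] == 0) next
    li <- arr[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in seq_len(nrow(nbhd))) {
        p2 <- cur + nbhd[k, ]
        if (any(p2 < 1) || any(p2 > dm)) next
        if (!seen[p2[1], p2[2], p2[3]] &&
            arr[p2[1], p2[2], p2[3]] == li) {
          seen[p2[1], p2[2], p2[3]] <- TRUE
          stack[[length(stack) + 1]] <- p2
        }
      }
    }
    zones[[length(zones) + 1]] <- c(li, size)
  }
  zm <- do.call(rbind, zones)
  M <- matrix(0, ng, max(zm[, 2]))
  for (i in seq_len(nrow(zm))) M[zm[i, 1], zm[i, 2]] <- M[zm[i, 1], zm[i, 2]] + 1
  M
}

bf_gldm <- function(arr, ng, alpha = 0) {
  dm <- dim(arr)
  M <- matrix(0, ng, 27)
  nbhd <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbhd <- nbhd[rowSums(abs(nbhd)) > 0, ]
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    li <- arr[x, y, z]
    if (li == 0) next
    dep <- 0
    for (k in seq_len(nrow(nbhd))) {
      p2 <- c(x, y, z) + nbhd[k, ]
      if (any(p2 < 1) || any(p2 > dm)) next
      lj <- arr[p2[1], p2[2], p2[3]]
      if (lj != 0 && abs(li - lj) <= alpha) dep <- dep + 1
    }
    M[li, dep + 1] <- M[li, dep + 1] + 1
  }
  M
}

bf_ngtdm <- function(arr, ng) {
  dm <- dim(arr)
  acc <- matrix(0, ng, 2)
  nbhd <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbhd <- nbhd[rowSums(abs(nbhd)) > 0, ]
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    li <- arr[x, y, z]
    if (li == 0) next
    vals <- c()
    for (k in seq_len(nrow(nbhd))) {
      p2 <- c(x, y, z) + nbhd[k, ]
      if (any(p2 < 1) || any(p2 > dm)) next
      lj <- arr[p2[1], p2[2], p2[3]]
      if (lj != 0) vals <- c(vals, lj)
    }
    if (!length(vals)) next
    acc[li, 1] <- acc[li, 1] + 1
    acc[li, 2] <- acc[li, 2] + abs(li - mean(vals))
  }
  acc
}
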