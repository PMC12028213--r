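# IBSI-style radiomic features: 18 first-order + 24 GLCM + 16 GLRLM +
# 16 GLSZM + 5 NGTDM + 14 GLDM = 93 features per parametric map.
# Conventions (fixed, pyradiomics-compatible): fixed-bin-width discretisation
# anchored at the ROI minimum; symmetric GLCM and GLRLM over the 13 unique 3D
# directions with direction-averaged features; 26-connectivity for GLSZM
# zones and for GLDM/NGTDM neighbourhoods; GLDM dependence size includes the
# center voxel; entropies in bits (log2).

#' Canonical parametric map names
#' @return Character vector of the 12 map names (9 DCE + 3 DWI).
#' @export
map_names <- function() c("MRE", "TTP", "WIS", "WOS", "WOR", "WIO",
                          "KTRANS", "VE", "VP", "D", "DSTAR", "F")

#' Default discretisation bin widths per parametric map
#'
#' Fixed bin widths (in each map's own units) chosen so typical lesion value
#' ranges discretise to roughly 10-40 gray levels; the maps live on wildly
#' different scales (TTP in seconds, Ve in [0,1]), so a single global width
#' would be meaningless.
#' @return Named numeric vector over [map_names()].
#' @export
default_bin_widths <- function() {
  c(MRE = 25, TTP = 38, WIS = 0.15, WOS = 0.03, WOR = 0.05, WIO = 25000,
    KTRANS = 0.02, VE = 0.05, VP = 0.01, D = 1e-4, DSTAR = 0.01, F = 0.02)
}

#' Discretise ROI values to consecutive gray levels
#'
#' Fixed-bin-width discretisation anchored at the ROI minimum:
#' `level(v) = floor((v - min) / bin_width) + 1`.
#'
#' @param values Finite numeric ROI values.
#' @param bin_width Positive bin width in the map's units.
#' @param max_levels Safety cap on the number of levels (guards against
#'   degenerate bin widths on wide-range maps).
#' @return List with `levels` (integer vector), `n_levels`, `bin_width`,
#'   `range`.
#' @export
discretize <- function(values, bin_width, max_levels = 2000L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite voxels in ROI")
  if (bin_width <= 0) stop("bin_width must be positive")
  lev <- floor((values - min(values)) / bin_width) + 1L
  nlev <- max(lev)
  if (nlev > max_levels)
    stop(sprintf("discretisation yields %d levels (> %d); increase bin_width",
                 nlev, max_levels))
  list(levels = as.integer(lev), n_levels = as.integer(nlev),
       bin_width = bin_width, range = range(values))
}

# entropy helper (bits)
.h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

#' First-order statistical features
#'
#' The 18 first-order features of the IBSI set.  Entropy and Uniformity are
#' computed on the discretised histogram ([discretize()] with `bin_width`);
#' all other features use raw values.  Percentiles use linear interpolation.
#' Skewness and Kurtosis use population moments (Kurtosis is not
#' excess-corrected: a Gaussian gives 3); both are defined as 0 for constant
#' input.
#'
#' @param values Finite numeric ROI values (>= 1).
#' @param bin_width Bin width for the Entropy/Uniformity histogram.
#' @param voxel_volume Voxel volume in mm^3 (TotalEnergy).
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(values, bin_width = 25,
                                 voxel_volume = 1) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  n <- length(values)
  dr <- discretize(values, bin_width)
  p <- tabulate(dr$levels, dr$n_levels) / n
  q <- stats::quantile(values, c(.10, .25, .50, .75, .90), names = FALSE,
                       type = 7)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  inr <- values[values >= q[1L] & values <= q[5L]]
  c(Energy = sum(values^2),
    TotalEnergy = voxel_volume * sum(values^2),
    Entropy = .h(p),
    Minimum = min(values),
    `10Percentile` = q[1L],
    `90Percentile` = q[5L],
    Maximum = max(values),
    Mean = mu,
    Median = q[3L],
    InterquartileRange = q[4L] - q[2L],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(inr)) mean(abs(inr - mean(inr))) else 0,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

# ---- GLCM ------------------------------------------------------------------

glcm_features_one <- function(C) {
  tot <- sum(C)
  P <- C / tot
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  present <- which(px + py > 0)
  Ng <- length(present)
  mux <- sum(i * P); muy <- sum(j * P)
  sigx <- sqrt(sum((i - mux)^2 * P)); sigy <- sqrt(sum((j - muy)^2 * P))
  kd <- 0:(ng - 1)
  pxy_d <- numeric(ng)
  agg_d <- rowsum(as.vector(P), as.vector(abs(i - j)))
  pxy_d[as.integer(rownames(agg_d)) + 1L] <- agg_d
  ks <- 2:(2 * ng)
  pxy_s <- numeric(2 * ng - 1)
  agg_s <- rowsum(as.vector(P), as.vector(i + j))
  pxy_s[as.integer(rownames(agg_s)) - 1L] <- agg_s
  da <- sum(kd * pxy_d)
  hx <- .h(px); hy <- .h(py); hxy <- .h(as.vector(P))
  pp <- outer(px, py)
  sel <- P > 0
  hxy1 <- -sum(P[sel & pp > 0] * log2(pp[sel & pp > 0]))
  hxy2 <- .h(as.vector(pp))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0)) else 0
  mcc <- if (Ng == 1L) 1 else {
    Pp <- P[present, present, drop = FALSE]
    pxp <- px[present]; pyp <- py[present]
    Q <- matrix(0, Ng, Ng)
    for (kk in seq_len(Ng)) {
      denom <- pxp * pyp[kk]
      ok <- denom > 0
      if (any(ok))
        Q[ok, ] <- Q[ok, ] + outer(Pp[ok, kk] / denom[ok], Pp[, kk])
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[min(2L, length(ev))], 0))
  }
  invvar <- { m <- abs(i - j) > 0; sum(P[m] / (i - j)[m]^2) }
  c(Autocorrelation = sum(P * i * j),
    JointAverage = mux,
    ClusterProminence = sum(P * (i + j - mux - muy)^4),
    ClusterShade = sum(P * (i + j - mux - muy)^3),
    ClusterTendency = sum(P * (i + j - mux - muy)^2),
    Contrast = sum(P * (i - j)^2),
    Correlation = if (sigx * sigy > 0)
      (sum(P * i * j) - mux * muy) / (sigx * sigy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = .h(pxy_d),
    DifferenceVariance = sum(pxy_d * (kd - da)^2),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / Ng^2)),
    Idn = sum(P / (1 + abs(i - j) / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = invvar,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * pxy_s),
    SumEntropy = .h(pxy_s),
    SumSquares = sum(P * (i - mux)^2))
}

# ---- run-length / size-zone style families ---------------------------------

glrlm_features_one <- function(P, np) {
  nr <- sum(P)
  ng <- nrow(P); nl <- ncol(P)
  i <- matrix(seq_len(ng), ng, nl); j <- t(matrix(seq_len(nl), nl, ng))
  p <- P / nr
  ri <- rowSums(P); rj <- colSums(P)
  mui <- sum(p * i); muj <- sum(p * j)
  c(ShortRunEmphasis = sum(P / j^2) / nr,
    LongRunEmphasis = sum(P * j^2) / nr,
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    RunLengthNonUniformity = sum(rj^2) / nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(p * (i - mui)^2),
    RunVariance = sum(p * (j - muj)^2),
    RunEntropy = .h(as.vector(p)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr)
}

glszm_features <- function(P, np) {
  nz <- sum(P)
  ng <- nrow(P); ns <- ncol(P)
  i <- matrix(seq_len(ng), ng, ns); j <- t(matrix(seq_len(ns), ns, ng))
  p <- P / nz
  ri <- rowSums(P); rj <- colSums(P)
  mui <- sum(p * i); muj <- sum(p * j)
  c(SmallAreaEmphasis = sum(P / j^2) / nz,
    LargeAreaEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(ri^2) / nz,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nz^2,
    SizeZoneNonUniformity = sum(rj^2) / nz,
    SizeZoneNonUniformityNormalized = sum(rj^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(p * (i - mui)^2),
    ZoneVariance = sum(p * (j - muj)^2),
    ZoneEntropy = .h(as.vector(p)),
    LowGrayLevelZoneEmphasis = sum(P / i^2) / nz,
    HighGrayLevelZoneEmphasis = sum(P * i^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz)
}

gldm_features <- function(P) {
  nz <- sum(P)
  ng <- nrow(P); nd <- ncol(P)
  i <- matrix(seq_len(ng), ng, nd); j <- t(matrix(seq_len(nd), nd, ng))
  p <- P / nz
  ri <- rowSums(P); rj <- colSums(P)
  mui <- sum(p * i); muj <- sum(p * j)
  c(SmallDependenceEmphasis = sum(P / j^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(ri^2) / nz,
    DependenceNonUniformity = sum(rj^2) / nz,
    DependenceNonUniformityNormalized = sum(rj^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mui)^2),
    DependenceVariance = sum(p * (j - muj)^2),
    DependenceEntropy = .h(as.vector(p)),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz)
}

ngtdm_features <- function(M) {
  ni <- M[, 1L]; si <- M[, 2L]
  nvp <- sum(ni)
  if (nvp == 0) stop("degenerate ROI: no voxel has an in-ROI neighbour")
  pi_ <- ni / nvp
  ng <- length(ni)
  lv <- seq_len(ng)
  pres <- which(pi_ > 0)
  ngp <- length(pres)
  coarse_den <- sum(pi_ * si)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  if (ngp > 1) {
    pij <- outer(pi_[pres], pi_[pres])
    dij <- outer(lv[pres], lv[pres], "-")
    contrast <- sum(pij * dij^2) / (ngp * (ngp - 1)) * sum(si) / nvp
    busy_den <- sum(abs(outer(lv[pres] * pi_[pres], lv[pres] * pi_[pres], "-")))
    busyness <- if (busy_den > 0) coarse_den / busy_den else 0
    num <- outer(pi_[pres] * si[pres], pi_[pres] * si[pres], "+")
    complexity <- sum(abs(dij) * num / outer(pi_[pres], pi_[pres], "+")) / nvp
    strength <- if (sum(si) > 0)
      sum(outer(pi_[pres], pi_[pres], "+") * dij^2) / sum(si) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

#' Texture features of a discretised ROI
#'
#' Computes one texture family from the 3D level array of a discretised ROI.
#' GLCM and GLRLM are built per direction over the 13 unique 3D offsets and
#' their features averaged across directions (directions without any voxel
#' pair are skipped); GLSZM zones use 26-connectivity; GLDM uses the
#' 26-neighbourhood with dependence tolerance `alpha` (dependence size
#' includes the center voxel); NGTDM uses the mean level of the valid
#' 26-neighbours.
#'
#' @param level_array Integer 3D array: gray levels 1..n_levels inside the
#'   ROI, 0 outside.
#' @param n_levels Number of gray levels.
#' @param family One of `"glcm"`, `"glrlm"`, `"glszm"`, `"ngtdm"`, `"gldm"`.
#' @param alpha GLDM dependence tolerance (default 0).
#' @return Named numeric vector (24/16/16/5/14 features).
#' @export
texture_features <- function(level_array, n_levels,
                             family = c("glcm", "glrlm", "glszm", "ngtdm",
                                        "gldm"),
                             alpha = 0L) {
  family <- match.arg(family)
  dims <- dim(level_array)
  stopifnot(length(dims) == 3L)
  lv <- as.integer(level_array)
  np <- sum(lv > 0L)
  if (np == 0L) stop("empty ROI")
  switch(family,
    glcm = {
      A <- cpp_glcm(lv, dims, n_levels)
      feats <- NULL
      for (d in seq_len(13L)) {
        C <- matrix(A[, , d], n_levels, n_levels)
        if (sum(C) == 0) next
        feats <- rbind(feats, glcm_features_one(C))
      }
      if (is.null(feats))
        stop("degenerate ROI: no co-occurring voxel pair in any direction")
      colMeans(feats)
    },
    glrlm = {
      A <- cpp_glrlm(lv, dims, n_levels)
      feats <- NULL
      for (d in seq_len(13L)) {
        P <- matrix(A[, , d], n_levels, dim(A)[2L])
        if (sum(P) == 0) next
        feats <- rbind(feats, glrlm_features_one(P, np))
      }
      colMeans(feats)
    },
    glszm = glszm_features(cpp_glszm(lv, dims, n_levels), np),
    gldm = gldm_features(cpp_gldm(lv, dims, n_levels, as.integer(alpha))),
    ngtdm = ngtdm_features(cpp_ngtdm(lv, dims, n_levels))
  )
}

#' Extract the 93-feature vector of one (map, ROI) pair
#'
#' Discretises the masked map values and computes all six feature families.
#' Non-finite map voxels inside the mask are excluded (they occur only
#' outside the fitted region).
#'
#' @param map 3D numeric array (a parametric map).
#' @param mask A [mask3d()] on the same grid.
#' @param bin_width Discretisation bin width in the map's units.
#' @param map_name Optional map name appended to feature names as
#'   `[group]_[name].[MAP]`.
#' @return Named numeric vector of 93 features.
#' @export
extract_feature_vector <- function(map, mask, bin_width, map_name = NULL) {
  check_same_grid(dim(map), dim(mask$data))
  sel <- mask$data & is.finite(map)
  if (!any(sel)) stop("no finite voxels in ROI")
  # crop to the ROI bounding box: texture matrices only involve in-ROI
  # voxels and their immediate neighbours, so this is exact and much faster
  idx <- which(sel, arr.ind = TRUE)
  rng <- apply(idx, 2L, range)
  sel <- sel[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
             rng[1, 3]:rng[2, 3], drop = FALSE]
  map <- map[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
             rng[1, 3]:rng[2, 3], drop = FALSE]
  values <- map[sel]
  dr <- discretize(values, bin_width)
  larr <- array(0L, dim(map))
  larr[sel] <- dr$levels
  vol <- prod(mask$spacing)
  fo <- first_order_features(values, bin_width, vol)
  gl <- texture_features(larr, dr$n_levels, "glcm")
  rl <- texture_features(larr, dr$n_levels, "glrlm")
  sz <- texture_features(larr, dr$n_levels, "glszm")
  ng <- texture_features(larr, dr$n_levels, "ngtdm")
  gd <- texture_features(larr, dr$n_levels, "gldm")
  out <- c(stats::setNames(fo, paste0("firstorder_", names(fo))),
           stats::setNames(gl, paste0("glcm_", names(gl))),
           stats::setNames(rl, paste0("glrlm_", names(rl))),
           stats::setNames(sz, paste0("glszm_", names(sz))),
           stats::setNames(ng, paste0("ngtdm_", names(ng))),
           stats::setNames(gd, paste0("gldm_", names(gd))))
  stopifnot(length(out) == 93L)
  if (!is.null(map_name)) names(out) <- paste0(names(out), ".", map_name)
  out
}

#' Extract the full feature table of a cohort
#'
#' Applies [extract_feature_vector()] to every (lesion, ROI variant, map)
#' triple and assembles the lesion-by-feature table: one row per (lesion,
#' variant), `93 * n_maps` feature columns named `[group]_[name].[MAP]`
#' (1116 columns for the full 12-map set).
#'
#' @param lesions List of lesion entries, each a list with `id`, `maps`
#'   (named list of 3D arrays over [map_names()] or a subset) and `rois`
#'   (named list of [mask3d()], must include `"original"`).
#' @param bin_widths Named bin widths per map, see [default_bin_widths()].
#' @return data.frame with columns `lesion_id`, `roi_variant`, then the
#'   feature columns.
#' @export
extract_feature_table <- function(lesions, bin_widths = default_bin_widths()) {
  rows <- list()
  for (les in lesions) {
    if (is.null(les$maps) || is.null(les$rois) ||
        !"original" %in% names(les$rois))
      stop("each lesion needs `maps` and `rois` (incl. \"original\")")
    mnames <- names(les$maps)
    missing_bw <- setdiff(mnames, names(bin_widths))
    if (length(missing_bw))
      stop("missing bin width for map ", paste(missing_bw, collapse = ", "))
    for (vn in names(les$rois)) {
      fv <- unlist(lapply(mnames, function(mn)
        extract_feature_vector(les$maps[[mn]], les$rois[[vn]],
                               bin_widths[[mn]], mn)))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(lesion_id = les$id, roi_variant = vn),
              as.data.frame(as.list(fv), check.names = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
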