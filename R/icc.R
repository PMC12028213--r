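#' Intraclass correlation coefficient, two-way random effects,
#' absolute agreement, single measurement
#'
#' ICC(2,1) from the mean squares of the two-way ANOVA decomposition of a
#' complete subjects x raters matrix:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square.  Here "raters" are ROI perturbations,
#' whose systematic offsets matter — hence absolute agreement.
#'
#' @param mat Numeric matrix, subjects in rows (>= 2), raters in columns
#'   (>= 2), no missing cells.
#' @return ICC value.  Negative estimates are returned as computed.  A
#'   matrix with zero total variance has trivially perfect agreement: the
#'   value 1 is returned with attribute `degenerate = TRUE`.
#' @export
icc <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  if (anyNA(mat)) stop("missing cells are not supported")
  grand <- mean(mat)
  ss_tot <- sum((mat - grand)^2)
  if (ss_tot == 0) return(structure(1, degenerate = TRUE))
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  ss_r <- k * sum((rm_ - grand)^2)
  ss_c <- n * sum((cm - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
}

#' Agreement category of an ICC value
#'
#' Conventional interpretation thresholds: below 0.5 poor, 0.5 to 0.75
#' moderate, 0.75 to 0.9 good, above 0.9 excellent.  Negative estimates are
#' poor.
#'
#' @param value ICC value(s).
#' @return Factor with levels poor/moderate/good/excellent.
#' @export
icc_category <- function(value) {
  cut(pmax(value, 0), breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
      labels = c("poor", "moderate", "good", "excellent"), right = FALSE)
}

#' Robust feature set under ROI perturbation
#'
#' Scores every feature's reproducibility across the ROI variants with the
#' ICC (lesions as subjects, variants as raters — by default all 16: the
#' original plus the 15 perturbations) and retains features with ICC
#' strictly greater than the threshold ("excellent" agreement).
#'
#' @param table Feature table from [extract_feature_table()]: columns
#'   `lesion_id`, `roi_variant`, then features.  Every lesion must carry
#'   the identical set of variants.
#' @param threshold Retention threshold on the ICC (default 0.9, strict
#'   inequality).
#' @param include_original Include the unperturbed ROI among the raters
#'   (default TRUE).
#' @return List with `retained` (character vector of feature names),
#'   `report` (data.frame: feature, map, icc, category, n_subjects,
#'   n_raters), and `matrix` (features x maps ICC matrix for heatmap-style
#'   display).
#' @export
robust_feature_set <- function(table, threshold = 0.9,
                               include_original = TRUE) {
  stopifnot(all(c("lesion_id", "roi_variant") %in% names(table)))
  if (!include_original)
    table <- table[table$roi_variant != "original", ]
  variants <- sort(unique(table$roi_variant))
  counts <- table(table$lesion_id, table$roi_variant)
  if (any(counts != 1L))
    stop("unbalanced variant coverage: every lesion needs each variant once")
  lesions <- sort(unique(table$lesion_id))
  ord <- order(match(table$lesion_id, lesions),
               match(table$roi_variant, variants))
  table <- table[ord, ]
  feat_cols <- setdiff(names(table), c("lesion_id", "roi_variant"))
  n <- length(lesions); k <- length(variants)
  vals <- vapply(feat_cols, function(fc) {
    m <- matrix(table[[fc]], nrow = n, ncol = k, byrow = TRUE)
    as.numeric(icc(m))
  }, numeric(1))
  base <- sub("\\.[^.]*$", "", feat_cols)
  mapn <- sub(".*\\.", "", feat_cols)
  report <- data.frame(feature = base, map = mapn, icc = vals,
                       category = icc_category(vals),
                       n_subjects = n, n_raters = k, row.names = NULL)
  retained <- feat_cols[vals > threshold]
  feats <- unique(base); maps <- unique(mapn)
  m <- matrix(NA_real_, length(feats), length(maps),
              dimnames = list(feats, maps))
  m[cbind(match(base, feats), match(mapn, maps))] <- vals
  list(retained = retained, report = report, matrix = m)
}
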