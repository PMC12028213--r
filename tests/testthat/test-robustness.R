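test_that("icc is 1 for perfect agreement and ~0 under the null", {
  m <- matrix(rep(c(1, 5, 9, 2), 4), 4, 4)   # identical raters, subjects vary
  expect_equal(icc(m), 1)
  set.seed(10)
  null <- matrix(rnorm(200 * 16), 200, 16)
  expect_lt(abs(icc(null)), 0.1)
  # zero total variance: trivially perfect, flagged
  z <- icc(matrix(3, 5, 4))
  expect_equal(as.numeric(z), 1)
  expect_true(attr(z, "degenerate"))
  expect_error(icc(matrix(1:4, 1, 4)), ">= 2 subjects")
})

test_that("icc approaches the variance-component value 9/(9+1)", {
  set.seed(11)
  n <- 4000
  subj <- rnorm(n, 0, 3)  # subject sd 3x the unit error sd: ICC -> 0.9
  m <- subj + matrix(rnorm(n * 16), n, 16)
  expect_equal(icc(m), 0.9, tolerance = 0.02)
})

test_that("icc is affine invariant and monotone in the variance ratio", {
  set.seed(12)
  m <- rnorm(100, 0, 2) + matrix(rnorm(100 * 8), 100, 8)
  expect_equal(icc(3.7 * m + 11), icc(m), tolerance = 1e-12)
  prev <- -Inf
  for (ratio in c(0.5, 1, 2, 4, 8)) {
    mm <- rnorm(100, 0, ratio) + matrix(rnorm(100 * 8), 100, 8)
    cur <- icc(mm)
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("agreement categories partition [0, 1] at the stated thresholds", {
  v <- c(-0.2, 0, 0.49, 0.5, 0.74, 0.75, 0.89, 0.9, 1)
  expect_equal(as.character(icc_category(v)),
               c("poor", "poor", "poor", "moderate", "moderate", "good",
                 "good", "excellent", "excellent"))
})

make_icc_table <- function(n_lesions = 8, values_fun, seed = 1) {
  set.seed(seed)
  variants <- c("original", paste0("v", 1:15))
  rows <- expand.grid(lesion_id = sprintf("l%02d", seq_len(n_lesions)),
                      roi_variant = variants, stringsAsFactors = FALSE)
  rows <- rows[order(rows$lesion_id), ]
  cbind(rows, values_fun(rows))
}

test_that("robust_feature_set gates at strictly ICC > threshold", {
  # stable feature: constant per lesion, varying between lesions -> kept;
  # noise feature: fresh draw per variant -> excluded
  tb <- make_icc_table(8, function(rows) {
    stable <- as.numeric(factor(rows$lesion_id)) * 2
    data.frame(`firstorder_Mean.VE` = stable,
               `glcm_Contrast.VP` = rnorm(nrow(rows)),
               check.names = FALSE)
  })
  rs <- robust_feature_set(tb)
  expect_true("firstorder_Mean.VE" %in% rs$retained)
  expect_false("glcm_Contrast.VP" %in% rs$retained)
  expect_equal(unique(rs$report$n_raters), 16L)
  expect_equal(dim(rs$matrix), c(2L, 2L))

  # strict inequality: a feature whose ICC equals the threshold is excluded
  r_noise <- rs$report$icc[rs$report$feature == "glcm_Contrast"]
  rs2 <- robust_feature_set(tb, threshold = 1)  # stable feature has ICC 1
  expect_false("firstorder_Mean.VE" %in% rs2$retained)

  # unbalanced coverage errors
  expect_error(robust_feature_set(tb[-1, ]), "unbalanced")
})

test_that("excluding the original ROI leaves 15 raters", {
  tb <- make_icc_table(6, function(rows)
    data.frame(`firstorder_Mean.VE` = rnorm(nrow(rows)),
               check.names = FALSE))
  rs <- robust_feature_set(tb, include_original = FALSE)
  expect_equal(unique(rs$report$n_raters), 15L)
})
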