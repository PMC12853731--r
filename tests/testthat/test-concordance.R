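test_that("Spearman correlation matches brute-force rank arithmetic with ties", {
  expect_equal(spearman_cor(1:10, 1:10)$rho, 1)
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)

  # tied fixture: mid-ranks, then Pearson on the ranks; p from the
  # t-approximation on n - 2 degrees of freedom
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2.0, 1.5, 3.0, 2.5, 4.0, 4.0, 5.0, 4.5)
  res <- spearman_cor(x, y)
  rho_brute <- cor(rank(x), rank(y))
  expect_equal(res$rho, rho_brute, tolerance = 1e-12)
  tstat <- rho_brute * sqrt((8 - 2) / (1 - rho_brute^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 6), tolerance = 1e-12)

  expect_error(spearman_cor(rep(1, 5), 1:5), class = "degenerate_correlation")
  expect_error(spearman_cor(1:2, 1:2), class = "invalid_input")
})

test_that("Bonferroni correction divides the family alpha", {
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.10, 4), 0.025)
  expect_error(bonferroni_alpha(0.05, 0), class = "invalid_input")
})

test_that("agreement pooling: equal weights collapse to the unweighted figure and rescaling is neutral", {
  agrees <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  eq <- agreement_summary(agrees)
  expect_equal(eq$unweighted, eq$weighted)
  expect_equal(eq$unweighted, 60)
  w <- c(5, 1, 0.5, 2, 0.1)
  expect_equal(agreement_summary(agrees, w)$weighted,
               agreement_summary(agrees, 17 * w)$weighted)
})

# build a synthetic concordance problem with designed correlation signs
make_concordance_inputs <- function(n_feat = 20, n_disagree = 2, n_pat = 30) {
  feats <- sprintf("f%02d", seq_len(n_feat))
  xs <- matrix(rep(seq_len(n_pat), n_feat), n_pat,
               dimnames = list(NULL, feats))
  vals <- xs            # attribution = +value => rho = +1 (agrees with +1 PDP)
  disagree <- seq_len(n_disagree)
  vals[, disagree] <- -vals[, disagree]
  attrib <- structure(list(values = vals, feature_names = feats),
                      class = "attribution_matrix")
  dirs <- data.frame(feature = feats, slope_sign = rep(1L, n_feat))
  list(feats = feats, x = as.data.frame(xs), attrib = attrib, dirs = dirs)
}

test_that("concordance report reproduces designed agreement patterns", {
  inp <- make_concordance_inputs(20, 2)
  w_eq <- setNames(rep(1, 20), inp$feats)
  rep1 <- concordance_report(inp$dirs, inp$attrib, inp$x, w_eq)
  expect_equal(rep1$unweighted_agreement, 90)
  expect_equal(rep1$alpha_corrected, 0.0025)
  expect_equal(sum(rep1$rows$agrees), 18)
  expect_true(all(rep1$rows$p_value[rep1$rows$agrees] < 0.0025))

  # discordant features carrying 2.2% of the weight: weighted agreement 97.8%
  w <- setNames(c(rep(0.022 / 2, 2), rep(0.978 / 18, 18)), inp$feats)
  rep2 <- concordance_report(inp$dirs, inp$attrib, inp$x, w)
  expect_equal(rep2$weighted_agreement, 97.8, tolerance = 1e-9)
  expect_equal(rep2$unweighted_agreement, 90)

  # full agreement: both figures 100
  inp0 <- make_concordance_inputs(10, 0)
  rep3 <- concordance_report(inp0$dirs, inp0$attrib, inp0$x,
                             setNames(runif(10, 0.5, 2), inp0$feats))
  expect_equal(rep3$unweighted_agreement, 100)
  expect_equal(rep3$weighted_agreement, 100)
})

test_that("flat PDPs and degenerate correlations are flagged as non-agreeing", {
  inp <- make_concordance_inputs(4, 0)
  inp$dirs$slope_sign[1] <- 0L
  inp$x[[3]] <- rep(1, nrow(inp$x))  # constant feature: rho undefined
  w <- setNames(rep(1, 4), inp$feats)
  rep <- concordance_report(inp$dirs, inp$attrib, inp$x, w)
  expect_false(rep$rows$agrees[1])
  expect_match(rep$rows$flag[1], "flat_pdp")
  expect_false(rep$rows$agrees[3])
  expect_match(rep$rows$flag[3], "degenerate_correlation")
  expect_equal(rep$unweighted_agreement, 50)
})

test_that("misaligned inputs fail loudly, naming the missing feature", {
  inp <- make_concordance_inputs(3, 0)
  w <- setNames(rep(1, 3), inp$feats)
  dirs_extra <- rbind(inp$dirs, data.frame(feature = "ghost", slope_sign = 1L))
  err <- tryCatch(concordance_report(dirs_extra, inp$attrib, inp$x, w),
                  error = function(e) e)
  expect_s3_class(err, "alignment_error")
  expect_match(conditionMessage(err), "ghost")

  w_short <- w[1:2]
  err2 <- tryCatch(concordance_report(inp$dirs, inp$attrib, inp$x, w_short),
                   error = function(e) e)
  expect_s3_class(err2, "alignment_error")
})

test_that("negative importances get zero weight in pooling", {
  inp <- make_concordance_inputs(3, 1)
  recs <- data.frame(feature = inp$feats,
                     relative_influence = c(0.5, 0.5, 0),
                     mean_drop = c(0.1, 0.1, -0.05))
  rep <- concordance_report(inp$dirs, inp$attrib, inp$x, recs)
  # the disagreeing feature f01 carries half the weight
  expect_equal(rep$weighted_agreement, 50)
  expect_equal(rep$rows$importance_weight[3], 0)
})
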