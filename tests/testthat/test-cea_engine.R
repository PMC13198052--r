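test_that("incremental estimates reproduce mean-difference and inversion conventions", {
  # arm mean costs fixed at the cost-utility table's ITT values
  r <- incremental(rep(26621, 4), rep(25418, 4),
                   c(0.7, 0.74), c(0.68, 0.70), "qaly")
  expect_equal(r$delta_cost, 1203)
  expect_equal(r$delta_effect, 0.03)
  expect_equal(r$verdict, "icer")
  expect_equal(r$icer, 1203 / 0.03)
  # deterioration is inverted (CG - IG) and reported in percentage points
  ig <- rep(c(1, 0), c(108, 616 - 108))
  cg <- rep(c(1, 0), c(128, 583 - 128))
  d <- incremental(rep(1, 616), rep(1, 583), ig, cg, "dcdl")
  expect_equal(d$delta_effect, 100 * (128 / 583 - 108 / 616))
  expect_equal(round(d$delta_effect, 2), 4.42)
  # WHODAS inverted: lower score is better
  w <- incremental(rep(1, 3), rep(1, 3), rep(26.06, 3), rep(27.03, 3),
                   "whodas")
  expect_equal(w$delta_effect, 0.97)
})

test_that("dominance classification is exhaustive over the four quadrants and boundaries", {
  mk <- function(dc, de) incremental(c(100 + dc, 100 + dc), c(100, 100),
                                     c(0.5 + de, 0.5 + de), c(0.5, 0.5),
                                     "qaly")
  expect_equal(mk(10, 0.1)$verdict, "icer")
  expect_equal(mk(10, 0.1)$quadrant, "north-east")
  expect_equal(mk(-10, 0.1)$verdict, "intervention_dominates")
  expect_equal(mk(10, -0.1)$verdict, "control_dominates")
  sw <- mk(-10, -0.1)
  expect_equal(sw$verdict, "icer")
  expect_equal(sw$quadrant, "south-west")
  expect_equal(sw$icer, 100)
  expect_equal(mk(10, 0)$verdict, "undefined_icer")
  expect_equal(mk(0, 0)$verdict, "undefined_icer")
  expect_equal(mk(0, 0.1)$icer, 0)   # equally costly, more effective
})

test_that("degenerate resampling collapses the cloud onto the point estimate", {
  cost <- c(rep(1000, 5), rep(800, 5))
  eff <- c(rep(0.8, 5), rep(0.7, 5))
  arm <- rep(c("IG", "CG"), each = 5)
  cl <- bootstrap_cloud(cost, eff, arm, "qaly", B = 50, seed = 1)
  expect_length(unique(cl$delta_cost), 1)
  expect_length(unique(cl$delta_effect), 1)
  expect_equal(unique(cl$delta_cost), 200)
  expect_equal(unique(cl$delta_effect), 0.1)
  expect_equal(diff(percentile_ci(cl$delta_cost)), 0)
})

test_that("the cloud is centred on the point estimate and is seed-deterministic", {
  set.seed(10)
  cost <- c(rgamma(150, 2, scale = 5000), rgamma(140, 2, scale = 4500))
  eff <- c(rnorm(150, 0.7, 0.2), rnorm(140, 0.68, 0.2))
  arm <- rep(c("IG", "CG"), c(150, 140))
  cl <- bootstrap_cloud(cost, eff, arm, "qaly", B = 3000, seed = 2)
  # bootstrap consistency: cloud mean within 2 bootstrap SE of the estimate
  expect_lt(abs(mean(cl$delta_cost) - cl$point$delta_cost),
            2 * sd(cl$delta_cost))
  expect_lt(abs(mean(cl$delta_effect) - cl$point$delta_effect),
            2 * sd(cl$delta_effect))
  cl2 <- bootstrap_cloud(cost, eff, arm, "qaly", B = 3000, seed = 2)
  expect_identical(cl$delta_cost, cl2$delta_cost)
  expect_error(bootstrap_cloud(cost, eff, arm, "qaly", B = 1), "B must")
})

test_that("percentile CI endpoints are order statistics under the inverse-ECDF convention", {
  x <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10)
  ci <- percentile_ci(x, 0.9)
  s <- sort(x)
  expect_equal(ci, c(s[ceiling(10 * 0.05)], s[ceiling(10 * 0.95)]))
})

test_that("CEAC boundary identities hold exactly", {
  set.seed(11)
  cl <- bootstrap_cloud(c(rgamma(80, 2, scale = 5000),
                          rgamma(80, 2, scale = 5000)),
                        c(rnorm(80, 0.72, 0.25), rnorm(80, 0.69, 0.25)),
                        rep(c("IG", "CG"), each = 80), "qaly",
                        B = 2000, seed = 3)
  cc <- ceac(cl, wtp_grid = c(0, 50000, 100000))
  expect_equal(cc$probability[cc$wtp == 0], mean(cl$delta_cost < 0))
  expect_equal(cc$probability[cc$wtp == 0] + mean(cl$delta_cost >= 0), 1)
  expect_error(ceac(cl, wtp_grid = c(-5, 0)), "non-negative")
  # a cloud entirely in the dominant quadrant accepts at every threshold
  dom <- cl
  dom$delta_cost <- -abs(dom$delta_cost) - 1
  dom$delta_effect <- abs(dom$delta_effect) + 1e-6
  expect_true(all(ceac(dom)$probability == 1))
  # monotone nondecreasing whenever every replicate has non-negative effect
  pos <- cl
  pos$delta_effect <- abs(pos$delta_effect)
  expect_true(all(diff(ceac(pos)$probability) >= 0))
})

test_that("the confidence ellipse matches a known isotropic distribution", {
  set.seed(12)
  cl <- structure(list(delta_cost = rnorm(20000), delta_effect = rnorm(20000),
                       effect_kind = "qaly", B = 20000L, seed = 1L),
                  class = "bootstrap_cloud")
  pl <- ce_plane(cl, confidence = 0.95)
  ev <- eigen(pl$cov)$values
  expect_equal(ev[1] / ev[2], 1, tolerance = 0.1)
  # ~95% of points inside the 95% contour
  ctr <- pl$center
  S_inv <- solve(pl$cov)
  xy <- cbind(cl$delta_effect - ctr[1], cl$delta_cost - ctr[2])
  d2 <- rowSums((xy %*% S_inv) * xy)
  expect_equal(mean(d2 <= qchisq(0.95, 2)), 0.95, tolerance = 0.01)
  expect_true(pl$crosses_effect_axis && pl$crosses_cost_axis)
  # shifted cloud with positive effects everywhere: no effect-axis crossing
  cl2 <- cl
  cl2$delta_effect <- cl2$delta_effect + 10
  pl2 <- ce_plane(cl2)
  expect_false(pl2$crosses_effect_axis)
  expect_equal(sum(pl2$quadrant_shares), 1)
  # collinear cloud flagged degenerate
  cl3 <- cl
  cl3$delta_cost <- 2 * cl3$delta_effect
  expect_true(ce_plane(cl3)$degenerate)
})
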