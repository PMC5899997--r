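test_that("Kruskal-Wallis H matches the explicit rank formula", {
  g1 <- c(1, 2, 3); g2 <- c(101, 102, 103); g3 <- c(201, 202, 203)
  vals <- c(g1, g2, g3)
  grp <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskalWallis(vals, grp)
  # oracle: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 (no ties here)
  r <- rank(vals); N <- length(vals)
  rb <- tapply(r, grp, mean)
  H <- 12 / (N * (N + 1)) * sum(3 * (rb - (N + 1) / 2)^2)
  expect_equal(kw$H, unname(H))
  expect_equal(kw$df, 2L)
  expect_equal(kw$p, stats::pchisq(H, 2, lower.tail = FALSE))
  # rank invariance under monotone transforms
  kw2 <- kruskalWallis(exp(vals / 50), grp)
  expect_equal(kw2$H, kw$H)
  # identical data: degenerate, p = 1
  kw3 <- kruskalWallis(rep(5, 9), grp)
  expect_true(kw3$degenerate)
  expect_equal(kw3$p, 1)
})

test_that("Dunn control comparisons match hand-computed rank sums", {
  # fixed small fixture, 3 groups x 4 observations, one tie pair
  ctl <- c(10, 12, 14, 16)
  gA <- c(11, 13, 15, 17)
  gB <- c(30, 31, 32, 16)    # 16 ties with a control value
  vals <- c(ctl, gA, gB)
  grp <- rep(c("ctl", "A", "B"), each = 4)
  d <- dunnVsControl(vals, grp, "ctl")
  # oracle, written out by hand: pooled ranks of the 12 values
  r <- rank(vals)          # ties get average ranks
  N <- 12
  tieSizes <- as.numeric(table(vals))
  tieTerm <- sum(tieSizes^3 - tieSizes) / (12 * (N - 1))
  sigma2 <- (N * (N + 1) / 12 - tieTerm) * (1 / 4 + 1 / 4)
  zA <- (mean(r[5:8]) - mean(r[1:4])) / sqrt(sigma2)
  zB <- (mean(r[9:12]) - mean(r[1:4])) / sqrt(sigma2)
  expect_equal(d$z[d$group == "A"], zA)
  expect_equal(d$z[d$group == "B"], zB)
  expect_equal(d$p, 2 * stats::pnorm(-abs(d$z)))
  # adding a constant everywhere changes nothing
  d2 <- dunnVsControl(vals + 7, grp, "ctl")
  expect_equal(d2$z, d$z)
  # a variant identical to the control scores z = 0, p = 1
  vals3 <- c(ctl, ctl, gB)
  d3 <- dunnVsControl(vals3, rep(c("ctl", "same", "B"), each = 4), "ctl")
  expect_equal(d3$z[d3$group == "same"], 0)
  expect_equal(d3$p[d3$group == "same"], 1)
  # symmetry under swapping variant and control labels
  swapped <- dunnVsControl(vals, rep(c("A", "ctl", "B"), each = 4), "ctl")
  expect_equal(swapped$p[swapped$group == "A"], d$p[d$group == "A"])
  expect_equal(swapped$z[swapped$group == "A"], -d$z[d$group == "A"])
})

test_that("Games-Howell reduces to Welch's t with two groups", {
  set.seed(5)
  a <- rnorm(12, 0, 1); b <- rnorm(9, 1, 3)
  gh <- gamesHowellVsControl(c(a, b), rep(c("ctl", "v"), c(12, 9)), "ctl")
  wt <- stats::t.test(b, a)
  expect_equal(gh$p, wt$p.value, tolerance = 1e-8)
  expect_equal(gh$t, unname(wt$statistic), tolerance = 1e-10)
  expect_equal(gh$df, unname(wt$parameter), tolerance = 1e-10)
  # identical groups give p = 1
  gh2 <- gamesHowellVsControl(rep(c(1, 2, 3), 2),
                              rep(c("ctl", "v"), each = 3), "ctl")
  expect_equal(gh2$p, 1)
})

test_that("Games-Howell p matches a quadrature studentized-range oracle", {
  set.seed(8)
  vals <- c(rnorm(10, 0, 1), rnorm(8, 2, 4), rnorm(12, -1, 0.5),
            rnorm(9, 0.5, 2))
  grp <- rep(c("ctl", "a", "b", "c"), c(10, 8, 12, 9))
  gh <- gamesHowellVsControl(vals, grp, "ctl")
  k <- 4
  # oracle: P(Q_{k,df} > q) by direct numerical integration of the
  # studentized-range CDF (outer integral over the scale chi, inner over
  # the location normal), written independently of stats::ptukey
  rangeCdf <- function(x, k) {
    stats::integrate(function(z)
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - x))^(k - 1),
      -9, 9, rel.tol = 1e-10)$value
  }
  tukeyTail <- function(q, k, df) {
    dchi <- function(s) 2 * (df / 2)^(df / 2) / gamma(df / 2) *
      s^(df - 1) * exp(-df * s^2 / 2)
    1 - stats::integrate(Vectorize(function(s) dchi(s) * rangeCdf(q * s, k)),
                         0, 5, rel.tol = 1e-8)$value
  }
  for (i in seq_len(nrow(gh))) {
    expect_equal(gh$p[i], tukeyTail(gh$q[i], k, gh$df[i]),
                 tolerance = 1e-5, label = paste("group", gh$group[i]))
  }
})

test_that("the Bonferroni family threshold is alpha over the test count", {
  th <- bonferroniThreshold(14, 7, 0.05)
  expect_equal(th$threshold, 0.05 / 98)
  expect_equal(th$display, 0.00051)
  expect_equal(bonferroniThreshold(1, 1, 0.05)$threshold, 0.05)
  expect_equal(bonferroniThreshold(2, 5, 0.1)$threshold, 0.01)
})

test_that("variant comparisons assign direction and respect the tiers", {
  ref <- nav14ReferenceCohorts()
  cells <- simulateParameterTable(ref[ref$variant_id %in%
    c("WT", "Arg1463Ser", "Val1442Met"), ], seed = 4)
  cmp <- compareVariants(cells, "WT", "kw_dunn")
  expect_equal(sort(unique(cmp$variant_id)),
               c("Arg1463Ser", "Val1442Met"))
  expect_equal(unique(cmp$threshold), 0.05 / (2 * 7))
  expect_true(all(cmp$significant == (cmp$p_raw < cmp$threshold)))
  expect_true(all(cmp$direction[!cmp$significant] == "none"))
  # strong printed effects carry their expected directions
  pick <- function(v, p) cmp[cmp$variant_id == v & cmp$parameter == p, ]
  expect_equal(pick("Val1442Met", "inact_V12_mV")$direction, "lower")
  expect_equal(pick("Val1442Met", "tau_rec_ms")$direction, "higher")
  expect_equal(pick("Arg1463Ser", "tau_rec_ms")$direction, "lower")
  expect_equal(pick("Arg1463Ser", "inact_V12_mV")$direction, "higher")
  # a cohort drawn identical to wild type yields no significant calls
  null <- ref[ref$variant_id == "WT", ]
  null2 <- null; null2$variant_id <- "COPY"
  cellsN <- simulateParameterTable(rbind(null, null2), seed = 99)
  cmpN <- compareVariants(cellsN, "WT", "kw_dunn")
  expect_false(any(cmpN$significant))
})

test_that("functional classification follows the precedence rules", {
  mk <- function(parameter, direction, mean_variant = 1, mean_wt = 0,
                 significant = TRUE)
    data.frame(variant_id = "V", parameter = parameter, method = "kw_dunn",
               statistic = 5, p_raw = ifelse(significant, 1e-6, 0.5),
               threshold = 0.00051, significant = significant,
               direction = ifelse(significant, direction, "none"),
               mean_variant = mean_variant, mean_wt = mean_wt)
  # no significant parameter: wild-type like, empty evidence
  wtl <- classifyVariant(mk("inact_V12_mV", "none", significant = FALSE))
  expect_equal(wtl$label, "wild_type_like")
  expect_equal(NROW(wtl$evidence), 0L)
  # depolarised inactivation, faster recovery, shallower slope, reduced
  # density: gain of function wins with the conflict recorded
  arg <- classifyVariant(rbind(
    mk("Ipeak_density_pA_per_pF", "higher", -71.3, -127.5),
    mk("inact_V12_mV", "higher", -61.7, -65.3),
    mk("inact_Vslope_mV", "higher", 6.3, 5.4),
    mk("tau_rec_ms", "lower", 1.95, 5.63)))
  expect_equal(arg$label, "gain_of_function")
  expect_true(arg$conflict)
  # density reduction alone: loss of function
  glu <- classifyVariant(mk("Ipeak_density_pA_per_pF", "higher",
                            -49.8, -127.5))
  expect_equal(glu$label, "loss_of_function")
  expect_false(glu$conflict)
  # enhanced inactivation (hyperpolarised V12, slower recovery): loss
  val <- classifyVariant(rbind(mk("inact_V12_mV", "lower", -71.9, -65.3),
                               mk("tau_rec_ms", "higher", 8.51, 5.63)))
  expect_equal(val$label, "loss_of_function")
  # slower open-state inactivation: gain of function
  ser <- classifyVariant(mk("tau_inact_0mV_ms", "higher", 0.40, 0.30))
  expect_equal(ser$label, "gain_of_function")
  # an isolated activation-slope change matches neither rule set
  act <- classifyVariant(mk("act_Vslope_mV", "higher", 7.2, 6.4))
  expect_equal(act$label, "wild_type_like")
  # a density increase is not a density reduction
  up <- classifyVariant(mk("Ipeak_density_pA_per_pF", "lower",
                           -200, -127.5))
  expect_equal(up$label, "wild_type_like")
})
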