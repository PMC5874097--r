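test_that("Pearson correlation matches its closed form and invariances", {
  x <- c(1, 2, 4, 5, 7, 9, 12)
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  set.seed(3)
  y <- rnorm(7)
  pc <- pearsonCorrelation(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt(5 / (1 - r^2))
  expect_equal(pc$r, r)
  expect_equal(pc$p, 2 * pt(-abs(tt), 5))
  ## invariant under positive affine transforms of either argument
  pc2 <- pearsonCorrelation(3 * x - 2, 0.5 * y + 4)
  expect_equal(pc2$r, pc$r)
  expect_error(pearsonCorrelation(rep(1, 5), y[1:5]), "variance")
})

test_that("signed-rank test matches exact enumeration for small n", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(4:11, 1)
    a <- round(rnorm(n), 1)          # rounding induces ties and zeros
    b <- round(rnorm(n), 1)
    if (all(a == b)) next
    w <- wilcoxonSignedRank(a, b)
    expect_equal(w$p, enumSignedRankP(a, b), tolerance = 1e-12,
                 label = sprintf("rep %d", rep))
  }
  ## agreement with the reference implementation when zero/tie-free
  a <- c(1.31, 0.27, -1.12, 2.04, 0.53, -0.48, 1.95, 0.21)
  b <- c(0.14, 1.80, -0.63, 0.92, -1.21, 0.33, 1.02, -0.77)
  expect_equal(wilcoxonSignedRank(a, b)$p,
               wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
})

test_that("signed-rank edge cases: degenerate pairs and constant shift", {
  w <- wilcoxonSignedRank(1:5, 1:5)
  expect_true(w$degenerate)
  expect_true(is.na(w$p))
  ## a = b + c, n = 15: every difference positive, minimal tail
  a <- rnorm(15); b <- a - 2
  w2 <- wilcoxonSignedRank(a, b)
  expect_equal(w2$p, 2 / 2^15)
  expect_equal(w2$statistic, 15 * 16 / 2)
})

test_that("combined PNA+VTA means average per tumor", {
  rec <- data.frame(
    tumor_id = rep(1:2, each = 3),
    region = rep(c("CNA", "PNA", "VTA"), 2),
    ktrans = c(0.01, 0.1, 0.3, 0.02, 0.2, 0.6),
    ve = c(0.3, 0.1, 0.2, 0.25, 0.15, 0.2),
    vp = c(0.01, 0.02, 0.03, 0.01, 0.03, 0.05),
    mvd = c(1, 5, 15, 2, 8, 20))
  comb <- combinePnaVta(rec)
  expect_equal(comb$ktrans, c(0.2, 0.4))
  expect_equal(comb$mvd, c(10, 14))
  ## identical PNA and VTA tables: combined equals either
  rec2 <- rec
  rec2[rec2$region == "VTA", c("ktrans", "ve", "vp", "mvd")] <-
    rec2[rec2$region == "PNA", c("ktrans", "ve", "vp", "mvd")]
  comb2 <- combinePnaVta(rec2)
  expect_equal(comb2$ktrans, rec2$ktrans[rec2$region == "PNA"])
  ## pooled mode concatenates
  expect_equal(nrow(combinePnaVta(rec, "pooled")), 4L)
  ## missing region excluded with warning
  expect_warning(out <- combinePnaVta(rec[-2, ]), "excluded")
  expect_equal(out$tumor_id, 2)
})

test_that("reference-table correlations reproduce the published pattern", {
  tab <- loadTable1Fixture()
  res <- runFullAnalysis(tab)
  k <- subset(res$correlations, parameter == "ktrans")
  rOf <- function(rg) k$r[k$region_set == rg]
  expect_equal(rOf("PNA"), 0.8124, tolerance = 0.03)
  expect_equal(rOf("VTA"), 0.5743, tolerance = 0.03)
  expect_equal(rOf("PNA+VTA"), 0.8470, tolerance = 0.03)
  expect_equal(rOf("CNA"), 0.0075, tolerance = 0.03)
  ## combined beats either region alone
  expect_gt(rOf("PNA+VTA"), rOf("PNA"))
  expect_gt(rOf("PNA"), rOf("VTA"))
  ## necrosis shows nothing
  expect_gt(k$p[k$region_set == "CNA"], 0.05)
})

test_that("summaries are invariant to tumor-row order", {
  tab <- loadTable1Fixture()
  set.seed(8)
  shuf <- tab[sample(nrow(tab)), ]
  r1 <- runFullAnalysis(tab)$correlations
  r2 <- runFullAnalysis(shuf)$correlations
  expect_equal(r1, r2)
})

test_that("correlation p-values are calibrated under the null link and
           powered under the default link", {
  ## null: slope = 0 severs the Ktrans-MVD association; p uniform
  ps <- vapply(1:200, function(s) {
    co <- simulateCohort(link = mvdLink(slope = 0), seed = 10000 + s)
    pna <- co[co$region == "PNA", ]
    pearsonCorrelation(pna$ktrans, pna$mvd)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  ## power: default link gives positive significant PNA/VTA correlations
  hits <- vapply(1:100, function(s) {
    co <- simulateCohort(seed = 20000 + s)
    all(vapply(c("PNA", "VTA"), function(rg) {
      sub <- co[co$region == rg, ]
      pc <- pearsonCorrelation(sub$ktrans, sub$mvd)
      pc$r > 0 && pc$p < 0.05
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
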