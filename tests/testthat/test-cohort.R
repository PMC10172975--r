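test_that("linregress matches exact lines and rejects degenerate input", {
  x <- 1:10
  f <- linregress(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r, 1)
  expect_equal(f$p_value, 0)
  expect_error(linregress(x, rep(3, 10)), "variance in ys")
  expect_error(linregress(rep(3, 10), x), "variance in xs")
})

test_that("linregress agrees with lm and cor.test", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    f <- linregress(x, y)
    lmfit <- lm(y ~ x)
    ct <- cor.test(x, y)
    expect_equal(f$slope, unname(coef(lmfit)[2]), tolerance = 1e-9)
    expect_equal(f$intercept, unname(coef(lmfit)[1]), tolerance = 1e-9)
    expect_equal(f$r, unname(ct$estimate), tolerance = 1e-9)
    expect_equal(f$p_value, ct$p.value, tolerance = 1e-9)
  }
})

test_that("MFI/DFI pairing takes the closest date under 8 days", {
  dfi <- data.frame(mouse_id = "a", date = as.Date("2026-01-10"), dfi = 0.2)
  mfi <- data.frame(mouse_id = "a",
                    date = as.Date(c("2026-01-05", "2026-01-16")),
                    overall = c(0.1, 0.3))
  p <- pair_mfi_dfi(dfi, mfi)
  expect_equal(nrow(p), 1)
  expect_equal(p$mfi_date, as.Date("2026-01-05"))
  expect_equal(p$gap_days, 5L)

  # a gap of exactly 8 days fails the strict "fewer than 8" rule
  mfi2 <- data.frame(mouse_id = "a", date = as.Date("2026-01-18"),
                     overall = 0.1)
  expect_equal(nrow(pair_mfi_dfi(dfi, mfi2)), 0)
  mfi3 <- data.frame(mouse_id = "a", date = as.Date("2026-01-17"),
                     overall = 0.1)
  expect_equal(nrow(pair_mfi_dfi(dfi, mfi3)), 1)

  # equidistant candidates resolve to the earlier MFI
  mfi4 <- data.frame(mouse_id = "a",
                     date = as.Date(c("2026-01-07", "2026-01-13")),
                     overall = c(0.11, 0.22))
  expect_equal(pair_mfi_dfi(dfi, mfi4)$mfi, 0.11)
})

test_that("pairing output satisfies its own constraints", {
  set.seed(62)
  dfi <- data.frame(mouse_id = sample(letters[1:8], 40, replace = TRUE),
                    date = as.Date("2026-01-01") + sample(0:60, 40, TRUE),
                    dfi = runif(40))
  mfi <- data.frame(mouse_id = sample(letters[1:8], 30, replace = TRUE),
                    date = as.Date("2026-01-01") + sample(0:60, 30, TRUE),
                    overall = runif(30))
  p <- pair_mfi_dfi(dfi, mfi)
  expect_lte(nrow(p), nrow(dfi))
  expect_true(all(p$gap_days < 8))
  expect_true(all(abs(as.integer(p$mfi_date - p$dfi_date)) < 8))
})

test_that("age-residual correlation isolates non-age covariation", {
  # both indexes exact linear functions of age: residuals are constant
  pairs <- data.frame(mouse_id = letters[1:10], age_days = seq(200, 800, length.out = 10))
  pairs$mfi <- 0.001 * pairs$age_days
  pairs$dfi <- 0.002 * pairs$age_days - 0.1
  expect_error(age_residual_correlation(pairs), "degenerate")

  # a shared latent beyond age keeps residuals correlated
  set.seed(63)
  n <- 80
  age <- runif(n, 200, 900)
  latent <- rnorm(n, 0, 0.1)
  pr <- data.frame(
    mouse_id = as.character(1:n), age_days = age,
    mfi = 0.0004 * age + latent + rnorm(n, 0, 0.03),
    dfi = 0.0007 * age + latent + rnorm(n, 0, 0.03))
  ra <- age_residual_correlation(pr)
  expect_gt(ra$residual$r, 0.5)
  expect_lt(ra$residual$p_value, 0.01)
  # residuals are centred by construction
  expect_equal(mean(ra$residual_mfi), 0, tolerance = 1e-9)

  # permuting one residual vector destroys the correlation
  perm_r <- replicate(100, {
    linregress(ra$residual_mfi, sample(ra$residual_dfi))$r
  })
  expect_lt(abs(mean(perm_r)), 0.1)
})

test_that("component correlation matrix filters sparse MFI items", {
  set.seed(64)
  n <- 40
  base <- rnorm(n)
  tab <- data.frame(c1 = base, c2 = base, c3 = rnorm(n))
  tab$item_sparse <- c(rep(1, 5), rep(0, n - 5))      # 5 non-zero -> drop
  tab$item_kept <- c(rep(0.5, 6), rep(0, n - 6))      # 6 non-zero -> keep
  cm <- component_correlation_matrix(tab,
                                     mfi_items = c("item_sparse", "item_kept"))
  expect_false("item_sparse" %in% colnames(cm))
  expect_true("item_kept" %in% colnames(cm))
  expect_equal(attr(cm, "excluded"), "item_sparse")
  expect_equal(cm["c1", "c2"], 1, tolerance = 1e-12)
  expect_equal(cm, t(cm), ignore_attr = TRUE)
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  # off-diagonals agree with direct per-pair regression
  expect_equal(cm["c1", "c3"], linregress(tab$c1, tab$c3)$r,
               tolerance = 1e-9)
})

test_that("WPGMA reproduces a hand-worked 4-leaf merge sequence", {
  # distances: AB=0.2 AC=0.5 AD=0.9 BC=0.4 BD=0.8 CD=0.7
  # step 1: merge A,B at 0.2;  d(AB,C) = (0.5+0.4)/2 = 0.45,
  #         d(AB,D) = (0.9+0.8)/2 = 0.85
  # step 2: merge AB,C at 0.45;  d(ABC,D) = (0.85+0.7)/2 = 0.775
  # step 3: merge ABC,D at 0.775
  d <- matrix(c(0, .2, .5, .9,
                .2, 0, .4, .8,
                .5, .4, 0, .7,
                .9, .8, .7, 0), 4, 4)
  R <- 1 - d
  diag(R) <- 1
  colnames(R) <- rownames(R) <- c("A", "B", "C", "D")
  hc <- wpgma_cluster(R)
  expect_equal(hc$height, c(0.2, 0.45, 0.775))
  cph <- as.matrix(cophenetic(hc))
  expect_equal(cph["A", "B"], 0.2)
  expect_equal(cph["A", "C"], 0.45)
  expect_equal(cph["B", "C"], 0.45)
  expect_equal(unname(cph[c("A", "B", "C"), "D"]), rep(0.775, 3))
})

test_that("WPGMA agrees with hclust's weighted linkage", {
  set.seed(65)
  X <- matrix(rnorm(30 * 6), 30, 6)
  colnames(X) <- paste0("v", 1:6)
  R <- cor(X)
  hc <- wpgma_cluster(R)
  ref <- hclust(as.dist(1 - R), method = "mcquitty")
  expect_equal(sort(hc$height), sort(ref$height), tolerance = 1e-12)
  expect_equal(as.matrix(cophenetic(hc))[colnames(R), colnames(R)],
               as.matrix(cophenetic(ref))[colnames(R), colnames(R)],
               tolerance = 1e-12)
})

test_that("WPGMA edge cases: ties, identical columns, bad input", {
  # two identical columns merge first at height 0
  set.seed(66)
  base <- rnorm(20)
  R <- cor(cbind(a = base, b = base, c = rnorm(20)))
  hc <- wpgma_cluster(R)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  # heights are non-decreasing along the merge sequence
  expect_true(all(diff(hc$height) >= -1e-12))

  # all off-diagonal correlations equal: every merge at the same height
  R2 <- matrix(0.3, 4, 4); diag(R2) <- 1
  colnames(R2) <- rownames(R2) <- letters[1:4]
  hc2 <- wpgma_cluster(R2)
  expect_equal(hc2$height, rep(0.7, 3), tolerance = 1e-12)
  expect_equal(sort(hc2$merge[1, ]), c(-2, -1))  # lowest-index tie-break

  R3 <- R2; R3[1, 2] <- 0.9
  expect_error(wpgma_cluster(R3), "symmetric")

  # newick export round-trips through ape
  nw <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc2, nw)
  tree <- ape::read.tree(nw)
  expect_setequal(tree$tip.label, letters[1:4])
})
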