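test_that("matched resolution reproduces the length-matching arithmetic", {
  beta <- matched_resolution(band_definition("beta", 14, 30))
  expect_identical(beta$EBL, 17)
  expect_identical(beta$MBL, 44L)
  expect_equal(beta$FR, 16 / 43)
  expect_equal(beta$FR_display, 0.37)
  expect_length(beta$points, 44)
  expect_equal(range(beta$points), c(14, 30))
  expect_equal(beta$emg_points, seq(20, 149, by = 3))

  mu <- matched_resolution(band_definition("mu", 8, 13))
  expect_equal(mu$FR, 5 / 43)

  expect_error(matched_resolution(band_definition("x", 10, 10.5)),
               "degenerate")
})

test_that("PSD re-gridding is linear, length-preserving and support-checked", {
  f <- 0:200
  # affine spectra are reproduced exactly by linear interpolation
  psd <- 3 + 0.5 * f
  g <- matched_resolution(band_definition("beta", 14, 30))
  v <- regrid_psd(f, psd, g)
  expect_equal(v, 3 + 0.5 * g$points)
  expect_length(v, 44)
  # identity when the grid equals the native axis
  expect_equal(regrid_psd(f, psd, f), psd)
  expect_error(regrid_psd(20:50, psd[21:51], g), "outside")
})

test_that("min-max normalization maps to [0, 1] and guards constants", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(x), x)  # idempotent on full-range input
  expect_warning(v <- minmax_normalize(c(5, 5, 5)), "constant")
  expect_equal(v, c(0, 0, 0))
  expect_error(minmax_normalize(numeric(0)), "two values")
})

test_that("Spearman connectivity matches the rank-then-Pearson oracle", {
  expect_equal(pbc_spearman(1:10, 1:10)$rho, 1)
  expect_equal(pbc_spearman(1:10, 10:1)$rho, -1)
  expect_equal(pbc_spearman(1:5, c(3, 1, 2, 5, 4))$rho, 0.6)

  set.seed(30)
  for (i in 1:25) {
    x <- rnorm(44); y <- rnorm(44)
    expect_equal(pbc_spearman(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  x <- runif(44); y <- runif(44)
  expect_equal(pbc_spearman(exp(x), y)$rho, pbc_spearman(x, y)$rho)
  expect_equal(pbc_spearman(x, y^3)$rho, pbc_spearman(x, y)$rho)

  flagged <- pbc_spearman(rep(1, 44), rnorm(44))
  expect_identical(flagged$flag, "constant")
  expect_true(is.na(flagged$rho))
  expect_error(pbc_spearman(1:5, 1:6), "equal length")
})

test_that("one-sided p-values match the t approximation of cor.test", {
  set.seed(31)
  x <- rnorm(44); y <- x + rnorm(44)
  sp <- pbc_spearman(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   alternative = "greater", exact = FALSE))
  expect_equal(sp$p, ref$p.value, tolerance = 1e-10)
})

test_that("normality screening recommends rank correlation when warranted", {
  set.seed(32)
  heavy <- rexp(500)
  rep1 <- normality_check(heavy)
  expect_lt(rep1$report$p[1], 0.01)
  expect_identical(rep1$recommendation, "spearman")

  const <- normality_check(rep(2, 50))
  expect_identical(const$report$flag[1], "degenerate")

  expect_error(normality_check(rnorm(10)), "20 samples")
})

test_that("aggregation modes average over the documented strata", {
  one <- data.frame(subject = "S01", trial = 1L, surface = "Suede",
                    eeg_channel = "C3", muscle = "AD", band = "all",
                    rho = 0.4, p = 0.01, flag = NA_character_)
  expect_equal(pbc_aggregate(one, "per_channel")$rho, 0.4)

  five <- do.call(rbind, lapply(1:5, function(i) {
    d <- one; d$muscle <- c("AD", "B", "FD", "CED", "FDI")[i]
    d$rho <- c(0.2, 0.4, 0.6, 0.8, 1.0)[i]; d
  }))
  expect_equal(pbc_aggregate(five, "per_channel")$rho, 0.6)

  grid <- expand.grid(eeg_channel = c("C3", "Cz", "C4"),
                      muscle = c("AD", "B", "FD", "CED", "FDI"),
                      surface = c("Sandpaper", "Suede"),
                      stringsAsFactors = FALSE)
  grid$subject <- "S01"; grid$trial <- 1L; grid$band <- "all"
  grid$rho <- runif(nrow(grid)); grid$p <- 0.5
  grid$flag <- NA_character_
  pp <- pbc_aggregate(grid, "per_pair")
  expect_identical(nrow(pp[pp$surface == "Suede", ]), 15L)
})

test_that("mean connectivity rises with the injected coupling gain", {
  mean_rho <- sapply(c(0, 0.5, 1), function(k) {
    set.seed(33)
    sp <- session_spec(coupling_gain_per_surface =
                         c(Sandpaper = k, Suede = k, Silk = k))
    trs <- lapply(1:25, function(i)
      preprocess_trial(generate_trial(sp, "Suede", trial_id = i)))
    mean(pbc(mk_epochs(trs), bands = cmc_bands()["all"])$rho)
  })
  expect_true(all(diff(mean_rho) > 0))
})
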