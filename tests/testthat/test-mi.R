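test_that("bin-count rule follows the printed width formula", {
  # construct a sample with range exactly 7, SD exactly 1, n = 1000:
  # bins = 7 / (3.5 * 1 * 1000^(-1/3)) = 20
  set.seed(40)
  w <- rnorm(998)
  f <- function(s) sd(c(-3.5, 3.5, w * s)) - 1
  s <- uniroot(f, c(1e-6, 1), tol = 1e-12)$root
  x <- c(-3.5, 3.5, w * s)
  expect_equal(max(x) - min(x), 7)
  expect_equal(sd(x), 1, tolerance = 1e-9)
  expect_identical(optimal_bins(x), 20L)

  # scale invariance: range and SD scale together
  expect_identical(optimal_bins(13 * x), optimal_bins(x))
  # degenerate window
  expect_identical(optimal_bins(rep(2, 100)), 1L)
  expect_error(optimal_bins(numeric(0)), "empty")

  # agrees with the direct formula on random windows
  for (i in 1:20) {
    v <- rnorm(50 + i, sd = runif(1, 0.5, 3))
    expect_identical(optimal_bins(v),
                     as.integer(min(256, max(1, round((max(v) - min(v)) /
                       (3.5 * sd(v) * length(v)^(-1 / 3)))))))
  }
})

test_that("histogram entropy matches hand-computed distributions", {
  # 4 equal-count bins -> 2 bits
  x4 <- rep(c(0.1, 0.35, 0.6, 0.85), 25)
  expect_equal(entropy_hist(x4, 4), 2)
  # single occupied bin -> 0 bits
  expect_equal(entropy_hist(rep(1, 50), 1), 0)
  # counts (2, 1, 1) over 3 bins, n = 4 -> 1.5 bits
  expect_equal(entropy_hist(c(0.1, 0.15, 0.5, 0.9), 3), 1.5)
  # bounded by log2(bins)
  set.seed(41)
  x <- rnorm(500)
  expect_lte(entropy_hist(x, 8), 3)
  expect_error(entropy_hist(numeric(0)), "empty")
})

test_that("joint entropy respects identity, independence and subadditivity", {
  set.seed(42)
  x <- rnorm(400)
  expect_equal(joint_entropy_hist(x, x, 6, 6), entropy_hist(x, 6),
               tolerance = 1e-12)
  # exact quarter counts over 2x2 bins -> 2 bits
  xs <- rep(c(0, 0, 1, 1), 25); ys <- rep(c(0, 1, 0, 1), 25)
  expect_equal(joint_entropy_hist(xs, ys, 2, 2), 2)
  y <- rnorm(400)
  expect_lte(joint_entropy_hist(x, y, 5, 7),
             entropy_hist(x, 5) + entropy_hist(y, 7) + 1e-12)
  expect_error(joint_entropy_hist(x, y[1:10], 4, 4), "equal length")
})

test_that("mutual information is symmetric, non-negative and self-consistent", {
  set.seed(43)
  x <- rnorm(1000)
  expect_equal(mutual_information(x, x), entropy_hist(x),
               tolerance = 1e-12)
  for (i in 1:10) {
    a <- rnorm(300); b <- a + rnorm(300, sd = 2)
    expect_equal(mutual_information(a, b), mutual_information(b, a),
                 tolerance = 1e-12)
    expect_gte(mutual_information(a, b), 0)
    expect_lte(mutual_information(a, b, 4, 4),
               min(entropy_hist(a, 4), entropy_hist(b, 4)) + 1e-12)
  }
  # an affine map preserves bin memberships exactly, so the joint
  # histogram stays diagonal and MI equals the marginal entropy
  u <- runif(16)
  expect_equal(mutual_information(u, 2 * u + 1, 4, 4),
               entropy_hist(u, 4), tolerance = 1e-12)
})

test_that("entropies match the exhaustive counting oracle on small inputs", {
  set.seed(44)
  for (rep in 1:60) {
    n <- sample(2:16, 1)
    bx <- sample(1:4, 1); by <- sample(1:4, 1)
    x <- runif(n); y <- runif(n)
    expect_equal(entropy_hist(x, bx),
                 oracle_entropy(oracle_bins(x, bx), bx), tolerance = 1e-12)
    expect_equal(joint_entropy_hist(x, y, bx, by),
                 oracle_entropy((oracle_bins(x, bx) - 1L) * by +
                                  oracle_bins(y, by), bx * by),
                 tolerance = 1e-12)
    expect_equal(mutual_information(x, y, bx, by), oracle_mi(x, y, bx, by),
                 tolerance = 1e-12)
  }
})

test_that("independent noise cannot raise the average information", {
  set.seed(45)
  base <- added <- numeric(60)
  for (r in 1:60) {
    x <- rnorm(500); y <- x + rnorm(500, sd = 0.5)
    base[r] <- mutual_information(x, y, 8, 8)
    added[r] <- mutual_information(x, y + rnorm(500, sd = 2), 8, 8)
  }
  expect_lt(mean(added), mean(base))
})

test_that("MI time course uses adjacent windows over the full trial", {
  set.seed(46)
  eeg <- matrix(rnorm(2 * 40000), 2, dimnames = list(c("C3", "Cz"), NULL))
  emg <- matrix(rnorm(1 * 40000), 1, dimnames = list("AD", NULL))
  tr <- mk_trial(eeg, emg)
  mi <- mi_timecourse(tr, "C3", "AD")
  expect_length(mi$mi, 100)  # 10 s / 100 ms
  expect_true(all(mi$mi >= 0))
  expect_equal(mi$times[1], 0.05)

  mismatch <- mk_trial(eeg, emg, fs_eeg = 500)
  expect_error(mi_timecourse(mismatch, "C3", "AD"), "sampling rate")
  tiny <- mk_trial(eeg[, 1:100, drop = FALSE], emg[, 1:100, drop = FALSE])
  expect_error(mi_timecourse(tiny, "C3", "AD"), "shorter")
})

test_that("session MI table averages trials then channels per muscle", {
  set.seed(47)
  spec <- tiny_spec(seed = 48)
  ep <- preprocess_session(generate_session(spec))
  tab <- mi_session(ep, muscles = c("AD", "B"))
  expect_s3_class(tab, "cmc_mi")
  expect_setequal(unique(tab$muscle), c("AD", "B"))
  # 4 s trials -> 40 windows per series
  expect_identical(sum(tab$surface == "Suede" & tab$muscle == "AD"), 40L)
  expect_true(all(tab$mi >= 0))
})
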