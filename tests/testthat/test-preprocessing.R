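make_row_ds <- function(wn, ...) {
  rows <- rbind(...)
  spectral_dataset(wn, rows, sprintf("s%d", seq_len(nrow(rows))))
}

test_that("Savitzky-Golay leaves polynomial rows invariant everywhere", {
  wn <- seq(900, 1800, by = 2)
  u <- (wn - 1350) / 450
  ds <- make_row_ds(wn, u^2 - 0.3 * u + 1, rep(0.7, length(wn)))
  sm <- savitzky_golay(ds, window = 7, polyorder = 2)
  expect_lt(max(abs(sm$absorbance - ds$absorbance)), 1e-9)
  expect_error(savitzky_golay(ds, window = 6), "odd")
  expect_error(savitzky_golay(ds, window = 3, polyorder = 3), "exceed")
})

test_that("Savitzky-Golay equals an explicit least-squares fit per window", {
  set.seed(42)
  wn <- seq(1000, 1100, by = 2)
  y <- rnorm(length(wn))
  ds <- make_row_ds(wn, y)
  sm <- savitzky_golay(ds, window = 7, polyorder = 2)[["absorbance"]][1, ]
  half <- 3
  for (i in seq(half + 1, length(wn) - half)) {
    idx <- (i - half):(i + half)
    fit <- lm(y[idx] ~ poly(idx, 2, raw = TRUE))
    expect_equal(sm[i], unname(predict(fit)[half + 1]), tolerance = 1e-8)
  }
})

test_that("AWLS removes a pure polynomial baseline to zero", {
  wn <- seq(900, 1800, by = 5)
  u <- (wn - 900) / 900
  ds <- make_row_ds(wn, 2 + 0.5 * u - 0.8 * u^2)
  out <- awls_baseline(ds, polyorder = 2)
  expect_lt(max(abs(out$absorbance)), 1e-6)
})

test_that("AWLS suppresses a linear baseline under a tall band", {
  wn <- seq(900, 1800, by = 2)
  band <- 0.8 * exp(-(wn - 1400)^2 / (2 * 15^2))
  baseline <- 0.2 + 0.0004 * (wn - 900)
  ds <- make_row_ds(wn, baseline + band)
  out <- awls_baseline(ds, polyorder = 1)
  off <- abs(wn - 1400) > 75  # beyond 5 sd of the band
  expect_lt(mean(abs(out$absorbance[1, off])), 0.05 * 0.8)
})

test_that("a single AWLS iteration is an unweighted polynomial subtraction", {
  set.seed(7)
  wn <- seq(1000, 1200, by = 4)
  y <- rnorm(length(wn), sd = 0.3) + 1
  ds <- make_row_ds(wn, y)
  one <- awls_baseline(ds, polyorder = 2, max_iter = 1)
  u <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  fit <- lm(y ~ u + I(u^2))
  expect_equal(one$absorbance[1, ], unname(residuals(fit)),
               tolerance = 1e-8)
})

test_that("AWLS weighted SSE never increases within an iteration", {
  set.seed(11)
  wn <- seq(900, 1800, by = 3)
  rows <- replicate(5, 0.3 + 0.0002 * wn +
                      0.5 * exp(-(wn - runif(1, 1100, 1700))^2 / 800) +
                      rnorm(length(wn), sd = 0.02))
  ds <- spectral_dataset(wn, t(rows), sprintf("s%d", 1:5))
  out <- awls_baseline(ds, diagnostics = TRUE)
  drops <- unlist(lapply(attr(out, "awls"), `[[`, "sse_drop"))
  expect_true(all(drops >= -1e-10))
})

test_that("Amide I normalization divides by the window maximum", {
  wn <- seq(1600, 1700, by = 2)
  y <- exp(-(wn - 1650)^2 / (2 * 8^2)) * 2   # peak 2.0 at 1650
  ds <- make_row_ds(wn, y)
  out <- normalize_amide_i(ds, 1650, 10)
  expect_equal(out$absorbance[1, wn == 1650], 1.0)
  expect_equal(out$absorbance, ds$absorbance / 2)
  # idempotent
  expect_equal(normalize_amide_i(out, 1650, 10), out)
  # shifted peak at 1648: the window max rules, not the literal 1650 point
  y2 <- exp(-(wn - 1648)^2 / (2 * 8^2)) * 1.7
  ds2 <- make_row_ds(wn, y2)
  out2 <- normalize_amide_i(ds2, 1650, 10)
  expect_equal(out2$absorbance[1, wn == 1648], 1.0)
  expect_equal(max(out2$absorbance[1, abs(wn - 1650) <= 10]), 1.0)
  # degenerate spectrum errors with the sample named
  ds3 <- make_row_ds(wn, -y)
  expect_error(normalize_amide_i(ds3, 1650, 10), "s1")
})

test_that("after normalization every row's window maximum is exactly 1", {
  gen <- generate_spectra(small_generator_config(), seed = 5)
  out <- preprocess(average_replicates(gen$dataset))
  win <- abs(out$wavenumbers - 1650) <= 10
  expect_identical(unname(apply(out$absorbance[, win], 1, max)),
                   rep(1, nrow(out$absorbance)))
})

test_that("the full chain reproduces frozen golden values", {
  gen <- generate_spectra(small_generator_config(n_samples = 3), seed = 123)
  out <- preprocess(average_replicates(gen$dataset))
  expect_identical(dim(out$absorbance), c(3L, 91L))
  probe <- out$absorbance[cbind(c(1, 1, 2, 3, 3),
                                c(1, 45, 60, 76, 91))]
  golden <- c(0.124305800724791, 0.0283213003110173, 0.0790259716939013,
              0.987411407546953, 0.0136539471317146)
  expect_equal(probe, golden, tolerance = 1e-12)
})
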