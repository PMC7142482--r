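test_that("exponential apodization applies the documented weights", {
  fid <- Fid(rep(1 + 0i, 64), dwell = 1)
  out <- apodizeExponential(fid, lb = 1)
  expect_equal(Mod(out@signal[1]), 1)                 # k = 0 untouched
  expect_equal(Mod(out@signal[2]), exp(-pi), tolerance = 1e-12)
  ident <- apodizeExponential(fid, lb = 0)
  expect_identical(ident@signal, fid@signal)
  expect_error(apodizeExponential(fid, lb = -1), "lb")
})

test_that("the Fourier transform maps a decaying exponential to one peak", {
  n <- 1024L; dwell <- 1e-3
  t <- (seq_len(n) - 1) * dwell
  f0 <- 120                                          # Hz
  fid <- Fid(exp(2i * pi * f0 * t - t / 0.05), dwell)
  sp <- fourierSpectrum(fid, frequencyMHz = 600, refPpm = 0)
  pk <- ppm(sp)[which.max(intensity(sp))]
  expect_equal(pk, f0 / 600, tolerance = 2 / (n * dwell) / 600)

  zero <- fourierSpectrum(Fid(rep(0 + 0i, 64), 1e-3))
  expect_true(all(intensity(zero) == 0))
})

test_that("the magnitude spectrum conserves signal energy (Parseval)", {
  set.seed(1)
  sig <- complex(real = rnorm(256), imaginary = rnorm(256))
  fid <- Fid(sig, 1e-3)
  sp <- fourierSpectrum(fid, mode = "modulus")
  expect_equal(sum(intensity(sp)^2) / 256, sum(Mod(sig)^2),
               tolerance = 1e-9)
})

test_that("normalizations are scale invariant and idempotent", {
  grid <- smallGrid(1024)
  dss <- metaboliteDef("dss", list(peakSpec(0, 5, 0.01)))
  lact <- metaboliteDef("lactate", list(peakSpec(1.33, 2, 0.02)))
  y <- 3 * intensity(makeReferenceSpectrum(dss, grid)) +
       2 * intensity(makeReferenceSpectrum(lact, grid))
  s <- Spectrum(grid, y)

  r1 <- normalizeReferencePeak(s)
  expect_equal(nmrflux:::integrateWindow(ppm(r1), intensity(r1),
                                         c(-0.05, 0.05)), 1, tolerance = 1e-9)
  r7 <- normalizeReferencePeak(Spectrum(grid, 7 * y))
  expect_equal(intensity(r1), intensity(r7), tolerance = 1e-12)
  expect_equal(intensity(normalizeReferencePeak(r1)), intensity(r1),
               tolerance = 1e-12)

  t1 <- normalizeTotalArea(s)
  expect_equal(nmrflux:::integrateWindow(ppm(t1), intensity(t1),
                                         c(-0.5, 10)), 1, tolerance = 1e-9)
  t7 <- normalizeTotalArea(Spectrum(grid, 7 * y))
  expect_equal(intensity(t1), intensity(t7), tolerance = 1e-12)

  expect_error(normalizeReferencePeak(Spectrum(grid, rep(0, 1024))),
               "nonpositive")
  expect_error(normalizeTotalArea(Spectrum(grid, -y)), "nonpositive")
})

test_that("region trimming and water exclusion retain the right points", {
  grid <- smallGrid(1024)
  s <- Spectrum(grid, seq_along(grid))
  full <- trimRegion(s, range(grid))
  expect_equal(ppm(full), ppm(s))
  tr <- trimRegion(s, c(0, 5))
  expect_true(all(ppm(tr) >= 0 & ppm(tr) <= 5))
  nw <- excludeRegion(s, c(4.5, 5.0))
  expect_false(any(ppm(nw) > 4.5 & ppm(nw) < 5.0))
  expect_true(length(ppm(nw)) < length(ppm(s)))
  expect_error(trimRegion(s, c(100, 101)), "fewer than 2")
})

test_that("every transform appends an auditable history record", {
  grid <- smallGrid(512)
  s <- Spectrum(grid, abs(rnorm(512)) + 1)
  s <- phaseCorrect(s)
  s <- normalizeTotalArea(s)
  s <- trimRegion(s, c(0, 8))
  s <- shiftSpectrum(s, 3L)
  h <- processingHistory(s)
  expect_length(h, 4L)
  expect_match(h[1], "phaseCorrect")
  expect_match(h[2], "normalizeTotalArea\\(region=\\[-0.5,10\\]\\)")
  expect_match(h[3], "trimRegion")
  expect_match(h[4], "shiftSpectrum\\(lag=3\\)")
})

test_that("FFT alignment recovers injected integer shifts exactly", {
  grid <- smallGrid(1024)
  defs <- smallDefs(3)
  ref <- makeMixture(defs, c(1, 2, 3), grid, seed = 2)$spectrum

  self <- alignFFT(ref, ref)
  expect_equal(self$lag, 0L)

  for (k in c(-30L, -7L, 1L, 13L, 30L)) {
    shifted <- shiftSpectrum(ref, k)
    al <- alignFFT(shifted, ref)
    expect_equal(al$lag, -k)
    expect_equal(al$lag,
                 exhaustiveLagOracle(intensity(shifted), intensity(ref)))
    core <- (abs(k) + 1):(1024 - abs(k))
    expect_equal(intensity(al$spectrum)[core], intensity(ref)[core],
                 tolerance = 1e-12)
  }

  flat <- Spectrum(grid, rep(1, 1024))
  expect_equal(alignFFT(flat, flat)$lag, 0L)
  expect_error(alignFFT(ref, Spectrum(grid[-1], rep(1, 1023))), "grid")
})

test_that("FFT alignment matches the exhaustive oracle on random spectra", {
  grid <- smallGrid(512)
  set.seed(101)
  for (rep in 1:20) {
    y <- abs(rnorm(512)) + dnorm(seq(-3, 3, length.out = 512)) * 20
    ref <- Spectrum(grid, y)
    k <- sample(-40:40, 1)
    shifted <- shiftSpectrum(ref, k)
    al <- alignFFT(shifted, ref)
    expect_equal(al$lag,
                 exhaustiveLagOracle(intensity(shifted), intensity(ref)))
  }
})

test_that("interval co-shifting corrects only inside its intervals", {
  grid <- smallGrid(2048)
  defs <- smallDefs(2)                      # lactate 1.33/4.11, alanine
  base <- makeMixture(defs, c(2, 1), grid, seed = 4)$spectrum
  spectra <- list(base, base, base)

  # identical spectra: nothing moves
  out <- alignIcoshift(spectra, list(c(1.0, 1.7)))
  expect_true(all(attr(out, "lags") == 0L))
  expect_equal(intensity(out[[2]]), intensity(base))

  # jitter one spectrum's lactate region by +3 bins inside the interval
  sel <- which(ppm(base) >= 1.0 & ppm(base) <= 1.7)
  jit <- base
  jit@intensity[sel] <- nmrflux:::shiftVector(intensity(base)[sel], 3L)
  out2 <- alignIcoshift(list(base, jit, base), list(c(1.0, 1.7)),
                        target = "median")
  expect_equal(attr(out2, "lags")[2, 1], -3L)
  expect_equal(attr(out2, "lags")[c(1, 3), 1], c(0L, 0L))
  outside <- setdiff(seq_along(grid), sel)
  expect_equal(intensity(out2[[2]])[outside], intensity(jit)[outside])

  # no intervals: outputs equal inputs
  none <- alignIcoshift(spectra, list())
  expect_equal(intensity(none[[1]]), intensity(base))

  expect_error(alignIcoshift(spectra, list(c(1, 2), c(1.5, 3))),
               "overlap")
})
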