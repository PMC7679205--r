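# independently coded brute-force reference for the 11 measures
oracle_measures <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  d <- v - m
  m2 <- sum(d^2) / n
  srt <- sort(v)
  qt <- function(p) {  # linear-interpolation (type 7) quantile
    h <- (n - 1) * p
    lo <- floor(h)
    srt[lo + 1] + (h - lo) * (srt[min(lo + 2, n)] - srt[lo + 1])
  }
  zc <- 0
  for (i in 2:n) if ((v[i] != 0) != (v[i - 1] != 0)) zc <- zc + 1
  mc <- 0
  prev <- 0
  for (i in 1:n) {
    s <- sign(v[i] - m)
    if (s != 0) {
      if (prev != 0 && s != prev) mc <- mc + 1
      prev <- s
    }
  }
  c(mean = m,
    median = if (n %% 2 == 0) (srt[n / 2] + srt[n / 2 + 1]) / 2 else
      srt[(n + 1) / 2],
    sd = sqrt(m2),
    max = srt[n], min = srt[1],
    zero_crossings = zc, mean_crossings = mc,
    iqr = qt(0.75) - qt(0.25),
    skewness = if (m2 > 0) (sum(d^3) / n) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) (sum(d^4) / n) / m2^2 - 3 else 0,
    energy = sum(v^2))
}

test_that("statistical measures follow the stated conventions", {
  expect_equal(unname(stat_measures(rep(0, 24))), rep(0, 11))
  v <- c(1, 2, 3, 4, rep(0, 20))
  s <- stat_measures(v)
  expect_equal(unname(s["max"]), 4)
  expect_equal(unname(s["energy"]), 30)
  expect_equal(unname(s["zero_crossings"]), 1)
  expect_error(stat_measures(1:10), "shape error")
})

test_that("all 11 measures match the brute-force oracle on random series", {
  set.seed(77)
  for (i in 1:1000) {
    v <- switch(1 + i %% 4,
                rpois(24, 5),
                round(rlnorm(24, 2, 1)),
                { x <- rpois(24, 2); x[sample(24, 12)] <- 0; x },
                rep(rpois(1, 3), 24))
    v <- as.numeric(v)
    expect_equal(unname(stat_measures(v)), unname(oracle_measures(v)),
                 tolerance = 1e-9)
  }
})

test_that("hourly series count ON events into the 50-stream layout", {
  M <- build_hourly_series(empty_day(), .schema)
  expect_equal(dim(M), c(50L, 24L))
  expect_true(all(M == 0))
  expect_equal(rownames(M)[1], "overall")

  d <- mk_day(rep(2.5, 10) + (0:9) / 1000, rep("bed", 10),
              activity = "Sleep")
  M <- build_hourly_series(d, .schema)
  expect_equal(unname(M["loc:bed", 3]), 10)
  expect_equal(unname(M["act:Sleep", 3]), 10)
  expect_equal(sum(M), 30)  # overall + location + activity each count 10

  # unlabeled ON events are a labeling error
  d2 <- mk_day(2.5, "bed", activity = NA)
  expect_error(build_hourly_series(d2, .schema), "labeling error")
})

test_that("overall series equals the sum of location series (conservation)", {
  for (s in 1:3) {
    d <- simulate_day(routine_profile(), seed = 40 + s)
    M <- build_hourly_series(d, .schema)
    expect_equal(M["overall", ], colSums(M[2:37, ]))
    expect_equal(sum(M["overall", ]), sum(d$events$state == "ON"))
  }
})

test_that("regularity is 1 for identical days, 0 for disjoint ones", {
  d1 <- mk_day(0:23 + 0.5, rep("bed", 24), activity = "Sleep")
  expect_equal(regularity(list(d1, d1), "location", .schema), 1.0)
  expect_equal(regularity(list(d1, d1), "activity", .schema), 1.0)
  # disjoint single locations in every hour -> maximal difference
  d2 <- mk_day(0:23 + 0.5, rep("kitchen", 24), activity = "Cook")
  expect_equal(regularity(list(d1, d2), "location", .schema), 0.0)
  expect_equal(regularity(list(d1, d2), "activity", .schema), 0.0)
  expect_error(regularity(list(d1), "location", .schema),
               "insufficient")
})

test_that("regularity matches exhaustive pair enumeration on a toy cohort", {
  # 3 days, two locations, hand-enumerable distributions
  dA <- mk_day(c(2.1, 2.2, 8.5), c("bed", "bed", "kitchen"),
               activity = c("Sleep", "Sleep", "Cook"))
  dB <- mk_day(c(2.3, 8.2, 8.9), c("bed", "kitchen", "kitchen"),
               activity = c("Sleep", "Cook", "Cook"))
  dC <- mk_day(c(2.4, 2.6), c("kitchen", "bed"),
               activity = c("Cook", "Sleep"))
  # hour 2 dists: A=(1,0), B=(1,0), C=(.5,.5); hour 8: A=(0,1), B=(0,1),
  # C=empty. TV(A,B)=0+0; TV(A,C)=.5+1; TV(B,C)=.5+1; all other hours
  # empty-empty = 0. mean diff = (0 + 1.5 + 1.5) / (3 pairs * 24 h)
  expected <- 1 - 3 / (3 * 24)
  expect_equal(regularity(list(dA, dB, dC), "location", .schema),
               expected, tolerance = 1e-12)
})

test_that("circadian strength isolates the 24-hour spectral line", {
  t <- 0:(7 * 24 - 1)
  pure <- cos(2 * pi * t / 24)
  expect_equal(circadian_strength(pure), 1.0, tolerance = 1e-9)
  expect_equal(circadian_strength(rep(3, 96)), 0)
  # invariant to adding a constant
  expect_equal(circadian_strength(pure + 100),
               circadian_strength(pure), tolerance = 1e-9)

  # noisy cosine: agrees with a directly coded DFT oracle and beats
  # noise-only strength
  set.seed(55)
  noise <- rnorm(length(t))
  x <- pure + noise  # SNR 1 on the amplitude scale
  W <- 7
  dft_oracle <- function(x) {
    N <- length(x)
    xc <- x - mean(x)
    P <- vapply(1:(N %/% 2), function(k)
      Mod(sum(xc * exp(-2i * pi * k * (0:(N - 1)) / N)))^2, 0)
    P[W] / sum(P)
  }
  expect_equal(circadian_strength(x), dft_oracle(x), tolerance = 1e-9)
  expect_gt(circadian_strength(x), circadian_strength(noise))
})

test_that("marker vectors have the fixed 550 + 3 layout", {
  d <- simulate_day(routine_profile(), seed = 12)
  ctx <- lapply(1:3, function(i)
    simulate_day(routine_profile(), seed = 12 + i))
  mv <- extract_markers(d, c(list(d), ctx), .schema)
  expect_length(mv$markers, 553L)
  expect_equal(names(mv$markers)[1:11],
               paste0("overall.", measure_names()))
  expect_equal(names(mv$markers)[551:553],
               c("regularity_location", "regularity_activity",
                 "circadian_strength"))
  expect_true(!anyNA(mv$markers))
  expect_true(mv$markers["regularity_location"] >= 0 &&
                mv$markers["regularity_location"] <= 1)
  expect_true(mv$markers["circadian_strength"] >= 0 &&
                mv$markers["circadian_strength"] <= 1)

  # empty day with empty context: zeros, neutral extras
  mv0 <- extract_markers(empty_day(), list(), .schema)
  expect_true(all(mv0$markers[1:550] == 0))
  expect_equal(unname(mv0$markers["circadian_strength"]), 0)
})

test_that("marker extraction is invariant to within-day event order", {
  d <- simulate_day(routine_profile(), seed = 88)
  set.seed(1)
  shuf <- d
  shuf$events <- d$events[sample(nrow(d$events)), ]
  mv1 <- extract_markers(d, list(d, d), .schema)
  mv2 <- extract_markers(shuf, list(shuf, shuf), .schema)
  expect_equal(mv1$markers, mv2$markers)
})
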