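test_that("population simulation is seed-deterministic and respects its extent", {
  ext <- c(0, 1000, 0, 500)
  cl <- data.frame(x = 300, y = 250, radius = 25, mu = 50)
  a <- simulate_population(ext, background_intensity = 10, clusters = cl,
                           seed = 123)
  b <- simulate_population(ext, background_intensity = 10, clusters = cl,
                           seed = 123)
  expect_identical(a$points, b$points)
  expect_true(all(a$points$x >= ext[1] & a$points$x <= ext[2]))
  expect_true(all(a$points$y >= ext[3] & a$points$y <= ext[4]))
  # cluster offspring stay within their disc when it fits in the extent
  only_cl <- simulate_population(ext, 0, cl, seed = 5)
  d <- sqrt((only_cl$points$x - 300)^2 + (only_cl$points$y - 250)^2)
  expect_true(all(d <= 25 + 1e-9))
  # degenerate case
  empty <- simulate_population(ext, 0, NULL, seed = 1)
  expect_identical(nrow(empty$points), 0L)
  expect_error(simulate_population(c(0, -1, 0, 1), 1), "extent")
})

test_that("expected point counts follow Campbell's formula", {
  # background 10 / ha on 10 ha plus one cluster of mean 50: E[N] = 150
  ext <- c(0, 500, 0, 200)  # 10 ha
  cl <- data.frame(x = 250, y = 100, radius = 25, mu = 50)
  counts <- vapply(1:200, function(s) {
    nrow(simulate_population(ext, 10, cl, seed = s)$points)
  }, integer(1))
  expected <- 10 * 10 + 50
  se <- sqrt(expected / 200)  # Poisson superposition
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # cluster-only reef: count ~ Poisson(50)
  ccounts <- vapply(1:200, function(s) {
    nrow(simulate_population(ext, 0, cl, seed = 1000 + s)$points)
  }, integer(1))
  expect_lt(abs(mean(ccounts) - 50), 3 * sqrt(50 / 200))
})

test_that("belt transects recover density unbiasedly on homogeneous reefs", {
  lambda <- 120  # ind / ha
  reef <- simulate_population(c(0, 1000, 0, 500), lambda, NULL, seed = 42)
  sv <- simulate_belt_transects(reef, 200, seed = 43)
  expect_true(all(sv$method == "belt_transect"))
  expect_equal(unique(sv$area_m2), 100)
  est <- transect_density(sv$count, sv$area_m2)
  # conditional on the realized reef, the target is its realized density
  realized <- nrow(reef$points) / 50  # 50 ha
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - realized), 3 * se)

  # empty reef -> all counts zero
  none <- simulate_belt_transects(simulate_population(c(0, 500, 0, 200), 0,
                                                      seed = 1),
                                  10, seed = 2)
  expect_true(all(none$count == 0))
})

test_that("clustered reefs show overdispersed transect counts", {
  # same expected density, clustered vs homogeneous: variance ratio > 1
  ext <- c(0, 1000, 0, 500)
  cl <- data.frame(x = runif(10, 100, 900), y = runif(10, 100, 400),
                   radius = 25, mu = 600)
  clustered <- simulate_population(ext, 0, cl, seed = 7)
  sv <- simulate_belt_transects(clustered, 200, seed = 8)
  mean_count <- mean(sv$count)
  expect_gt(stats::var(sv$count), 2 * mean_count)  # Poisson would give ratio 1
})

test_that("timed swims are thinned belt transects", {
  reef <- simulate_population(c(0, 1000, 0, 500), 100, NULL, seed = 31)
  # detect_p = 1 with identical geometry seed reproduces the belt counts
  sw <- simulate_timed_swims(reef, 50, distance_m = 50, path_width_m = 2,
                             detect_p = 1, seed = 99)
  bt <- simulate_belt_transects(reef, 50, length_m = 50, width_m = 2,
                                seed = 99)
  expect_identical(sw$count, bt$count)
  expect_true(all(sw$method == "timed_swim"))

  # detect_p = 0.5 halves the expected count over 200 swims
  full <- simulate_timed_swims(reef, 200, distance_m = 250, detect_p = 1,
                               seed = 101)
  half <- simulate_timed_swims(reef, 200, distance_m = 250, detect_p = 0.5,
                               seed = 101)
  se <- sd(half$count) / sqrt(200)
  expect_lt(abs(mean(half$count) - mean(full$count) / 2), 3 * se)
  expect_error(simulate_timed_swims(reef, 5, detect_p = 0),
               class = "cotswatch_domain_error")
})

test_that("swims over an outbreak-density reef classify as confirmed", {
  # lambda = 300 / ha, 250 m x 2 m swim: mean 15 in the corridor;
  # P(count >= 6) = 1 - ppois(5, 15) = 0.9972 by closed form
  reef <- simulate_population(c(0, 2000, 0, 1000), 300, NULL, seed = 55)
  sw <- simulate_timed_swims(reef, 200, distance_m = 250, detect_p = 1,
                             seed = 56)
  frac_confirmed <- mean(classify_swim(sw$count) == "confirmed_outbreak")
  expect_gte(frac_confirmed, 0.9)
  expect_equal(1 - ppois(5, 15), 0.99721, tolerance = 1e-4)
})

test_that("simulated report streams behave like the two observer classes", {
  ext <- c(0, 20000, 0, 15000)  # several 5 km quadrats
  reef <- simulate_population(ext, 2, NULL, seed = 200)
  spec <- grid_spec(166.4, -22.3)

  # volunteers spread wider than zone-bound professionals (MC over 30 seeds)
  wider <- vapply(1:30, function(s) {
    reps <- simulate_reports(reef, seed = 300 + s)
    cc <- contribution_analysis(grid_summary(reps, spec))
    cc$range_non_professional > cc$range_professional
  }, logical(1))
  expect_gte(mean(wider), 0.9)

  # zero-density reef: all reports are absences or near-zero counts
  bare <- simulate_population(ext, 0, NULL, seed = 201)
  reps0 <- simulate_reports(bare, seed = 202)
  expect_true(all(reps0$abundance_count == 0))

  # identical parameters + seed -> identical outputs
  r1 <- simulate_reports(reef, seed = 400)
  r2 <- simulate_reports(reef, seed = 400)
  expect_identical(r1, r2)

  # end-to-end: pipeline equals brute-force recomputation
  reps <- simulate_reports(reef, seed = 500)
  g <- grid_summary(reps, spec)
  cc <- contribution_analysis(g)
  qa <- assign_quadrat(reps$lon, reps$lat, spec)
  expect_identical(cc$range_professional,
                   length(unique(qa$quadrat_id[reps$observer_class ==
                                                 "professional"])))
  expect_identical(cc$range_non_professional,
                   length(unique(qa$quadrat_id[reps$observer_class ==
                                                 "non_professional"])))
  expect_identical(cc$range_combined, length(unique(qa$quadrat_id)))
  expect_identical(sum(g$n_total), nrow(reps))
})
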