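spec_nc <- grid_spec(166.4, -22.3, cell_km = 5)

test_that("quadrat assignment is deterministic with half-open 5 km cells", {
  # anchor sits in cell (0, 0)
  q0 <- assign_quadrat(166.4, -22.3, spec_nc)
  expect_identical(c(q0$ix, q0$iy), c(0L, 0L))

  # a point exactly 5 km due east lies on a cell edge -> cell (1, 0)
  p <- unproject_from_grid(5000, 0, spec_nc)
  q1 <- assign_quadrat(p$lon, p$lat, spec_nc)
  expect_identical(c(q1$ix, q1$iy), c(1L, 0L))

  # interior points 1 km apart share a quadrat
  pa <- unproject_from_grid(1000, 1000, spec_nc)
  pb <- unproject_from_grid(2000, 1000, spec_nc)
  expect_identical(assign_quadrat(pa$lon, pa$lat, spec_nc)$quadrat_id,
                   assign_quadrat(pb$lon, pb$lat, spec_nc)$quadrat_id)

  # same spec + same reports -> identical ids across runs
  lons <- 166.4 + runif(50, -0.2, 0.2)
  lats <- -22.3 + runif(50, -0.2, 0.2)
  expect_identical(assign_quadrat(lons, lats, spec_nc),
                   assign_quadrat(lons, lats, spec_nc))
})

test_that("the local equirectangular projection tracks haversine distance", {
  skip_if_not_installed("geosphere")
  # projected distances within 1% of great-circle at |dlat| < 0.2 degrees
  set.seed(7)
  lon <- 166.4 + runif(30, -0.2, 0.2)
  lat <- -22.3 + runif(30, -0.2, 0.2)
  pr <- project_to_grid(lon, lat, spec_nc)
  d_proj <- sqrt(pr$x^2 + pr$y^2)
  d_hav <- geosphere::distHaversine(cbind(166.4, -22.3), cbind(lon, lat),
                                    r = 6371000)
  expect_lt(max(abs(d_proj - d_hav) / d_hav), 0.01)
})

test_that("grid summaries conserve reports and match a nested-loop tally", {
  # 3 reports in one cell, 1 in another
  idx <- tibble::tibble(ix = c(0L, 0L, 0L, 2L), iy = c(0L, 0L, 0L, 1L))
  reports <- reports_in_quadrats(idx, "non_professional", spec_nc)
  g <- grid_summary(reports, spec_nc)
  expect_identical(nrow(g), 2L)
  expect_setequal(g$n_total, c(3L, 1L))

  # class-tagged fixture vs independent nested-loop oracle
  set.seed(11)
  n <- 40L
  mixed <- make_reports(sample(c(1:20, 150), n, TRUE),
                        observer_class = sample(c("professional",
                                                  "non_professional"), n, TRUE))
  mixed$lon <- 166.4 + runif(n, 0, 0.3)
  mixed$lat <- -22.3 + runif(n, 0, 0.3)
  g2 <- grid_summary(mixed, spec_nc)
  qa <- assign_quadrat(mixed$lon, mixed$lat, spec_nc)
  for (i in seq_len(nrow(g2))) {
    in_cell <- qa$quadrat_id == g2$quadrat_id[i]
    expect_identical(g2$n_professional[i],
                     sum(in_cell & mixed$observer_class == "professional"))
    expect_identical(g2$n_non_professional[i],
                     sum(in_cell & mixed$observer_class == "non_professional"))
    expect_identical(g2$cots_total[i], sum(mixed$abundance_count[in_cell]))
  }
  # conservation
  expect_identical(sum(g2$n_total), n)

  # professional-only fixture: combined occupancy equals professional occupancy
  prof_only <- dplyr::filter(mixed, observer_class == "professional")
  g3 <- grid_summary(prof_only, spec_nc)
  expect_identical(sum(g3$occupied_combined), sum(g3$occupied_professional))
  expect_identical(sum(g3$occupied_non_professional), 0L)
})

test_that("contribution analysis reproduces set-arithmetic range sizes", {
  # prof = {A,B}, nonprof = {B,C,D} -> ranges 2/3, combined 4, +50%
  prof <- reports_in_quadrats(tibble::tibble(ix = c(0L, 1L), iy = 0L),
                              "professional", spec_nc)
  nonp <- reports_in_quadrats(tibble::tibble(ix = c(1L, 2L, 3L), iy = 0L),
                              "non_professional", spec_nc)
  contrib <- contribution_analysis(grid_summary(dplyr::bind_rows(prof, nonp),
                                                spec_nc))
  expect_identical(contrib$range_professional, 2L)
  expect_identical(contrib$range_non_professional, 3L)
  expect_identical(contrib$range_combined, 4L)
  expect_equal(contrib$range_increase_pct, 50)

  # identical occupancy -> +0%
  same <- dplyr::bind_rows(
    reports_in_quadrats(tibble::tibble(ix = 0:1, iy = 0L), "professional",
                        spec_nc),
    reports_in_quadrats(tibble::tibble(ix = 0:1, iy = 0L), "non_professional",
                        spec_nc)
  )
  expect_equal(contribution_analysis(grid_summary(same, spec_nc))$range_increase_pct, 0)

  # no professional quadrats -> increase not applicable
  none <- contribution_analysis(grid_summary(nonp, spec_nc))
  expect_true(is.na(none$range_increase_pct))

  # detection bands sum to each class's report total
  set.seed(5)
  n <- 50L
  mixed <- make_reports(sample(c(1, 3, 50, 120, 400), n, TRUE),
                        observer_class = sample(c("professional",
                                                  "non_professional"), n, TRUE))
  mixed$lon <- 166.4 + runif(n, 0, 0.4)
  mixed$lat <- -22.3 + runif(n, 0, 0.4)
  cc <- contribution_analysis(grid_summary(mixed, spec_nc))
  band_totals <- tapply(cc$detections$n, cc$detections$observer_class, sum)
  expect_identical(unname(band_totals[["professional"]]),
                   sum(mixed$observer_class == "professional"))
  expect_identical(unname(band_totals[["non_professional"]]),
                   sum(mixed$observer_class == "non_professional"))
})

test_that("range sizes are monotone under added reports", {
  set.seed(3)
  base_idx <- tibble::tibble(ix = sample(0:6, 12, TRUE),
                             iy = sample(0:6, 12, TRUE))
  reports <- reports_in_quadrats(base_idx,
                                 sample(c("professional", "non_professional"),
                                        12, TRUE),
                                 spec_nc)
  g0 <- contribution_analysis(grid_summary(reports, spec_nc))
  for (k in 1:10) {
    extra <- reports_in_quadrats(
      tibble::tibble(ix = sample(0:8, 1), iy = sample(0:8, 1)),
      sample(c("professional", "non_professional"), 1), spec_nc
    )
    reports <- dplyr::bind_rows(reports, extra)
    g1 <- contribution_analysis(grid_summary(reports, spec_nc))
    expect_gte(g1$range_professional, g0$range_professional)
    expect_gte(g1$range_non_professional, g0$range_non_professional)
    expect_gte(g1$range_combined,
               max(g1$range_professional, g1$range_non_professional))
    g0 <- g1
  }
})

test_that("Mann-Whitney matches exact enumeration and wilcox.test", {
  # identical tied samples: U at its midpoint, p = 1
  mid <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mid$U, 4.5)
  expect_equal(mid$p_value, 1)

  # hand-enumerated extreme case: all 20 assignments, one-sided 1/20
  ext <- mann_whitney_u(c(1, 1, 2), c(5, 6, 7))
  expect_equal(ext$U, 0)
  expect_equal(ext$p_value, 0.1)

  # tie-free exact case agrees with stats::wilcox.test (independent oracle)
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(4.3, 6.7, 8.1, 2.9, 7.7)
  got <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)

  # large-sample normal path agrees with wilcox.test(correct = FALSE)
  set.seed(9)
  x2 <- rpois(30, 4); y2 <- rpois(25, 5)
  got2 <- mann_whitney_u(x2, y2)
  ref2 <- stats::wilcox.test(x2, y2, exact = FALSE, correct = FALSE)
  expect_equal(got2$U, unname(ref2$statistic))
  expect_equal(got2$p_value, ref2$p.value, tolerance = 1e-12)
})

test_that("per-quadrat report-count comparison holds its level under the null", {
  # 200 seeded replicates of ~207 occupied-quadrat observations with equal
  # count distributions: the two-sided test should rarely reject
  set.seed(77)
  rejections <- 0L
  for (r in 1:200) {
    # 116 occupied quadrats, professionals occupy 91 of them
    g <- tibble::tibble(
      n_professional = c(rpois(91, 2) + 1L, rep(0L, 25)),
      n_non_professional = rpois(116, 2) + 1L,
      occupied_professional = c(rep(TRUE, 91), rep(FALSE, 25)),
      occupied_non_professional = TRUE
    )
    res <- compare_reports_per_quadrat(g)
    expect_identical(res$n, 207L)
    if (res$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(1 - rejections / 200, 0.9)
})
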