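test_that("occupancy counts microtubules with at least one filament", {
  mts <- data.frame(mt_id = 1:10)
  recs <- data.frame(host_mt = c(3, 7))
  expect_equal(occupancy(mts, recs)$percent, 20)
  # a microtubule hosting four filaments counts once
  one <- data.frame(mt_id = 1)
  four <- data.frame(host_mt = rep(1, 4))
  expect_equal(occupancy(one, four)$percent, 100)
  expect_equal(occupancy(mts, recs[0, , drop = FALSE])$percent, 0)
  expect_error(occupancy(mts[0, , drop = FALSE], recs), "empty")
  expect_error(occupancy(one, data.frame(host_mt = 99)), "host")
  # duplicating a record within the same host changes nothing
  expect_equal(occupancy(mts, rbind(recs, data.frame(host_mt = 3)))$percent, 20)
  # grouped occupancy pools consistently: sum of group positives = total
  mts$replicate <- rep(c("r1", "r2"), 5)
  occ <- occupancy(mts, recs, group_by = "replicate")
  expect_equal(sum(occ$n_occupied), 2)
  expect_equal(sum(occ$n_mt * occ$percent / 100), 2)
})

test_that("coverage fraction sums filaments, clamps and warns", {
  expect_equal(coverage_fraction(300), 0)
  expect_equal(coverage_fraction(300, c(100, 50)), 0.5)
  expect_equal(coverage_fraction(200, 200), 1)
  expect_warning(cv <- coverage_fraction(100, 120), "clamping")
  expect_equal(cv, 1)
  expect_error(coverage_fraction(0, 10), "mt_length")
  # monotonic non-decreasing in each filament length (warnings expected
  # once the summed length overshoots the microtubule)
  covs <- vapply(seq(10, 400, by = 30), function(l)
    suppressWarnings(coverage_fraction(300, c(l, 20))), 0)
  expect_true(all(diff(covs) >= 0))
})

test_that("orientation concordance is a simple resolved fraction", {
  all_plus <- data.frame(filament_polarity = rep("towards-plus", 5))
  expect_equal(orientation_concordance(all_plus)$fraction, 1)
  # one filament towards minus, two towards plus -> 2/3
  trio <- data.frame(filament_polarity = c("towards-minus", "towards-plus",
                                           "towards-plus"))
  expect_equal(orientation_concordance(trio)$fraction, 2 / 3)
  none <- data.frame(filament_polarity = NA_character_)
  expect_true(is.na(orientation_concordance(none)$fraction))
  # independent random polarity converges to 0.5 within 3 binomial s.e.
  set.seed(51)
  rnd <- data.frame(filament_polarity = sample(
    c("towards-plus", "towards-minus"), 10000, replace = TRUE))
  expect_equal(orientation_concordance(rnd)$fraction, 0.5,
               tolerance = 3 * sqrt(0.25 / 10000) / 0.5)
})

test_that("morphology length fractions weigh segments by length", {
  pure <- data.frame(morphology = "cofilactin", length_nm = 250)
  expect_equal(morphology_length_fraction(pure)$per_group$percent, 100)
  mixed <- data.frame(morphology = c("cofilactin", "other"),
                      length_nm = c(60, 40))
  expect_equal(morphology_length_fraction(mixed)$per_group$percent, 60)
  two <- data.frame(morphology = c("cofilactin", "cofilactin", "factin"),
                    length_nm = c(80, 100, 20),
                    replicate = c("a", "b", "a"))
  res <- morphology_length_fraction(two, group_by = "replicate")
  expect_equal(sort(res$per_group$percent), c(80, 100))
  expect_equal(res$summary$mean, 90)
  expect_equal(res$summary$sd, sd(c(80, 100)), tolerance = 1e-9)
  zero <- data.frame(morphology = "cofilactin", length_nm = 0)
  expect_error(morphology_length_fraction(zero), "zero total length")
})

test_that("replicate summaries use the n-1 standard deviation", {
  s <- replicate_summary(c(90, 96))
  expect_equal(s$mean, 93)
  expect_equal(s$sd, 4.2426407, tolerance = 1e-6)
  s1 <- replicate_summary(42)
  expect_equal(s1$mean, 42)
  expect_true(is.na(s1$sd))
  expect_equal(replicate_summary(c(7, 7, 7))$sd, 0)
})

test_that("scene ground truth flows through host assignment to exact statistics", {
  # a noiseless synthetic scene: two microtubules, one hosting two luminal
  # filaments; every downstream statistic must equal its ground-truth value
  mts <- list(
    list(trace = straight_trace(1, 10, 10), n_pf = 13, polarity = "plus"),
    list(trace = straight_trace(2, 30, 30), n_pf = 14, polarity = "minus"))
  lfs <- list(
    list(host = 1, start_nm = 8, end_nm = 31, sym = cofilactin_sym(),
         polarity = "plus", decorated = TRUE),
    list(host = 1, start_nm = 34, end_nm = 46, sym = factin_sym(),
         polarity = "minus", decorated = FALSE))
  sc <- render_scene(scene_spec(mts, lfs, wedge_halfangle = 60, seed = 8),
                     box = 48, apix = 11.81)
  truth <- sc$luminal_filaments
  # reconstruct traces from ground truth and re-derive the host mapping
  mt_traces <- lapply(seq_along(mts), function(i) {
    tr <- mts[[i]]$trace; tr$id <- i; tr
  })
  hosts <- vapply(seq_len(nrow(truth)), function(i) {
    zr <- seq(truth$start_nm[i], truth$end_nm[i], length.out = 6)
    f <- filament_trace(cbind(10, 10, 5 + zr * 46 / 46), id = i,
                        kind = "luminal")
    assign_host_microtubule(f, mt_traces)
  }, numeric(1))
  expect_equal(hosts, truth$host_mt)
  # occupancy: 1 of 2 microtubules occupied
  occ <- occupancy(data.frame(mt_id = sc$microtubules$mt_id), truth)
  expect_equal(occ$percent, 100 * 1 / 2)
  # coverage of the host equals the summed ground-truth lengths
  cov <- coverage_fraction(sc$microtubules$length_nm[1],
                           truth$length_nm[truth$host_mt == 1])
  expect_equal(cov, (23 + 12) / 46)
  # orientation concordance from ground-truth polarities: host 1 is plus,
  # so filament polarity plus means barbed-end-towards-plus
  recs <- data.frame(filament_polarity = ifelse(
    truth$polarity == sc$microtubules$polarity[truth$host_mt],
    "towards-plus", "towards-minus"))
  expect_equal(orientation_concordance(recs)$fraction, 1 / 2)
})
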