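test_that("cc cleaning retains the top keep_fraction with stable ties", {
  tab <- data.frame(particle_id = 1:100, filament_id = rep(1:10, each = 10),
                    class_label = "13:plus", cc = seq(0.3, 0.101, by = -0.002))
  expect_equal(nrow(clean_by_cc(tab)), 80)
  tab10 <- tab[1:10, ]
  expect_equal(nrow(clean_by_cc(tab10)), 8)
  # all-tied scores: rank (cc desc, id asc), so the highest ids drop
  ties <- data.frame(particle_id = 1:5, filament_id = 1,
                     class_label = "13:plus", cc = rep(0.2, 5))
  kept <- clean_by_cc(ties)
  expect_equal(nrow(kept), 4)
  expect_equal(kept$particle_id, 1:4)
  expect_error(clean_by_cc(tab[0, ]), "empty")
})

test_that("filament calls follow the 65%/50%+cc rule", {
  mk <- function(fracs, ccs) data.frame(
    particle_id = seq_along(fracs), filament_id = 1,
    class_label = fracs, cc = ccs)
  # 70% majority assigns regardless of cc
  p <- mk(c(rep("13:plus", 7), rep("12:plus", 3)), rep(0.05, 10))
  expect_true(call_filament(p)$assigned)
  expect_equal(call_filament(p)$class, "13:plus")
  # 55% with cc 0.14 assigns; with cc 0.10 it does not
  p2 <- mk(c(rep("13:plus", 11), rep("12:plus", 9)), rep(0.14, 20))
  expect_true(call_filament(p2)$assigned)
  p3 <- mk(c(rep("13:plus", 11), rep("12:plus", 9)), rep(0.10, 20))
  expect_false(call_filament(p3)$assigned)
  # 40/40/20 three-way split is undetermined
  p4 <- mk(c(rep("13:plus", 4), rep("12:plus", 4), rep("14:plus", 2)),
           rep(0.2, 10))
  expect_false(call_filament(p4)$assigned)
  expect_true(is.na(call_filament(p4)$class))
  # exact 50/50 modal tie is undetermined even at high cc
  p5 <- mk(c(rep("13:plus", 5), rep("12:plus", 5)), rep(0.3, 10))
  expect_false(call_filament(p5)$assigned)
})

test_that("call_filament matches an independent per-class oracle", {
  set.seed(31)
  classes <- names(pf_class_fractions())
  for (i in 1:300) {
    n <- sample(1:12, 1)
    labels <- sample(classes, n, replace = TRUE,
                     prob = runif(8)^sample(1:3, 1))
    cc <- runif(n, 0, 0.3)
    got <- call_filament(data.frame(particle_id = 1:n, filament_id = 1,
                                    class_label = labels, cc = cc))
    want <- oracle_call(labels, cc)
    expect_identical(got$class, want)
  }
})

test_that("raising cc_min never converts undetermined to assigned", {
  set.seed(32)
  classes <- names(pf_class_fractions())
  for (i in 1:100) {
    n <- sample(2:15, 1)
    p <- data.frame(particle_id = 1:n, filament_id = 1,
                    class_label = sample(classes, n, replace = TRUE),
                    cc = runif(n, 0, 0.3))
    low <- call_filament(p, assignment_rule(cc_min = 0.10))
    high <- call_filament(p, assignment_rule(cc_min = 0.20))
    expect_false(!low$assigned && high$assigned)
  }
})

test_that("cleaning plus calling is invariant to particle order", {
  tab <- simulate_vote_table(30, 12, pf_class_fractions(), seed = 33)
  calls1 <- call_filaments(clean_by_cc(tab))
  set.seed(34)
  shuffled <- tab[sample(nrow(tab)), ]
  calls2 <- call_filaments(clean_by_cc(shuffled))
  calls2 <- calls2[match(calls1$filament_id, calls2$filament_id), ]
  expect_equal(calls1$class, calls2$class)
  expect_equal(calls1$fraction, calls2$fraction)
})

test_that("protrusion summaries apply the 2-microtubule rule", {
  calls <- data.frame(
    filament_id = 1:6,
    protrusion_id = c(1, 1, 1, 2, 3, 3),
    class = c("13:plus", "13:plus", "13:plus", "13:plus", "13:plus", "12:minus"),
    assigned = TRUE, stringsAsFactors = FALSE)
  s <- summarize_protrusions(calls)
  expect_equal(s$orientation[s$protrusion_id == 1], "uniform")
  expect_equal(s$pf_mix[s$protrusion_id == 1], "single")
  expect_equal(s$orientation[s$protrusion_id == 2], "excluded")  # 1 assigned
  expect_equal(s$orientation[s$protrusion_id == 3], "mixed")
  expect_equal(s$pf_mix[s$protrusion_id == 3], "mixed")
})

test_that("polarity unification flips minus filaments and is idempotent", {
  tab <- simulate_vote_table(20, 10, pf_class_fractions(), p_correct = 1,
                             seed = 35)
  calls <- call_filaments(tab)
  uni1 <- unify_polarity(tab, calls)
  # undetermined filaments are dropped; assigned ones all kept
  expect_setequal(unique(uni1$filament_id),
                  calls$filament_id[calls$assigned])
  # minus-called particles have their direction reversed vs the original
  pol <- split_class_label(calls$class[match(uni1$filament_id,
                                             calls$filament_id)])$polarity
  for (i in which(pol == "minus")[1:5]) {
    d0 <- euler_direction(c(uni1$rot0[i], uni1$tilt0[i], uni1$psi0[i]))
    d1 <- euler_direction(c(uni1$rot[i], uni1$tilt[i], uni1$psi[i]))
    expect_equal(d1, -d0, tolerance = 1e-9)
  }
  for (i in which(pol == "plus")[1:5]) {
    d0 <- euler_direction(c(uni1$rot0[i], uni1$tilt0[i], uni1$psi0[i]))
    d1 <- euler_direction(c(uni1$rot[i], uni1$tilt[i], uni1$psi[i]))
    expect_equal(d1, d0, tolerance = 1e-9)
  }
  # idempotence: unifying the unified table reproduces it
  uni2 <- unify_polarity(uni1, calls)
  expect_equal(uni2$rot, uni1$rot, tolerance = 1e-9)
  expect_equal(uni2$tilt, uni1$tilt, tolerance = 1e-9)
})

test_that("protofilament distributions normalize per group", {
  calls <- data.frame(filament_id = 1:4, protrusion_id = 1,
                      class = c("13:plus", "13:minus", "13:plus", "12:plus"),
                      assigned = TRUE, stringsAsFactors = FALSE)
  d <- pf_distribution(calls)
  expect_equal(unname(d$per_group[1, "13"]), 75)
  expect_equal(unname(d$per_group[1, "12"]), 25)
  # two replicates at 90% and 96%: mean 93, sd 4.243
  calls2 <- data.frame(
    filament_id = 1:100, protrusion_id = 1,
    class = c(rep("13:plus", 90), rep("12:plus", 10),
              rep("13:plus", 96), rep("12:plus", 4))[1:100],
    assigned = TRUE, stringsAsFactors = FALSE)
  calls2 <- rbind(calls2, calls2)
  calls2$filament_id <- 1:200
  calls2$class <- c(rep("13:plus", 90), rep("12:plus", 10),
                    rep("13:plus", 96), rep("12:plus", 4))
  groups <- rep(c("r1", "r2"), each = 100)
  d2 <- pf_distribution(calls2, groups)
  expect_equal(unname(d2$summary$mean_percent[d2$summary$n_pf == 13]), 93)
  expect_equal(unname(d2$summary$sd_percent[d2$summary$n_pf == 13]),
               sd(c(90, 96)), tolerance = 1e-9)
  # all-undetermined group stays flagged as NA
  calls3 <- data.frame(filament_id = 1, protrusion_id = 1,
                       class = NA_character_, assigned = FALSE)
  d3 <- pf_distribution(calls3)
  expect_true(all(is.na(d3$per_group)))
})

test_that("the 13-protofilament percentage is recovered across seeded runs", {
  # at 40 votes per filament with p_correct 0.85 the caller recovers each
  # filament, so the deviation from 93.3% is the binomial sampling of 544
  # filaments (s.e. ~1.1 points); nearly all seeded runs land within 3
  devs <- vapply(1:20, function(s) {
    tab <- simulate_vote_table(544, 40, pf_class_fractions(),
                               p_correct = 0.85, seed = 100 + s)
    calls <- call_filaments(clean_by_cc(tab),
                            all_ids = unique(tab$filament_id))
    a <- calls[calls$assigned, ]
    abs(100 * mean(split_class_label(a$class)$n_pf == 13) - 93.3)
  }, 0)
  expect_gte(mean(devs <= 3), 0.95)
})
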