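mde_rule <- function() mde_gad_fixture()$rules$MDE
gad_rule <- function() mde_gad_fixture()$rules$GAD

test_that("the 14-day episodic rule holds on exact boundaries", {
  fx <- mde_gad_fixture()
  syms <- fx$table$symptoms
  rule <- mde_rule()

  # five symptoms including a core active on days 10-23 (14 days): positive
  h <- empty_history(syms, 40)
  h[c("mDep", "mWei", "mRep", "bSle", "bFat"), 10:23] <- 1L
  expect_true(diagnose_history(h, rule))

  # 13 days only: negative
  h13 <- empty_history(syms, 40)
  h13[c("mDep", "mWei", "mRep", "bSle", "bFat"), 10:22] <- 1L
  expect_false(diagnose_history(h13, rule))

  # five non-core symptoms for 20 days, no core ever: negative
  hn <- empty_history(syms, 40)
  hn[c("mWei", "mRep", "bSle", "bFat", "bCon"), 10:29] <- 1L
  expect_false(diagnose_history(hn, rule))

  # only 4 simultaneous symptoms: negative
  h4 <- empty_history(syms, 40)
  h4[c("mDep", "mWei", "bSle", "bFat"), 1:30] <- 1L
  expect_false(diagnose_history(h4, rule))

  # symptom identity may vary day to day within the run
  hv <- empty_history(syms, 40)
  hv[c("mDep", "mWei", "mRep", "bSle"), 10:23] <- 1L
  hv["bFat", 10:16] <- 1L
  hv["bCon", 17:23] <- 1L
  expect_true(diagnose_history(hv, rule))

  expect_error(diagnose_history(empty_history(c("x", "y"), 20), rule),
               "lacks")
})

test_that("the 182-day chronic rule needs most symptoms most days", {
  fx <- mde_gad_fixture()
  syms <- fx$table$symptoms
  rule <- gad_rule()

  # all GAD symptoms on all of days 1-182: positive
  h <- empty_history(syms, 365)
  h[rule$symptoms, 1:182] <- 1L
  expect_true(diagnose_history(h, rule))

  # a history shorter than the window cannot qualify (with a warning)
  h181 <- empty_history(syms, 181)
  h181[rule$symptoms, ] <- 1L
  expect_warning(res <- diagnose_history(h181, rule), "window")
  expect_false(res)

  # cores near-always active but only 2 other symptoms ever on: the
  # majority requirement (>50% of the 9 symptoms) fails
  h2 <- empty_history(syms, 365)
  h2[rule$core, 1:182] <- 1L
  h2[c("gMus", "bSle"), 1:120] <- 1L  # duty 120/182 > 0.5 but only 5 symptoms
  # 3 cores + 2 others = 5 of 9 > 4.5: actually qualifies under per-symptom
  expect_true(diagnose_history(h2, rule))
  h3 <- empty_history(syms, 365)
  h3[rule$core, 1:182] <- 1L
  h3["gMus", 1:120] <- 1L             # 4 symptoms with majority duty: fails
  expect_false(diagnose_history(h3, rule))

  # a core active on exactly half the days fails the strict majority
  h4 <- empty_history(syms, 365)
  h4[rule$symptoms, 1:182] <- 1L
  h4["gAnx", ] <- 0L
  h4["gAnx", 1:91] <- 1L
  expect_false(diagnose_history(h4, rule))

  # simultaneous variant is stricter: scattered duty cycles fail it
  rule_sim <- diagnosis_rule("GAD", rule$symptoms, rule$core, 5L, 182L,
                             criterion = "most-days",
                             window_mode = "simultaneous")
  h5 <- empty_history(syms, 365)
  h5[rule$core, 1:182] <- 1L
  h5[c("gMus", "gIrr")[1], seq(1, 182, by = 2)] <- 1L
  h5[c("gMus", "gIrr")[2], seq(2, 182, by = 2)] <- 1L
  expect_false(diagnose_history(h5, rule_sim))
  h6 <- empty_history(syms, 365)
  h6[c(rule$core, "gMus", "gIrr"), 1:182] <- 1L
  expect_true(diagnose_history(h6, rule_sim))
})

test_that("activating additional symptom-days never revokes a diagnosis", {
  fx <- mde_gad_fixture()
  sp <- fixture_dynamics_spec(fx)

  # constructed positive stays positive under any added activation
  h0 <- empty_history(fx$table$symptoms, 60)
  h0[c("mDep", "mInt", "mWei", "bSle", "bFat"), 20:40] <- 1L
  expect_true(diagnose_history(h0, fx$rules$MDE))
  set.seed(41)
  h1 <- h0
  h1[sample(which(h1 == 0L), 100)] <- 1L
  expect_true(diagnose_history(h1, fx$rules$MDE))

  # and on simulated histories for both rules
  set.seed(44)
  for (i in 1:8) {
    h <- simulate_person(sp, 365, seed = 100 + i)
    extra <- h
    flip <- which(extra == 0L)
    extra[sample(flip, length(flip) %/% 10)] <- 1L
    for (rule in fx$rules) {
      expect_true(!diagnose_history(h, rule) || diagnose_history(extra, rule))
    }
  }
})

test_that("odds ratios follow the 2x2 arithmetic with continuity handling", {
  mk <- function(n11, n10, n01, n00) {
    x <- rep(c(TRUE, TRUE, FALSE, FALSE), c(n11, n10, n01, n00))
    y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(n11, n10, n01, n00))
    list(x = x, y = y)
  }
  t1 <- mk(30, 10, 10, 50)
  expect_equal(as.numeric(odds_ratio(t1$x, t1$y)), 15)
  t2 <- mk(25, 25, 25, 25)
  expect_equal(as.numeric(odds_ratio(t2$x, t2$y)), 1)
  # swapping the disorders leaves the OR unchanged
  expect_equal(as.numeric(odds_ratio(t1$y, t1$x)), 15)
  # a zero cell triggers the Haldane correction
  t3 <- mk(10, 5, 0, 85)
  expect_message(or3 <- odds_ratio(t3$x, t3$y), "Haldane")
  expect_equal(as.numeric(or3), (10.5 * 85.5) / (5.5 * 0.5))
  expect_true(attr(or3, "corrected"))

  # independent diagnoses: OR near 1
  set.seed(2)
  x <- runif(20000) < 0.2; y <- runif(20000) < 0.1
  expect_lt(abs(log(as.numeric(odds_ratio(x, y)))), 3 * sqrt(sum(1 / c(
    sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)))))
})

test_that("Cronbach's alpha matches its closed form", {
  set.seed(3)
  z <- rbinom(200, 1, 0.5)
  # two perfectly correlated items: alpha = 1
  expect_equal(cronbach_alpha(cbind(z, z)), 1, tolerance = 1e-12)
  items <- cbind(z, rbinom(200, 1, 0.5), rbinom(200, 1, 0.5))
  k <- ncol(items)
  direct <- k / (k - 1) *
    (1 - sum(apply(items, 2, var)) / var(rowSums(items)))
  expect_equal(cronbach_alpha(items), direct, tolerance = 1e-12)
})

test_that("plausibility checks use closed intervals", {
  fx <- mde_gad_fixture()
  sp <- fixture_dynamics_spec(fx)
  panel <- simulate_population(sp, 300, 365, seed = 8)
  st <- suppressMessages(population_statistics(panel, fx$rules))
  chk <- plausibility_check(st)
  expect_named(chk$per_statistic, c("MDE", "GAD", "odds_ratio", "alpha"))
  expect_equal(chk$overall, all(chk$per_statistic))

  # boundary values are in range (closed intervals)
  st2 <- st
  st2$prevalence[["MDE"]] <- 0.15
  expect_true(plausibility_check(st2)$per_statistic[["MDE"]])
  st2$prevalence[["MDE"]] <- 0.199
  expect_false(plausibility_check(st2)$per_statistic[["MDE"]])
  expect_false(plausibility_check(st2)$overall)

  expect_error(plausible_ranges(mde = c(0.2, 0.1)), "increasing")
})

test_that("replication studies are reproducible and shuffle-invariant for tied params", {
  fx <- mde_gad_fixture()
  g <- project_to_symptom_graph(fx$table)
  # identical (b, c) on every symptom: shuffled mode is a no-op
  sp_tied <- dynamics_spec(g, 0.22, b = 1, c = 4.5)
  ro <- replication_study(sp_tied, fx$rules, n_reps = 2, n_persons = 150,
                          days = 365, seed = 5, mode = "original")
  rs <- replication_study(sp_tied, fx$rules, n_reps = 2, n_persons = 150,
                          days = 365, seed = 5, mode = "shuffled")
  expect_equal(ro$replicates[, 2:5], rs$replicates[, 2:5], tolerance = 1e-12)

  # fixed seed: bitwise-identical summaries
  r1 <- replication_study(sp_tied, fx$rules, n_reps = 2, n_persons = 100,
                          days = 365, seed = 9)
  r2 <- replication_study(sp_tied, fx$rules, n_reps = 2, n_persons = 100,
                          days = 365, seed = 9)
  expect_identical(r1$summary, r2$summary)
})

test_that("shuffling keeps the multiset of parameter pairs intact", {
  pars <- data.frame(symptom = letters[1:6], b = 1:6 / 2, c = 6:1)
  sh <- shuffle_params(pars, seed = 3)
  expect_setequal(paste(sh$b, sh$c), paste(pars$b, pars$c))
  expect_equal(sh$symptom, pars$symptom)
  # identical pairs: shuffle is the identity
  same <- data.frame(symptom = c("x", "y"), b = c(1, 1), c = c(2, 2))
  expect_equal(shuffle_params(same, seed = 1), same)
  expect_equal(shuffle_params(pars, seed = 7), shuffle_params(pars, seed = 7))
})
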