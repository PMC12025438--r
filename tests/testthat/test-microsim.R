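test_that("discount factors follow the smooth monthly convention", {
  expect_equal(discount_factor(0, 0.015), 1)
  expect_equal(discount_factor(12, 0), 1)
  expect_equal(discount_factor(12, 0.015), 1 / 1.015)
  expect_equal(discount_factor(12, 0.015), 0.985222, tolerance = 1e-6)
  expect_equal(discount_factor(6, 0.015), 1.015^-0.5)
})

test_that("degenerate parameters produce the expected paths", {
  sq <- mcspc_sequence("abi", "doce")
  cfg <- sim_config(n_patients = 1, horizon = 180, seed = 5)

  # all-zero parameters: the patient never leaves the starting state
  p <- simulate_patient(sq, uniform_catalogue(0, 0, 0, 0), cfg)
  expect_equal(nrow(p), 180)
  expect_true(all(p$state == "mCSPC_low"))
  expect_equal(attr(p, "death_month"), 0)

  # gamma = 1 in the starting state: death at month 1
  p <- simulate_patient(sq, uniform_catalogue(0, 0, 1, 0), cfg)
  expect_equal(nrow(p), 1)
  expect_equal(attr(p, "death_month"), 1)
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  sq <- mcspc_sequence("abi", "doce")
  cat2 <- generate_param_catalogue(seed = 8)
  cfg <- sim_config(n_patients = 500, horizon = 120, seed = 7)
  a <- simulate_cohort(sq, cat2, cfg)
  b <- simulate_cohort(sq, cat2, cfg)
  expect_identical(a$qaly, b$qaly)
  expect_identical(a$cost, b$cost)
  expect_identical(a$death_month, b$death_month)
})

test_that("missing transition parameters are reported by pair", {
  sq <- mcspc_sequence("abi", "doce")
  cat2 <- uniform_catalogue(0.05, 0, 0.02, 0.05)
  cat2[["mCRPC_L1|doce"]] <- NULL
  expect_error(simulate_cohort(sq, cat2, sim_config(n_patients = 10)),
               "mCRPC_L1, doce")
})

test_that("utility accrual matches the cost-utility tables by hand", {
  # one month in mCSPC on abiraterone, undiscounted
  p <- make_path(1, "mCSPC_low", "abi", "active")
  cfg <- sim_config(annual_discount = 0)
  au <- accrue_utility(p, config = cfg)
  expect_equal(unname(au["qaly"]), (0.85 - 0.021) / 12)
  expect_equal(unname(au["ly"]), 1 / 12)

  # full health for the whole horizon: QALY = LY = 15
  p <- make_path(1:180, "nmCSPC", "adt", "active", months_in_state = 1:180)
  tb <- default_tables()
  tb$utilities["nmCSPC"] <- 1
  au <- accrue_utility(p, tables = tb, config = cfg)
  expect_equal(unname(au["qaly"]), 15)
  expect_equal(unname(au["ly"]), 15)

  # an empty path (dead the whole horizon) accrues nothing
  au <- accrue_utility(make_path(integer(0), character(0), character(0),
                                 character(0)), config = cfg)
  expect_equal(unname(au), c(0, 0))

  # suspended months carry no treatment disutility
  p <- make_path(1, "nmCSPC", "enza", "suspended")
  expect_equal(unname(accrue_utility(p, config = cfg)["qaly"]), 0.95 / 12)
})

test_that("cost accrual matches the tables, including terminal care", {
  cfg <- sim_config(annual_discount = 0)

  # one month in mCSPC on abiraterone: 919 + 322 + 92
  p <- make_path(1, "mCSPC_low", "abi", "active")
  expect_equal(accrue_cost(p, config = cfg), 1333)

  # a suspended nmCSPC month incurs only non-IV monitoring
  p <- make_path(1, "nmCSPC", "enza", "suspended")
  expect_equal(accrue_cost(p, config = cfg), 92)

  # chemo months: drug + ADT + IV management; afterwards non-IV, no chemo drug
  p <- make_path(1:2, rep("mCRPC_L1", 2), rep("doce", 2),
                 c("active", "off_chemo"))
  expect_equal(accrue_cost(p, config = cfg),
               (103 + 322 + 455) + (322 + 92))

  # death in progressed mCRPC after >= 12 months there: 12 x 1449 terminal care
  p <- make_path(1:13, rep("progressed_mCRPC", 13), NA_character_, "active",
                 months_in_state = 1:13, death_month = 13)
  expect_equal(accrue_cost(p, config = cfg), 13 * 92 + 12 * 1449)
  expect_equal(12 * 1449, 17388)

  # shorter stays get proportionally fewer terminal-care months
  p <- make_path(1:3, rep("progressed_mCRPC", 3), NA_character_, "active",
                 months_in_state = 1:3, death_month = 3)
  expect_equal(accrue_cost(p, config = cfg), 3 * 92 + 3 * 1449)
})

test_that("engine accruals agree with the R accrual functions path by path", {
  cat2 <- generate_param_catalogue(seed = 21)
  for (sq in list(nmcspc_sequence("enza", "adt", "doce", "caba"),
                  mcspc_sequence("doce + abi", "doce", "caba",
                                 state = "mCSPC_high"))) {
    for (seed in 1:10) {
      cfg <- sim_config(n_patients = 1, horizon = 180, seed = seed)
      p <- simulate_patient(sq, cat2, cfg)
      au <- accrue_utility(p, config = cfg)
      expect_equal(attr(p, "qaly"), unname(au["qaly"]), tolerance = 1e-10)
      expect_equal(attr(p, "ly"), unname(au["ly"]), tolerance = 1e-10)
      expect_equal(attr(p, "cost"), accrue_cost(p, config = cfg),
                   tolerance = 1e-8)
    }
  }
})

test_that("suspension lengths follow the scaled beta distribution", {
  tb <- default_tables()
  m <- tb$suspension
  m$a <- 1; m$b <- 1; m$scale <- 24
  set.seed(2)
  draws <- sample_suspension(m, "enza", n = 10000)
  expect_true(all(draws >= 1))
  expect_lt(abs(mean(draws) - 12), 0.5)

  m$scale <- 1
  expect_true(all(sample_suspension(m, "adt", n = 100) == 1))

  m$a <- 50; m$b <- 1; m$scale <- 10
  set.seed(3)
  expect_lt(abs(mean(sample_suspension(m, "enza", n = 10000)) - 9.8), 0.3)

  expect_error(sample_suspension(m, "abi"), "not taken intermittently")
})

test_that("cohort invariants hold: QALY <= LY, discounting, occupancy", {
  cat2 <- generate_param_catalogue(seed = 14)
  sq <- nmcspc_sequence("enza", "adt", "doce")
  cfg <- sim_config(n_patients = 2000, horizon = 180, seed = 9)
  ch <- simulate_cohort(sq, cat2, cfg)
  expect_true(all(ch$qaly <= ch$ly + 1e-12))
  cfg0 <- cfg; cfg0$annual_discount <- 0
  ch0 <- simulate_cohort(sq, cat2, cfg0)
  expect_true(all(ch$ly <= ch0$ly + 1e-12))
  expect_true(all(ch$cost <= ch0$cost + 1e-8))
  expect_true(all(ch$qaly <= ch0$qaly + 1e-12))
  # same stream: identical death months, so discounted totals are comparable
  expect_identical(ch$death_month, ch0$death_month)
  expect_equal(colSums(ch$occupancy), rep(1, cfg$horizon), tolerance = 1e-12)
})

test_that("the microsimulation mean matches the deterministic projection", {
  set.seed(60)
  sqs <- enumerate_sequences(starting_state = "mCSPC_high")
  for (k in 1:2) {
    cat2 <- generate_param_catalogue(seed = 100 + k)
    sq <- sqs[[sample(length(sqs), 1)]]
    cfg <- sim_config(n_patients = 20000, horizon = 180, seed = k)
    ch <- simulate_cohort(sq, cat2, cfg)
    or <- project_sequence(sq, cat2, cfg)
    se <- stats::sd(ch$ly) / sqrt(cfg$n_patients)
    expect_lt(abs(ch$mean_ly - or$mean_ly), 3 * se)
    # mean months of occupancy per state within three standard errors
    exp_months <- rowSums(or$occupancy[1:7, , drop = FALSE])
    for (s in 1:7) {
      sm <- ch$state_months[, s]
      se_s <- stats::sd(sm) / sqrt(cfg$n_patients)
      expect_lt(abs(mean(sm) - exp_months[s]), 3 * se_s + 1e-9)
    }
  }
})

test_that("an n = 1 cohort equals simulate_patient on the same stream", {
  cat2 <- generate_param_catalogue(seed = 5)
  sq <- mcspc_sequence("enza", "doce", "caba")
  cfg <- sim_config(n_patients = 1, horizon = 120, seed = 33)
  p <- simulate_patient(sq, cat2, cfg)
  ch <- simulate_cohort(sq, cat2, cfg)
  expect_equal(attr(p, "qaly"), ch$qaly[1])
  expect_equal(attr(p, "cost"), ch$cost[1])
  expect_equal(attr(p, "death_month"), ch$death_month[1])
})
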