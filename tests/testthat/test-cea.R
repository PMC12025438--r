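test_that("net health benefit reproduces published table rows", {
  expect_equal(round(compute_nhb(9.57, 95780, 50000), 2), 7.65)
  expect_equal(round(compute_nhb(10.87, 172579, 100000), 2), 9.14)
  expect_equal(compute_nhb(3.2, 0, 50000), 3.2)
  expect_error(compute_nhb(1, 1, 0), "positive")
})

test_that("ranking orders by NHB with deterministic tie handling", {
  res <- data.frame(
    label = c("ref", "a", "b"),
    benefit = c(5, 7, 6.5),
    cost = c(30000, 120000, 60000),
    stringsAsFactors = FALSE)
  tab <- rank_sequences(res, cet = 100000, reference = "ref")
  # brute-force expected order
  nhb <- res$benefit - res$cost / 100000
  expect_equal(tab$label, res$label[order(-nhb, res$cost, res$label)])
  expect_equal(tab$incr_nhb[tab$label == "ref"], 0)
  expect_equal(tab$nhb, nhb[match(tab$label, res$label)])

  # equal NHB: lower cost ranks first
  res2 <- data.frame(label = c("cheap", "dear"),
                     benefit = c(5, 6), cost = c(50000, 150000))
  tab2 <- rank_sequences(res2, cet = 100000, reference = "cheap")
  expect_equal(tab2$nhb[1], tab2$nhb[2])
  expect_equal(tab2$label[1], "cheap")

  expect_error(rank_sequences(res2, 50000, reference = "absent"),
               "not among")
})

test_that("acceptability fractions are probabilities that sum to one", {
  set.seed(77)
  mk <- function(b, cmu) list(benefit = b + rnorm(300, 0, 0.5),
                              cost = cmu + rnorm(300, 0, 5000))
  out <- list(early = mk(8, 150000), late = mk(7, 90000), none = mk(5, 30000))
  cets <- seq(10000, 200000, by = 10000)
  ac <- acceptability_curve(out, cets, iterations = 300, seed = 4)
  expect_true(all(ac >= 0 & ac <= 1))
  expect_equal(unname(rowSums(ac)), rep(1, length(cets)), tolerance = 1e-12)

  # single group: probability one everywhere
  ac1 <- acceptability_curve(out["early"], cets, iterations = 50, seed = 1)
  expect_true(all(ac1 == 1))

  # strict dominance: higher benefit and lower cost for every patient
  dom <- list(best = list(benefit = rep(10, 200), cost = rep(1000, 200)),
              worst = list(benefit = rep(5, 200), cost = rep(9000, 200)))
  ac2 <- acceptability_curve(dom, cets, iterations = 100, seed = 2)
  expect_true(all(ac2[, "best"] == 1))

  # deterministic given the seed
  expect_identical(acceptability_curve(out, cets, iterations = 100, seed = 9),
                   acceptability_curve(out, cets, iterations = 100, seed = 9))

  expect_error(acceptability_curve(out, cets, iteration_size = 1000),
               "fewer than")
})

test_that("tornado threshold scans the acceptability grid", {
  cets <- seq(10000, 100000, by = 10000)
  mk_ac <- function(win) structure(cbind(early = win, other = 1 - win),
                                   cet = cets, class = "acceptability_curve")
  expect_equal(tornado_threshold(mk_ac(rep(1, 10))), 10000)
  expect_true(is.na(tornado_threshold(mk_ac(rep(0, 10)))))
  # step function crossing 0.99 between 40K and 50K: first grid point above
  win <- ifelse(cets >= 45000, 0.995, 0.5)
  expect_equal(tornado_threshold(mk_ac(win)), 50000)
  expect_error(tornado_threshold(structure(matrix(1), cet = numeric(0),
                                           class = "acceptability_curve")),
               "empty CET grid")
})

test_that("pairwise NHB differences cross at most once in 1/CET", {
  set.seed(11)
  cets <- seq(1000, 300000, by = 1000)
  for (i in 1:20) {
    a <- c(benefit = runif(1, 3, 10), cost = runif(1, 2e4, 2e5))
    b <- c(benefit = runif(1, 3, 10), cost = runif(1, 2e4, 2e5))
    d <- compute_nhb(a["benefit"], a["cost"], cets) -
      compute_nhb(b["benefit"], b["cost"], cets)
    signs <- sign(d[abs(d) > 1e-12])
    expect_lte(sum(diff(signs) != 0), 1)
  }
})

test_that("ranking limits: benefit order as CET grows, cost order as it
           vanishes", {
  set.seed(13)
  res <- data.frame(label = letters[1:6], benefit = runif(6, 2, 10),
                    cost = runif(6, 1e4, 2e5))
  hi <- rank_sequences(res, cet = 1e12, reference = "a")
  expect_equal(hi$label, res$label[order(-res$benefit)])
  lo <- rank_sequences(res, cet = 1e-6, reference = "a")
  expect_equal(lo$label, res$label[order(res$cost)])
})

test_that("scenarios adjust horizon, prices, discounting and exchange", {
  sc <- apply_scenario("price_equalized")
  cmp <- sc$tables$components
  expect_equal(cmp$monthly_cost[cmp$name == "enza"], 919)
  expect_equal(cmp$monthly_cost[cmp$name == "apa"], 919)
  expect_equal(cmp$monthly_cost[cmp$name == "daro"], 919)
  expect_equal(cmp$monthly_cost[cmp$name == "abi"], 919)
  expect_equal(unname(sc$tables$costs[["enza"]]), 919)

  expect_equal(apply_scenario("horizon20")$config$horizon, 240L)
  expect_equal(apply_scenario("horizon10")$config$horizon, 120L)

  us <- apply_scenario("us_va")
  expect_equal(us$config$annual_discount, 0.03)
  expect_equal(us$fx, 1.3698)
  expect_equal(us$currency, "USD")

  uk <- apply_scenario("uk_public")
  expect_equal(uk$config$annual_discount, 0.035)
  expect_equal(uk$fx, 1.7504)

  # unlisted prices stay at base values
  expect_equal(unname(us$tables$costs[["management_noniv"]]), 92)
  expect_error(apply_scenario("nonsense"))
})
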