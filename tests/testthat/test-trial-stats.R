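test_that("derived traits follow the stated sums and ratios", {
  d <- rbind(
    rec("trt", "CW", c(10, 12)), rec("trt", "FW", c(20, 18)),
    rec("trt", "AGB", c(50, 60)),
    rec("control", "CW", c(8, 9)), rec("control", "FW", c(10, 11)),
    rec("control", "AGB", c(30, 40))
  )
  out <- derive_traits(d)
  tu <- out$value[out$trait == "total underground" & out$treatment == "trt"]
  expect_equal(tu, c(30, 30))
  tb <- out$value[out$trait == "total biomass" & out$treatment == "trt"]
  expect_equal(tb, c(80, 90))
  rs <- out$value[out$trait == "root/shoot ratio" & out$treatment == "trt"]
  expect_equal(rs, c(30 / 50, 30 / 60))
})

test_that("alkaloid totals are additive over all six compounds", {
  mono <- c("benzoylhypaconitine", "benzoylaconitine", "benzoylmesaconitine")
  di <- c("hypaconitine", "aconitine", "mesaconitine")
  vals <- c(0.1, 0.2, 0.3, 0.05, 0.04, 0.03)
  d <- do.call(rbind, Map(function(tr, v) {
    rbind(rec("trt", tr, v * c(1, 2)), rec("control", tr, v * c(1, 1)))
  }, c(mono, di), vals))
  out <- derive_traits(d)
  pick <- function(trait) out$value[out$trait == trait &
                                      out$treatment == "trt"]
  expect_equal(pick("total MDA"), 0.6 * c(1, 2))
  expect_equal(pick("total DDA"), 0.12 * c(1, 2))
  expect_equal(pick("total alkaloids"), pick("total MDA") + pick("total DDA"))
  # additive consistency: total equals the sum of all six compounds
  six <- rowSums(sapply(c(mono, di), function(tr) {
    out$value[out$trait == tr & out$treatment == "trt"]
  }))
  expect_equal(pick("total alkaloids"), unname(six))
})

test_that("C/N ratio uses the organic-matter conversion where needed", {
  d <- rbind(rec("trt", "organic matter", c(17.24, 34.48)),
             rec("trt", "total nitrogen", c(1, 2)),
             rec("control", "organic matter", c(17.24, 17.24)),
             rec("control", "total nitrogen", c(1, 1)))
  out <- derive_traits(d)
  cn <- out$value[out$trait == "C/N ratio" & out$treatment == "trt"]
  expect_equal(cn, c(17.24 / 1.724, 17.24 / 1.724), tolerance = 1e-12)
  # custom conversion factor
  out2 <- derive_traits(d, om_to_oc = 0.5)
  expect_equal(out2$value[out2$trait == "organic carbon" &
                            out2$treatment == "trt"], c(8.62, 17.24))
})

test_that("a partially measured replicate fails loudly, naming the gap", {
  d <- rbind(rec("trt", "CW", c(10, 12)),
             rec("trt", "FW", 20)) # replicate 2 lacks FW
  expect_error(derive_traits(d), "replicate 2.*FW|FW.*replicate 2")
  # a trait group entirely absent is simply skipped
  d2 <- rec("trt", "plant height", c(100, 110))
  expect_identical(derive_traits(d2), d2)
})

test_that("percent increments and significance stars are correct", {
  d <- two_group_trial(c(98, 100, 102), c(196, 200, 204))
  es <- increment_vs_control(d, "yield", "trt")
  expect_equal(es$increment_pct, 100)
  expect_equal(es$control_mean, 100)

  # identical samples: increment 0, not significant
  d0 <- two_group_trial(c(1, 2, 3), c(1, 2, 3))
  es0 <- increment_vs_control(d0, "yield", "trt")
  expect_equal(es0$increment_pct, 0)
  expect_identical(es0$stars, "ns")

  # increments are invariant to the trait's units
  d_scaled <- d
  d_scaled$value <- d_scaled$value * 37.2
  expect_equal(increment_vs_control(d_scaled, "yield", "trt")$increment_pct,
               es$increment_pct)
  expect_equal(increment_vs_control(d_scaled, "yield", "trt")$p_value,
               es$p_value)
})

test_that("the Welch p-value matches a textbook computation", {
  x <- c(12.1, 14.3, 13.8, 15.2, 12.9) # control
  y <- c(16.4, 18.1, 15.9, 17.3, 18.8) # treatment
  d <- two_group_trial(x, y)
  es <- increment_vs_control(d, "yield", "trt")
  # independent Welch computation from the definition
  sx2 <- sum((x - mean(x))^2) / (length(x) - 1)
  sy2 <- sum((y - mean(y))^2) / (length(y) - 1)
  se2 <- sx2 / length(x) + sy2 / length(y)
  tstat <- (mean(y) - mean(x)) / sqrt(se2)
  df <- se2^2 / ((sx2 / length(x))^2 / (length(x) - 1) +
                   (sy2 / length(y))^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(es$p_value, p, tolerance = 1e-10)
  expected_stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  expect_identical(es$stars, expected_stars)
})

test_that("region averages pool the intercrop increments", {
  d <- rbind(rec("control", "pH", c(9, 11)),
             rec("t1", "pH", c(10.5, 11.5)),
             rec("t2", "pH", c(11.5, 12.5)))
  expect_equal(region_average_increment(d, "pH", "R1"), 15)
  # a single treatment is its own average
  d1 <- d[d$treatment != "t2", ]
  expect_equal(region_average_increment(d1, "pH", "R1"), 10)
})

test_that("errors cover zero control mean and missing control", {
  dz <- two_group_trial(c(-1, 1), c(2, 3))
  expect_error(increment_vs_control(dz, "yield", "trt"), "zero")
  d_noctrl <- rbind(rec("t1", "yield", c(1, 2)), rec("t2", "yield", c(3, 4)))
  expect_error(increment_vs_control(d_noctrl, "yield", "t1"),
               "exactly one control")
  # explicit control mapping overrides label detection
  es <- increment_vs_control(d_noctrl, "yield", "t1",
                             controls = c(R1 = "t2"))
  expect_equal(es$control_mean, 3.5)
})

test_that("disease index obeys its closed forms and monotonicity", {
  expect_equal(disease_index(c(10, 0, 0), grades = 0:2, s_max = 2), 0)
  expect_equal(disease_index(c(0, 0, 10), grades = 0:2, s_max = 2), 100)
  expect_equal(disease_index(c(2, 2), grades = c(0, 2), s_max = 4), 25)
  # moving a plant to a worse grade never lowers the index
  base <- disease_index(c(5, 3, 2), grades = 0:2, s_max = 4)
  worse <- disease_index(c(4, 3, 3), grades = 0:2, s_max = 4)
  expect_gte(worse, base)
  expect_error(disease_index(c(0, 0, 0), grades = 0:2, s_max = 2),
               "no plants")
  expect_error(disease_index(c(1, 2), grades = 0:1, s_max = 0), "s_max")
})

test_that("correlation screen retains real signal and masks noise", {
  set.seed(42)
  x <- rnorm(30)
  m <- cbind(a = x, b = 2 * x, c = c(1, 2, 3)[1 + (seq_len(30) %% 3)],
             d = rnorm(30))
  m <- cbind(m, e = -c(m[, "a"])) # perfect negative
  cs <- correlation_screen(m, alpha = 0.05)
  expect_equal(cs$r["a", "b"], 1)
  expect_true(cs$retained["a", "b"])
  expect_equal(cs$r["a", "e"], -1)
  expect_identical(cs$r, t(cs$r))
  expect_true(all(abs(cs$r[!is.na(cs$r)]) <= 1 + 1e-12))
  expect_equal(unname(diag(cs$masked)), rep(1, 5))

  # perfect negative on the spec's 3-point example
  cs2 <- correlation_screen(cbind(x = c(1, 2, 3), y = c(6, 4, 2)))
  expect_equal(cs2$r["x", "y"], -1)

  # constant variables are flagged, not NaN
  cc <- correlation_screen(cbind(k = rep(5, 10), z = rnorm(10)))
  expect_true(is.na(cc$r["k", "z"]))
  expect_match(cc$edges$reason[1], "constant")
  expect_false(cc$retained["k", "z"])
})

test_that("masking is monotone in alpha and calibrated under the null", {
  set.seed(99)
  m <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, letters[1:4]))
  strict <- correlation_screen(m, alpha = 0.01)
  loose <- correlation_screen(m, alpha = 0.10)
  expect_true(all(loose$retained[strict$retained]))

  # independent noise pairs should be masked ~95% of the time at alpha 0.05
  masked <- vapply(1:200, function(s) {
    set.seed(s)
    cs <- correlation_screen(cbind(u = rnorm(100), v = rnorm(100)))
    !cs$retained["u", "v"]
  }, logical(1))
  expect_gte(mean(masked), 0.90)
})
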