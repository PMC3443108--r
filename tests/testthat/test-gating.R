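test_that("flow compositions validate their fractions", {
  expect_error(flow_composition(live_fraction = 1.2), "fractions")
  expect_error(flow_composition(beadpos_fraction_of_monocytes = 0.6,
                                gr1lo_fraction_of_monocytes = 0.5), "Gr1-low")
  cp <- flow_composition()$class_params
  cp$debris$fsc[2] <- 0
  expect_error(flow_composition(class_params = cp), "sigma")
})

test_that("event generation is a deterministic multinomial mixture", {
  comp <- flow_composition(n_events = 5000)
  a <- generate_flow_events(comp, seed = 1)
  b <- generate_flow_events(comp, seed = 1)
  expect_identical(a, b)
  expect_identical(nrow(a), 5000L)
  expect_true(all(table(a$true_class) > 0))
  expect_true(all(is.finite(as.matrix(a[, c("fsc", "ssc", "cd115", "gr1", "fitc")]))))
})

test_that("the live gate is a pure filter that removes planted debris", {
  comp <- flow_composition(n_events = 4000)
  ev <- generate_flow_events(comp, seed = 2)
  live <- gate_live(ev, gate_params())
  expect_lte(nrow(live), nrow(ev))
  expect_identical(sum(live$true_class == "debris"), 0L)
  # all-inside and all-outside degenerate gates
  expect_identical(nrow(gate_live(ev, gate_params(fsc_range = c(-Inf, Inf),
                                                  ssc_range = c(-Inf, Inf)))),
                   nrow(ev))
  expect_identical(nrow(gate_live(ev, gate_params(fsc_range = c(1e7, 1e8)))), 0L)
  expect_error(gate_live(ev[0, ], gate_params()), "non-empty")
})

test_that("monocyte fraction recovers the planted 12.7% and matches enumeration", {
  comp <- flow_composition(n_events = 10000,
                           monocyte_fraction_of_leukocytes = 0.127)
  ev <- generate_flow_events(comp, seed = 3)
  live <- gate_live(ev, gate_params())
  mf <- monocyte_fraction(live, gate_params())
  se3 <- 3 * sqrt(0.127 * 0.873 / nrow(live)) * 100
  expect_lt(abs(mf - 12.7), se3)
  # direct enumeration oracle
  expect_equal(mf, 100 * sum(live$cd115 > 600) / nrow(live))
  # threshold below all values: 100%
  expect_equal(monocyte_fraction(live, gate_params(cd115_threshold = -1e9)), 100)
})

test_that("the Gr1 split is a disjoint partition with high latent accuracy", {
  comp <- flow_composition(n_events = 8000)
  ev <- generate_flow_events(comp, seed = 4)
  live <- gate_live(ev, gate_params())
  mono <- live[live$cd115 > 600, ]
  parts <- split_gr1(mono, gate_params())
  expect_identical(nrow(parts$gr1hi) + nrow(parts$gr1lo), nrow(mono))
  expect_identical(intersect(rownames(parts$gr1hi), rownames(parts$gr1lo)), character(0))
  hi_acc <- mean(parts$gr1hi$true_class %in% c("mono_gr1hi", "mono_gr1hi_beadpos"))
  lo_acc <- mean(parts$gr1lo$true_class %in% c("mono_gr1lo", "mono_gr1lo_beadpos"))
  expect_gte(hi_acc, 0.99)
  expect_gte(lo_acc, 0.99)
  # all below threshold
  all_lo <- split_gr1(mono, gate_params(gr1_threshold = 1e9))
  expect_identical(nrow(all_lo$gr1hi), 0L)
  expect_identical(nrow(all_lo$gr1lo), nrow(mono))
})

test_that("bead-positive fraction recovers the planted 5.8% of monocytes", {
  comp <- flow_composition(n_events = 10000,
                           beadpos_fraction_of_monocytes = 0.058)
  ev <- generate_flow_events(comp, seed = 5)
  live <- gate_live(ev, gate_params())
  mono <- live[live$cd115 > 600, ]
  bp <- bead_positive_fraction(mono, gate_params(), "all_monocytes")
  se3 <- 3 * sqrt(0.058 * 0.942 / nrow(mono)) * 100
  expect_lt(abs(bp - 5.8), se3)
  # beads planted only in Gr1-low: Gr1-high bead-positive fraction is 0
  parts <- split_gr1(mono, gate_params())
  expect_identical(sum(parts$gr1hi$fitc > 400), 0L)
  # fitc threshold above all values: 0%
  expect_equal(bead_positive_fraction(mono, gate_params(fitc_threshold = 1e9)), 0)
  # gr1lo denominator is larger than all_monocytes denominator in value
  expect_gte(bead_positive_fraction(mono, gate_params(), "gr1lo"), bp)
})

test_that("zero bead-positive composition yields no elevated FITC", {
  comp <- flow_composition(n_events = 3000, beadpos_fraction_of_monocytes = 0)
  ev <- generate_flow_events(comp, seed = 6)
  expect_identical(sum(ev$fitc > 400), 0L)
})

test_that("gating fractions are bounded and subsets nest", {
  comp <- flow_composition(n_events = 3000)
  ev <- generate_flow_events(comp, seed = 7)
  res <- gate_chain(ev, gate_params())
  expect_true(res$monocyte_percent >= 0 && res$monocyte_percent <= 100)
  expect_lte(res$n_monocytes, res$n_live)
  expect_lte(res$beadpos_gr1lo_percent_of_monocytes, res$gr1lo_percent_of_monocytes)
})
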