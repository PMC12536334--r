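test_that("risk quotient and band classification follow the documented partition", {
  expect_equal(risk_quotient(66, 6.8), 66 / 6.8) # ~9.71, medium
  expect_equal(as.character(classify_rq(risk_quotient(66, 6.8))), "medium")
  expect_equal(risk_quotient(0, 5), 0)
  expect_error(risk_quotient(1, 0), "positive")
  expect_error(risk_quotient(-1, 5), ">= 0")

  # boundary suite: 0.1-eps, 0.1, 1-eps, 1, 10, 10+eps
  eps <- 1e-9
  got <- as.character(classify_rq(c(0.05, 0.1 - eps, 0.1, 1 - eps, 1, 10,
                                    10 + eps, 25)))
  expect_equal(got, c("insignificant", "insignificant", "low", "low",
                      "medium", "medium", "high", "high"))
  # monotone: category never decreases as RQ grows
  rq <- sort(stats::runif(100, 0, 20))
  expect_true(!is.unsorted(as.integer(classify_rq(rq))))
  expect_error(classify_rq(-0.1), ">= 0")
})

test_that("internal EC50 and worst-case BCF selection", {
  expect_equal(internal_ec50(20, 100), 2000) # ug/L x L/kg = ng/g
  expect_equal(internal_ec50(3.5, 1), 3.5)
  expect_error(internal_ec50(0, 10), "positive")
  expect_equal(select_worst_case_bcf(c(120, 85)), 120)
  expect_equal(select_worst_case_bcf(7), 7)
  expect_equal(select_worst_case_bcf(c(3, 3)), 3)
  expect_error(select_worst_case_bcf(numeric(0)), "no BCF")
  expect_error(select_worst_case_bcf(c(2, -1)), "positive")
})

test_that("toxic units are log ratios with a strict -3 threshold", {
  expect_equal(toxic_unit(200, 200), 0)
  expect_equal(toxic_unit(0.2, 200), -3)
  expect_false(toxic_unit(0.2, 200) > -3) # boundary does not exceed
  expect_equal(toxic_unit(63, 200), log10(63 / 200), tolerance = 1e-12)
  expect_equal(round(toxic_unit(63, 200), 3), -0.502)
  # log-linearity: x10 concentration shifts TU by exactly +1
  expect_equal(toxic_unit(630, 200), toxic_unit(63, 200) + 1)
})

test_that("effect units use the configured tissue-scale denominator", {
  # denominator: pc_crit [mg/L] x bcf [L/kg] = mg/kg -> ng/g via x1000
  expect_equal(eu_denominator_ng_g(1e-4, 10), 1)
  expect_equal(effect_unit(1, 1e-4, 10), 0)
  expect_equal(effect_unit(10, 1e-4, 10), 1)
  # c_invert equal to the denominator gives 0
  expect_equal(effect_unit(6.4e-6 * 15600 * 1000, 6.4e-6, 15600), 0)
  # halving bcf raises EU by log10(2)
  expect_equal(effect_unit(5, 1e-4, 5) - effect_unit(5, 1e-4, 10), log10(2))
  # x10 concentration shifts EU by exactly +1
  expect_equal(effect_unit(50, 1e-4, 10), effect_unit(5, 1e-4, 10) + 1)
  # pc_crit_only form ignores bcf
  expect_equal(effect_unit(0.1, 1e-4, form = "pc_crit_only"), 0)
  expect_error(effect_unit(1, 0, 10), "positive")
  expect_error(effect_unit(1, 1e-4, NULL), "bcf")
})

test_that("sampler-as-organism pseudo-concentration is mass over disk weight", {
  expect_equal(psd_pseudo_concentration(6.7), 6.7 / 0.0115)
  expect_equal(psd_pseudo_concentration(0), 0)
  expect_equal(psd_pseudo_concentration(0.0115), 1)
  expect_error(psd_pseudo_concentration(1, 0), "positive")
  # substitution transparency: sampler TU equals tissue TU when the
  # pseudo-concentration equals the tissue concentration
  conc <- 63
  expect_equal(toxic_unit(psd_pseudo_concentration(conc * 0.0115), 200),
               toxic_unit(conc, 200))
})

test_that("risk_table assembles RQ/TU/EU per quantifiable cell", {
  comp <- demo_compounds()
  meas <- demo_measurements()
  rt <- risk_table(meas, comp)

  # water RQ for the demo neonicotinoid: monthly MEC / PNEC
  imi_rq <- rt[rt$compound_id == "imidacloprid" & rt$matrix == "water" &
                 rt$metric == "RQ", ]
  expect_equal(nrow(imi_rq), 6)
  expect_equal(sort(imi_rq$value),
               sort(c(52, 60, 89, 75, 62, 58) / 6.8))
  expect_true(all(imi_rq$value > 1)) # medium or above every month

  # sampler RQ exists only where Rs exists: no HLB rows (no HLB rate)
  expect_equal(nrow(rt[rt$compound_id == "imidacloprid" &
                         rt$matrix == "psd_hlb" & rt$metric == "RQ", ]), 0)
  expect_gt(nrow(rt[rt$compound_id == "imidacloprid" &
                      rt$matrix == "psd_anion" & rt$metric == "RQ", ]), 0)
  skipped <- attr(rt, "skipped")
  expect_true(any(skipped$compound_id == "imidacloprid" &
                    skipped$matrix == "psd_hlb"))

  # sampler RQ value equals TWA/PNEC computed by hand
  anion_sep <- rt[rt$compound_id == "imidacloprid" &
                    rt$matrix == "psd_anion" & rt$metric == "RQ" &
                    rt$month == "2021-09", ]
  mass <- meas$value[meas$compound_id == "imidacloprid" &
                       meas$matrix == "psd_anion" & meas$month == "2021-09"]
  expect_equal(anion_sep$value, (mass / (0.045 * 7)) / 6.8)

  # TU rows: pesticide with EC50+BCF, tissue and sampler routes
  tu <- rt[rt$metric == "TU", ]
  expect_true(all(tu$compound_id == "imidacloprid"))
  expect_setequal(unique(tu$matrix),
                  c("biota", "psd_hlb", "psd_anion", "psd_cation"))
  expect_true(all(tu$exceeds_tu_threshold))

  # EU rows: pharmaceuticals with PC_crit; sulfapyridine skipped
  eu <- rt[rt$metric == "EU", ]
  expect_setequal(unique(eu$compound_id), c("citalopram", "clopidogrel"))
  expect_true(any(skipped$compound_id == "sulfapyridine"))

  # sorted descending within metric
  for (mt in c("RQ", "TU", "EU")) {
    expect_false(is.unsorted(rev(rt$value[rt$metric == mt])))
  }

  # empty input gives an empty table
  expect_equal(nrow(risk_table(meas[0, ], comp)), 0)
})

test_that("monthly risk summaries pool mean and sd", {
  rt <- risk_table(demo_measurements(), demo_compounds())
  sm <- summarise_risk(rt)
  imi <- sm[sm$compound_id == "imidacloprid" & sm$matrix == "water" &
              sm$metric == "RQ", ]
  expect_equal(imi$mean, 66 / 6.8)
  expect_equal(imi$n, 6)
})

test_that("risk report writes CSV plus JSON summary", {
  rt <- risk_table(demo_measurements(), demo_compounds())
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  payload <- write_risk_report(rt, csv, js)
  expect_true(file.exists(csv) && file.exists(js))
  expect_equal(payload$n_results, nrow(rt))
  reread <- jsonlite::read_json(js)
  expect_equal(reread$n_results, nrow(rt))
})
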