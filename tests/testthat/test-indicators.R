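test_that("quantification formulas reproduce hand-checked values", {
  # zero numerators
  expect_equal(quantify_indicator("PE2", c(n_large_farms = 0, n_farms = 500))$value, 0)
  expect_equal(quantify_indicator("PS4", c(n_infected_cattle = 0,
                                           n_beef_cattle = 250))$value, 0)
  # self-sufficiency: 10000 * 180 / (1.9 * 900000) * 100 = 105.263...
  pe3 <- quantify_indicator("PE3", c(slaughter_capacity = 10000,
                                     avg_carcass_weight = 180,
                                     consumption_per_capita = 1.9,
                                     population = 900000))
  expect_equal(pe3$value, 1800000 / 1710000 * 100, tolerance = 1e-12)
  expect_identical(pe3$unit, "percent")
  # yearly water cost: 2 USD/head/month * 10 head * 12 months
  expect_equal(quantify_indicator("PL1", c(water_cost_per_head_month = 2,
                                           n_beef_cattle = 10))$value, 240)
  # fuel cost: 120 km / (12 km/L) * 0.9 USD/L = 9 USD
  expect_equal(quantify_indicator("PL3", c(distance_km = 120,
                                           fuel_km_per_litre = 12,
                                           fuel_price_per_litre = 0.9))$value, 9)
})

test_that("quantification validates operands and denominators", {
  expect_error(quantify_indicator("PE2", c(n_large_farms = 1)), "n_farms")
  expect_error(quantify_indicator("PE2", c(n_large_farms = 1, n_farms = 0)),
               "denominator")
  expect_error(quantify_indicator("PS1", c(n_farmers = -3, n_farms = 10)),
               "non-negative")
})

test_that("scale mapping reproduces published scores and clamps", {
  expect_identical(map_to_scale("PE2", 0.93), 1L)
  expect_identical(map_to_scale("PL1", 925988.57), 2L)
  expect_identical(map_to_scale("RS1", 10.75), 4L)
  expect_identical(map_to_scale("PE3", 519.11), 6L)      # clamp above top bin
  expect_identical(map_to_scale("RE1", 3215.13), 1L)     # clamp below bottom
  expect_identical(map_to_scale("PS4", 1.41), 6L)        # reversed scale
  expect_identical(map_to_scale("RS2", 100), 6L)         # clamp at >= 50%
  # values exactly at a lower breakpoint belong to that bin
  expect_identical(map_to_scale("PE2", 8), 2L)
  expect_identical(map_to_scale("PE3", 100), 6L)
  expect_identical(map_to_scale("PL2", 4644.57), 2L)
})

test_that("scale mapping is a total monotone step function per indicator", {
  for (def in indicator_definitions()) {
    edges <- as.numeric(def$edges)
    grid <- sort(unique(c(
      seq(edges[1] - diff(range(edges)) * 0.2,
          edges[6] + diff(range(edges)) * 0.2, length.out = 400),
      edges, edges - 1e-9, edges + 1e-9)))
    sc <- map_to_scale(def, grid)
    expect_true(all(sc %in% 1:6), info = def$id)
    steps <- diff(sc)
    if (identical(def$polarity, "higher-is-better")) {
      expect_true(all(steps >= 0), info = def$id)
    } else {
      expect_true(all(steps <= 0), info = def$id)
    }
  }
})

test_that("unit mismatch between value and definition is rejected", {
  v <- quantify_indicator("PS1", c(n_farmers = 120, n_farms = 100))
  expect_error(map_to_scale("PE2", v), "unit mismatch")
})

test_that("share indicators stay within 0-100 when numerator <= denominator", {
  set.seed(7)
  for (k in 1:50) {
    den <- sample(1:1000, 1)
    num <- sample(0:den, 1)
    for (id in c("PE2", "PE4", "PS3", "PS4")) {
      ops <- switch(id,
        PE2 = c(n_large_farms = num, n_farms = den),
        PE4 = c(n_insured_cattle = num, n_beef_cattle = den),
        PS3 = c(n_educated_farmers = num, n_farmers = den),
        PS4 = c(n_infected_cattle = num, n_beef_cattle = den))
      val <- quantify_indicator(id, ops)$value
      expect_true(val >= 0 && val <= 100)
    }
  }
})

test_that("score_entities builds the published farm score matrix", {
  fix <- region_fixture()
  farm <- fix$values[fix$values$level == "farm", ]
  obs <- data.frame(entity = farm$entity, indicator = farm$indicator,
                    value = farm$value)
  m <- score_entities(indicator_definitions(), obs)
  expect_identical(dim(m), c(3L, 11L))
  expect_true(all(attr(m, "provenance") == "quantified"))
  consistent <- farm[farm$consistent, ]
  for (k in seq_len(nrow(consistent))) {
    expect_identical(m[consistent$entity[k], consistent$indicator[k]],
                     consistent$printed_score[k])
  }
})

test_that("score_entities handles direct scores, degenerate and bad input", {
  defs <- indicator_definitions(c("PE1", "PE2", "PE3"))
  best <- data.frame(entity = "only", indicator = names(defs),
                     score = c(6L, 6L, 6L))
  m <- score_entities(defs, best)
  expect_identical(unname(m[1, ]), c(6L, 6L, 6L))
  expect_true(all(attr(m, "provenance") == "supplied"))

  empty <- data.frame(entity = character(0), indicator = character(0),
                      score = integer(0))
  m0 <- score_entities(defs, empty)
  expect_identical(nrow(m0), 0L)

  hole <- data.frame(entity = c("a", "a"), indicator = c("PE1", "PE2"),
                     score = c(3L, 3L))
  expect_error(score_entities(defs, rbind(hole,
    data.frame(entity = "b", indicator = "PE1", score = 2L))),
    "unresolved")
  expect_error(score_entities(defs,
    data.frame(entity = "a", indicator = "PE1", score = 7L)), "1-6")
})

test_that("status bands partition 0-100 as published", {
  expect_identical(as.character(classify_status(56.14)), "moderately sustainable")
  expect_identical(as.character(classify_status(47.05)), "fairly unsustainable")
  expect_identical(as.character(classify_status(0)), "unsustainable")
  expect_identical(as.character(classify_status(100)), "good sustainability")
  # every index gets exactly one band
  grid <- seq(0, 100, by = 0.25)
  expect_false(anyNA(classify_status(grid)))
  expect_error(classify_status(-0.1), "\\[0, 100\\]")
  expect_error(classify_status(100.1), "\\[0, 100\\]")
})

test_that("mixed decimal styles parse locale-correctly", {
  expect_equal(parse_number("$ 1.657,29", "comma"), 1657.29)
  expect_equal(parse_number("$ 520.662,86", "comma"), 520662.86)
  expect_equal(parse_number("2.43%", "point"), 2.43)
  expect_equal(parse_number("1,234.56", "point"), 1234.56)
  expect_equal(parse_number(c("1,5", "1.5"), c("comma", "point")), c(1.5, 1.5))
})
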