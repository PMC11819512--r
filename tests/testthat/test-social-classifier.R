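test_that("searching phase detection tolerates isolated slow intervals", {
  crit <- social_criteria()
  # constant 500 c/s burst: nothing below 200
  expect_false(has_searching_phase(const_train(500, 100), crit))
  # opening with 20 ICIs at 50 c/s: contiguous run longer than the window
  expect_true(has_searching_phase(rate_train(c(rep(50, 20), rep(500, 200))), crit))
  # one isolated 150 c/s interval inside a 100-ICI burst: 1% < 10% tolerance
  expect_false(has_searching_phase(rate_train(c(rep(500, 60), 150, rep(500, 40))), crit))
})

test_that("terminal buzz requires a robust rising trend above the median", {
  crit <- social_criteria()
  # rates rising 100 -> 600 over the final 10 ICIs
  expect_true(ends_in_buzz(rate_train(c(rep(300, 50), seq(100, 600, length.out = 10))), crit))
  # constant-rate burst: zero slope
  expect_false(ends_in_buzz(const_train(400, 100), crit))
  # mushroom rise-fall: terminal rate below the median
  expect_false(ends_in_buzz(rate_train(mushroom_rates()), crit))
  # shorter than the trend window: evaluated false, with a note
  short <- ends_in_buzz(const_train(400, 6), crit)
  expect_false(as.logical(short))
  expect_match(attr(short, "note"), "shorter")
})

test_that("discreteness needs 150 ms of silence on both sides", {
  crit <- social_criteria()
  burst <- const_train(500, 100, id = "b", start = 10)
  expect_true(is_discrete(burst, list(), crit))

  before_close <- const_train(300, 50, id = "n1", start = 10 - 50/300 - 0.05)
  expect_false(is_discrete(burst, list(before_close, burst), crit))

  # 200 ms clearance on both sides
  end_b <- burst$times[n_clicks(burst)]
  before_far <- const_train(300, 50, id = "n2", start = 10 - 50/300 - 0.2 + 1/300)
  after_far <- const_train(300, 50, id = "n3", start = end_b + 0.2)
  expect_true(is_discrete(burst, list(before_far, after_far, burst), crit))

  # a foreign click inside the span breaks discreteness
  inside <- click_train("n4", c(10.05), 125)
  expect_false(is_discrete(burst, list(inside), crit))
})

test_that("repeat counting matches profile similarity", {
  crit <- social_criteria()
  m1 <- rate_train(mushroom_rates(), id = "m1", start = 0)
  m2 <- rate_train(mushroom_rates(), id = "m2", start = 3)
  w1 <- rate_train(wiggle_rates(), id = "w1", start = 6)
  expect_equal(find_repeats(m1, list(m1, m2), crit), 2)
  expect_equal(find_repeats(m1, list(m1), crit), 1)
  # mushroom and wiggle of equal duration are not repeats of each other
  expect_equal(find_repeats(m1, list(m1, w1), crit), 1)
  expect_equal(find_repeats(w1, list(m1, w1), crit), 1)
})

test_that("rate band is inclusive at both ends", {
  crit <- social_criteria()
  expect_true(in_rate_band(const_train(600, 100), crit))
  expect_false(in_rate_band(const_train(1200, 100), crit))
  expect_true(in_rate_band(const_train(200, 100), crit))
  expect_true(in_rate_band(const_train(1000, 100), crit))
  expect_false(in_rate_band(const_train(150, 100), crit))
})

test_that("classification is the conjunction of all criteria", {
  crit <- social_criteria()
  # three repeated mushrooms in one frame, one foraging train further away
  m1 <- rate_train(mushroom_rates(), id = "m1", start = 1)
  m2 <- rate_train(mushroom_rates(), id = "m2", start = 4)
  m3 <- rate_train(mushroom_rates(), id = "m3", start = 7)
  forage <- rate_train(foraging_rates(), id = "f1", start = 40)
  trains <- list(m1, m2, m3, forage)
  fr <- frame_partition(trains, 0, 60)
  out <- classify(trains, fr, crit)
  expect_equal(out$decision[out$train_id %in% c("m1", "m2", "m3")],
               rep("social", 3))
  expect_equal(out$pattern[out$train_id == "m1"], "mushroom")
  frow <- out[out$train_id == "f1", ]
  expect_equal(frow$decision, "nonsocial")
  expect_true(grepl("a_search", frow$failed_criteria))
  expect_true(grepl("a_buzz", frow$failed_criteria))

  # deterministic
  expect_identical(out, classify(trains, fr, crit))
  # empty input
  expect_equal(nrow(classify(list(), fr, crit)), 0)
})

test_that("a lone burst fails the repetition criterion", {
  m1 <- rate_train(mushroom_rates(), id = "m1", start = 1)
  fr <- frame_partition(list(m1), 0, 15)
  out <- classify(list(m1), fr)
  expect_equal(out$decision, "nonsocial")
  expect_true(grepl("c_repeat", out$failed_criteria))
})

test_that("tightening tolerances never increases the social count", {
  cfg <- scenario_config(seed = 31, duration_days = 3)
  dep <- generate_deployment(cfg)
  fr <- frame_partition(dep$trains, dep$record_start, dep$record_end)
  el <- eligible_frames(fr)
  cands <- candidate_view(dep$trains, fr)
  n_social <- function(crit)
    sum(classify(cands, el, crit, neighbors = dep$trains)$decision == "social")
  base <- n_social(social_criteria())
  expect_lte(n_social(social_criteria(max_subthreshold_fraction = 0.02)), base)
  expect_lte(n_social(social_criteria(similarity_min = 0.95)), base)
  expect_lte(n_social(social_criteria(discreteness_gap = 500)), base)
  expect_lte(n_social(social_criteria(min_repeats = 3)), base)
})

test_that("no buzz-flagged train is ever marked social", {
  cfg <- scenario_config(seed = 33, duration_days = 5)
  dep <- generate_deployment(cfg)
  fr <- frame_partition(dep$trains, dep$record_start, dep$record_end)
  cands <- candidate_view(dep$trains, fr)
  out <- classify(cands, eligible_frames(fr), neighbors = dep$trains)
  buzzed <- grepl("a_buzz", out$failed_criteria)
  expect_true(all(out$decision[buzzed] == "nonsocial"))
})

test_that("pattern labelling distinguishes mushrooms, wiggles and flats", {
  crit <- social_criteria()
  m <- rate_train(mushroom_rates(), id = "m", label = "social")
  w <- rate_train(wiggle_rates(), id = "w", label = "social")
  flat <- const_train(500, 100, id = "fl", label = "social")
  expect_equal(label_pattern(m, crit), "mushroom")
  expect_equal(label_pattern(w, crit), "wiggle")
  expect_equal(label_pattern(flat, crit), "none")
  expect_error(label_pattern(const_train(500, 100)), "social trains only")
})
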