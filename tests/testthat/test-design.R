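test_that("the counterbalancing scheme matches the published sequences", {
  d <- impl_design()
  expect_equal(nrow(d), 16)
  r11 <- d[d$sequence_id == 1 & d$trial == 1, ]
  expect_equal(r11$verb, "gorp")
  expect_equal(r11$agent, "boy")
  expect_equal(r11$target_action, "D")
  expect_equal(r11$distracter_action, "C")
  expect_equal(r11$target_side, "right")
  r82 <- d[d$sequence_id == 8 & d$trial == 2, ]
  expect_equal(r82$verb, "gorp")
  expect_equal(r82$agent, "girl")
  expect_equal(r82$target_action, "D")
  expect_equal(r82$target_side, "right")
})

test_that("the design is balanced", {
  d <- impl_design()
  expect_equal(sum(d$target_side == "left"), 8)
  expect_equal(as.integer(table(d$target_action)), rep(4L, 4))
  expect_equal(as.integer(table(d$distracter_action)), rep(4L, 4))
  expect_true(all(d$target_action != d$distracter_action))
  # within a sequence each verb and each agent appears exactly once
  for (s in 1:8) {
    rows <- d[d$sequence_id == s, ]
    expect_setequal(rows$verb, c("gorp", "tam"))
    expect_setequal(rows$agent, c("boy", "girl"))
  }
  expect_equal(sort(unique(d$item)), 1:16)
})
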