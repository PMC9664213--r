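test_that("compute_stats matches a hand-computed fixture", {
  s <- compute_stats(c(5, 4, 3, 2, 1))
  expect_identical(s$n, 5L)
  expect_equal(s$mean, 3)
  expect_equal(s$sd, 1.5811388, tolerance = 1e-6)
  expect_equal(s$cv, 0.5270463, tolerance = 1e-6)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$full_score_rate, 0.2)
  expect_identical(classify_consensus(s), "no_consensus")
})

test_that("compute_stats validates ratings and handles n = 1", {
  expect_error(compute_stats(integer()), class = "pip_input_error")
  expect_error(compute_stats(c(1, 6)), class = "pip_input_error")
  expect_error(compute_stats(c(2.5, 3)), class = "pip_input_error")
  s1 <- compute_stats(5L)
  expect_equal(s1$sd, 0)
  expect_equal(s1$cv, 0)
  expect_identical(classify_consensus(s1), "accept")
})

test_that("consensus rules accept, reject and respect the strict CV cut", {
  expect_identical(classify_consensus(compute_stats(c(5, 5, 5, 4, 5))),
                   "accept")
  # unanimity is needed to keep the CV below 0.20 near the bottom of
  # the scale: CV(1,1,2,1,1) = 0.37 is already no consensus
  expect_identical(classify_consensus(compute_stats(c(1, 1, 1, 1, 1))),
                   "reject")
  expect_identical(classify_consensus(compute_stats(c(1, 1, 2, 1, 1))),
                   "no_consensus")
  # high mean but too dispersed: no consensus
  expect_identical(classify_consensus(compute_stats(c(5, 5, 5, 5, 2))),
                   "no_consensus")
  # a CV of exactly 0.20 must not reach consensus
  s <- compute_stats(c(5, 5, 5, 4, 5))
  s$cv <- 0.20
  expect_identical(classify_consensus(s), "no_consensus")
})

test_that("delphi_table summarizes per proposition and round", {
  ratings <- data.frame(
    proposition_id = rep(c("p1", "p2"), each = 5),
    round = 1L,
    rating = c(5, 5, 5, 4, 5, 3, 2, 4, 1, 5))
  tab <- delphi_table(ratings)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$status[tab$proposition_id == "p1"], "accept")
  expect_identical(tab$status[tab$proposition_id == "p2"], "no_consensus")
})

test_that("tally_rounds enforces conservation and hand-over", {
  led <- tally_rounds(list(
    list(entered = 10, accepted = 6, rejected = 1, carried = 3,
         new_next_round = 2),
    list(entered = 5, accepted = 2, rejected = 0, carried = 3)),
    adjudicated_retained = 1)
  expect_identical(led$final_retained, 9)
  expect_error(tally_rounds(list(
    list(entered = 10, accepted = 6, rejected = 1, carried = 2))),
    class = "pip_ledger_error")
  expect_error(tally_rounds(list(
    list(entered = 10, accepted = 6, rejected = 1, carried = 3,
         new_next_round = 0),
    list(entered = 5, accepted = 2, rejected = 0, carried = 3))),
    class = "pip_ledger_error")
})

test_that("read_ratings reads the CSV shape delphi_table consumes", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(proposition_id = "p1", round = 1,
                       panelist_id = paste0("e", 1:5),
                       rating = c(5, 4, 5, 5, 5)),
            f, row.names = FALSE)
  r <- read_ratings(f)
  expect_true(all(c("proposition_id", "round", "rating") %in% names(r)))
  expect_identical(nrow(r), 5L)
  unlink(f)
})
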