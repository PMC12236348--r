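# Helper: minimal response table with constant items.
make_responses <- function(n, spq = 0L, bag = 3L, vid = 4L,
                           attention = TRUE) {
  out <- data.frame(participant_id = paste0("P", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (i in 1:22) out[[sprintf("spq_%02d", i)]] <- rep(spq, n)
  for (i in 1:12) out[[sprintf("bag_%02d", i)]] <- rep(bag, n)
  for (cond in video_conditions()) out[[paste0("vid_", cond)]] <- rep(vid, n)
  out$attention_pass <- rep(attention, length.out = n)
  out
}

test_that("attention filter reproduces the exclusion arithmetic", {
  resp <- make_responses(1139)
  resp$attention_pass[1:45] <- FALSE
  flt <- apply_attention_filter(resp)
  expect_equal(nrow(flt$retained), 1094)
  expect_equal(flt$report$n_removed, 45)
  expect_equal(flt$report$prop_removed, 45 / 1139)

  all_pass <- apply_attention_filter(make_responses(10))
  expect_equal(nrow(all_pass$retained), 10)

  expect_warning(all_fail <- apply_attention_filter(
    make_responses(10, attention = FALSE)), "empty")
  expect_equal(nrow(all_fail$retained), 0)
  expect_equal(all_fail$report$prop_removed, 1)
})

test_that("SPQ-B scoring sums items under the declared map", {
  ones <- make_responses(3, spq = 1L)
  s <- score_spq(ones)
  expect_equal(s$SPQ_total, rep(22, 3))
  expect_equal(s$CogPerc + s$Interp + s$Disorg, s$SPQ_total)

  zeros <- make_responses(3, spq = 0L)
  expect_true(all(score_spq(zeros)[, 1:4] == 0))

  disorg_only <- make_responses(2, spq = 0L)
  for (i in spq_item_map()$Disorg) disorg_only[[sprintf("spq_%02d", i)]] <- 1L
  s2 <- score_spq(disorg_only)
  expect_equal(s2$Disorg, rep(6, 2))
  expect_equal(s2$CogPerc, rep(0, 2))
  expect_equal(s2$Interp, rep(0, 2))

  expect_error(score_spq(make_responses(2, spq = 2L)), "binary")
  expect_error(score_spq(make_responses(2), item_map = list(A = 1:22)),
               "partition|subscale")
  overlap <- list(CogPerc = 1:8, Interp = 8:16, Disorg = 16:22)
  expect_error(score_spq(make_responses(2), item_map = overlap),
               "more than one")
})

test_that("BAG scoring recodes reverse-keyed items before summation", {
  mid <- make_responses(2, bag = 3L)
  s <- score_bag(mid, reverse_keyed = integer())
  expect_true(all(s == 9))

  # reverse-keyed response 5 contributes 1
  r <- make_responses(1, bag = 1L)
  r$bag_01 <- 5L
  s2 <- score_bag(r, reverse_keyed = 1L)
  expect_equal(s2$Perc, 1 + 1 + 1)

  # mixed fixture, hand-summed
  mix <- make_responses(1, bag = 1L)
  vals <- c(2, 4, 5, 1, 3, 2, 5, 5, 4, 1, 2, 3)
  for (i in 1:12) mix[[sprintf("bag_%02d", i)]] <- vals[i]
  s3 <- score_bag(mix, reverse_keyed = 1L)
  expect_equal(s3$Perc, (6 - 2) + 4 + 5)
  expect_equal(s3$Prod, 1 + 3 + 2)
  expect_equal(s3$SocPerc, 5 + 5 + 4)
  expect_equal(s3$SocProd, 1 + 2 + 3)

  bad <- make_responses(2)
  bad$bag_07[2] <- 6L
  expect_error(score_bag(bad), "row 2, item 7")
})

test_that("gesture-task indices are the related-minus-unrelated contrasts", {
  r <- make_responses(1, vid = 4L)
  r$vid_CR1 <- 7L; r$vid_CR2 <- 7L; r$vid_CU1 <- 1L; r$vid_CU2 <- 1L
  expect_equal(score_gesture_task(r)$Icon, 6)

  flat <- make_responses(2, vid = 5L)
  s <- score_gesture_task(flat)
  expect_equal(s$Icon, c(0, 0))
  expect_equal(s$Metaph, c(0, 0))

  r2 <- make_responses(1)
  r2$vid_AR1 <- 7L; r2$vid_AR2 <- 6L; r2$vid_AU1 <- 2L; r2$vid_AU2 <- 1L
  expect_equal(score_gesture_task(r2)$Metaph, 6.5 - 1.5)

  r3 <- make_responses(1)
  r3$vid_CU1 <- NULL
  expect_error(score_gesture_task(r3), "conditions")
  r4 <- make_responses(1)
  r4$vid_AR1 <- 8L
  expect_error(score_gesture_task(r4), "out of range")
})

test_that("scores are invariant to row order and antisymmetric in condition labels", {
  gt <- make_ground_truth()
  resp <- simulate_item_responses(gt, 60, seed = 14)
  scored <- score_responses(resp, apply_filter = FALSE)$subscales
  perm <- sample(nrow(resp))
  scored_perm <- score_responses(resp[perm, ], apply_filter = FALSE)$subscales
  expect_equal(scored[perm, -1], scored_perm[, -1], ignore_attr = TRUE)

  # swapping Related and Unrelated labels flips the sign of both indices
  swapped <- resp
  for (pair in list(c("AR", "AU"), c("CR", "CU"))) {
    for (k in 1:2) {
      a <- paste0("vid_", pair[1], k); b <- paste0("vid_", pair[2], k)
      tmp <- swapped[[a]]; swapped[[a]] <- swapped[[b]]; swapped[[b]] <- tmp
    }
  }
  s1 <- score_gesture_task(resp); s2 <- score_gesture_task(swapped)
  expect_equal(s2$Icon, -s1$Icon)
  expect_equal(s2$Metaph, -s1$Metaph)
})
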