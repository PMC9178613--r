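test_that("eight-to-three state mapping follows the DSSP grouping", {
  expect_equal(map_8_to_3(ss_track("GHIEBTSL"))$labels, "HHHEECCC")
  expect_equal(map_8_to_3(ss_track(strrep("T", 140)))$labels,
               strrep("C", 140))
  # three-state tracks pass through untouched
  t3 <- ss_track("HHEECC")
  expect_identical(map_8_to_3(t3)$labels, "HHEECC")
  # surjective and composition-preserving under the groupings
  set.seed(31)
  chars <- sample(c("G", "H", "I", "E", "B", "T", "S", "L"), 500,
                  replace = TRUE)
  mapped <- map_8_to_3(ss_track(paste(chars, collapse = "")))$labels
  mc <- strsplit(mapped, "")[[1]]
  expect_setequal(unique(mc), c("H", "E", "C"))
  expect_equal(sum(mc == "H"), sum(chars %in% c("G", "H", "I")))
  expect_equal(sum(mc == "E"), sum(chars %in% c("E", "B")))
  expect_error(ss_track("GHIX", alphabet = "eight_state"), "position 4")
})

test_that("the minimum-run filter drops short structured elements and is
           idempotent", {
  expect_equal(min_run_filter("CHHHC"), "CCCCC")
  expect_equal(min_run_filter("CHHHHC"), "CHHHHC")
  expect_equal(min_run_filter("EEEHHHEEE"), "CCCCCCCCC")
  expect_equal(min_run_filter("HHHH"), "HHHH")
  expect_equal(min_run_filter("HHH", k = 3), "HHH")
  set.seed(32)
  for (i in 1:20) {
    s <- paste(sample(c("H", "E", "C"), 60, replace = TRUE), collapse = "")
    f1 <- min_run_filter(s)
    expect_identical(min_run_filter(f1), f1)  # idempotent
    count_he <- function(x) sum(strsplit(x, "")[[1]] %in% c("H", "E"))
    expect_lte(count_he(f1), count_he(s))     # never adds structure
  }
})

test_that("consensus voting takes the per-residue plurality with ties to
           coil", {
  t1 <- ss_track("HHHH"); t2 <- ss_track("HHHH"); t3 <- ss_track("CCCC")
  cons <- ss_consensus(list(t1, t2, t3), k = 1)
  expect_equal(cons$labels, "HHHH")
  # identical tracks reproduce themselves
  same <- ss_consensus(list(t3, t3, t3), k = 1)
  expect_equal(same$labels, "CCCC")
  # two-way H/E tie goes to C
  tie <- ss_consensus(list(ss_track("HHHH"), ss_track("EEEE")), k = 1)
  expect_equal(tie$labels, "CCCC")
  expect_error(ss_consensus(list(ss_track("HH"), ss_track("HHH"))),
               "length mismatch")
  expect_error(ss_consensus(list()), "at least one")
})

test_that("consensus runs tile the sequence and composition sums to one", {
  set.seed(33)
  truth <- ss_track(paste(sample(c("H", "E", "C"), 140, replace = TRUE,
                                 prob = c(0.45, 0.1, 0.45)), collapse = ""))
  tracks <- gen_ss_ensemble(truth, m = 5, err = 0.1, seed = 34)
  cons <- ss_consensus(tracks)
  expect_equal(sum(cons$composition), 1, tolerance = 1e-9)
  expect_equal(cons$runs$start[1], 1L)
  expect_equal(cons$runs$end[nrow(cons$runs)], 140L)
  if (nrow(cons$runs) > 1L)
    expect_equal(cons$runs$start[-1], cons$runs$end[-nrow(cons$runs)] + 1L)
  expect_equal(paste(rep(cons$runs$state, cons$runs$end - cons$runs$start + 1L),
                     collapse = ""), cons$labels)
})

test_that("consensus of noisy predictor tracks matches the simulated
           expectation", {
  set.seed(35)
  truth_str <- paste(sample(c("H", "E", "C"), 140, replace = TRUE),
                     collapse = "")
  truth <- ss_track(truth_str)
  tc <- strsplit(truth_str, "")[[1]]
  # Monte-Carlo oracle over 1000 replicates: each residue is observed
  # correctly with probability 1 - err, otherwise as one of the two *other*
  # symbols uniformly; consensus is the plurality with ties to C
  m <- 5; err <- 0.1; states <- c("H", "E", "C")
  sim_identity <- function() {
    correct <- vapply(tc, function(s) {
      others <- setdiff(states, s)
      obs <- character(m)
      flip <- runif(m) < err
      obs[!flip] <- s
      obs[flip] <- others[sample.int(2, sum(flip), replace = TRUE)]
      cnt <- table(factor(obs, levels = states))
      top <- names(cnt)[cnt == max(cnt)]
      win <- if (length(top) > 1) "C" else top
      win == s
    }, logical(1))
    mean(correct)
  }
  ident <- replicate(1000, sim_identity())
  mu <- mean(ident); sdev <- sd(ident)
  tracks <- gen_ss_ensemble(truth, m = m, err = err, seed = 36)
  cons <- ss_consensus(tracks, k = 1)
  obs_ident <- mean(strsplit(cons$labels, "")[[1]] == tc)
  expect_gte(obs_ident, mu - 4 * sdev)
  expect_gt(obs_ident, 1 - err)  # the vote must beat a single predictor
})

test_that("score-track regions are maximal runs strictly above threshold", {
  flat <- score_track(rep(0.4, 50))
  expect_equal(nrow(call_regions(flat)), 0L)
  at_thr <- score_track(rep(0.5, 50))
  expect_equal(nrow(call_regions(at_thr)), 0L)  # exactly 0.5 is not disorder
  step <- score_track(c(rep(0.3, 82), rep(0.9, 58)))
  reg <- call_regions(step)
  expect_equal(reg$start, 83L)
  expect_equal(reg$end, 140L)
  expect_equal(mean_score(step, 83, 140), 0.9)
  expect_error(mean_score(step, 0, 10), "bad window")
  expect_error(mean_score(step, 20, 10), "bad window")
  expect_error(score_track(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("a disordered C-terminus profile is recovered from a noisy score
           track", {
  seg <- data.frame(start = c(1, 110), end = c(109, 140),
                    mean = c(0.45, 0.823))
  tr <- gen_score_track(seg, sigma = 0.02, seed = 37)
  m <- mean_score(tr, 110, 140)
  expect_equal(m, 0.823, tolerance = 4 * 0.02 / sqrt(31) / 0.823)
  reg <- call_regions(tr)
  # the dominant called region covers the C-terminal disordered segment
  main <- reg[which.max(reg$end - reg$start), ]
  expect_lte(abs(main$start - 110), 3)
  expect_equal(main$end, 140L)
})
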