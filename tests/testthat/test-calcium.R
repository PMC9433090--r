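make_rec <- function(f, bg = rep(0, length(f)), fps = 10) {
  recording(time = (seq_along(f) - 1) / fps, f_neuron = f, f_background = bg)
}

test_that("background subtraction is elementwise and guarded", {
  rec <- make_rec(rep(100, 5), rep(20, 5))
  expect_equal(subtract_background(rec), rep(80, 5))
  rec2 <- make_rec(1:5, 1:5)
  expect_equal(subtract_background(rec2), rep(0, 5))

  set.seed(2)
  a <- runif(50); b <- runif(50)
  rec3 <- make_rec(a, b)
  loop <- numeric(50)
  for (i in 1:50) loop[i] <- a[i] - b[i]
  expect_equal(subtract_background(rec3), loop)

  expect_error(recording(1:5 / 10, 1:5, 1:4), "match the time base")
})

test_that("moving median smooths impulses and matches the sort oracle", {
  expect_equal(moving_median(rep(7, 30)), rep(7, 30))

  spiked <- rep(2, 40); spiked[20] <- 50
  expect_equal(moving_median(spiked, 10)[20], 2)

  set.seed(3)
  x <- rnorm(200)
  expect_equal(moving_median(x, 10), oracle_moving_median(x, 10))
  expect_equal(moving_median(x, 7), oracle_moving_median(x, 7))

  # idempotent on monotone series away from the truncated edge windows
  mono <- sort(runif(50))
  once <- moving_median(mono, 5)
  twice <- moving_median(once, 5)
  interior <- 6:45
  expect_equal(twice[interior], once[interior])
  expect_error(moving_median(numeric(0)), "empty")
})

test_that("percentile baseline follows the interpolation convention", {
  expect_equal(percentile_baseline(rep(4.2, 100)), 4.2)
  expect_equal(percentile_baseline(c(rep(1, 95), rep(10, 5))), 1)

  set.seed(4)
  x <- rlnorm(173, 2, 0.4)
  expect_equal(percentile_baseline(x, 5), oracle_percentile(x, 5))
  expect_equal(percentile_baseline(x, 30), oracle_percentile(x, 30))

  expect_error(percentile_baseline(c(-5, -4, -3)), "not positive")
})

test_that("dF/F0 algebra and baseline positivity invariant", {
  rec <- make_rec(rep(50, 100))
  trace <- compute_dff(rec)
  expect_equal(trace$dff, rep(0, 100))
  expect_equal(trace$baseline, 50)

  step <- make_rec(c(rep(50, 90), rep(100, 10)))
  tr2 <- compute_dff(step)
  expect_equal(max(tr2$dff), 1.0)
  # dff >= -1 whenever smoothed fluorescence >= 0
  expect_true(all(tr2$dff >= -1))
  # at most ~5% of smoothed samples fall below the 5th-percentile baseline
  expect_lte(mean(tr2$smoothed < tr2$baseline), 0.05 + 1 / 100)
})

test_that("peak detection finds planted transients with FWHM durations", {
  flat <- compute_dff(make_rec(rep(30, 200)))
  expect_equal(nrow(detect_peaks(flat)), 0L)

  one <- sim_gcamp_recording(duration = 60, transients = transient(20, 1.0),
                             noise_sd = 0, trajectory_mode = "stationary",
                             seed = 1)
  trace <- compute_dff(one$rec)
  peaks <- detect_peaks(trace)
  expect_equal(nrow(peaks), 1L)
  expect_equal(peaks$time, one$truth$transients$peak_time, tolerance = 0.3)
  expect_equal(peaks$amplitude, 1.0, tolerance = 0.05)
  # FWHM of the 0.5/2 s kernel is about 3 s
  expect_gt(peaks$duration, 1.5)
  expect_lt(peaks$duration, 5)
  # everything inside the reported peak region stays above half maximum
  expect_true(all(trace$dff[peaks$start:peaks$end] >= peaks$amplitude / 2))

  # amplitude is monotone in the planted amplitude
  amps <- c(0.4, 0.8, 1.6)
  det <- sapply(amps, function(a) {
    sim <- sim_gcamp_recording(duration = 40, transients = transient(15, a),
                               noise_sd = 0, trajectory_mode = "stationary",
                               seed = 2)
    max(detect_peaks(compute_dff(sim$rec))$amplitude)
  })
  expect_true(all(diff(det) > 0))

  # separation constraint merges nearby candidates
  two <- sim_gcamp_recording(duration = 40,
                             transients = rbind(transient(15, 1), transient(15.5, 0.9)),
                             noise_sd = 0, trajectory_mode = "stationary",
                             seed = 3)
  pk2 <- detect_peaks(compute_dff(two$rec), min_separation = 5)
  expect_equal(nrow(pk2), 1L)
})

test_that("epoch maxima honour the printed Pre/Stim/Post windows", {
  fps <- 10
  time <- seq(0, 29.9, by = 1 / fps)
  f0_level <- 80
  f <- rep(f0_level, length(time))
  quiet <- microfluidic_percent_change(f, time)
  expect_equal(quiet$f0, f0_level)
  expect_equal(quiet$pre_max, 0)
  expect_equal(quiet$stim_max, 0)
  expect_equal(quiet$post_max, 0)

  f2 <- ifelse(time >= 5 & time <= 15, 1.5 * f0_level, f0_level)
  burst <- microfluidic_percent_change(f2, time)
  expect_equal(burst$stim_max, 50)
  expect_equal(burst$pre_max, 0)
  expect_equal(burst$post_max, 0)

  # a unique maximum exactly at t = 5.0 s belongs to Stim, not Pre
  f3 <- rep(f0_level, length(time))
  f3[which.min(abs(time - 5.0))] <- 2 * f0_level
  edge <- microfluidic_percent_change(f3, time)
  expect_equal(edge$stim_max, 100)
  expect_equal(edge$pre_max, 0)

  # frames in the (4.9, 5.0) gap belong to neither epoch
  t_gap <- c(seq(0, 4.9, 0.1), 4.95, seq(5, 29.9, 0.1))
  f4 <- rep(f0_level, length(t_gap))
  f4[t_gap == 4.95] <- 3 * f0_level
  gap <- microfluidic_percent_change(f4, t_gap)
  expect_equal(gap$pre_max, 0)
  expect_equal(gap$stim_max, 0)

  expect_error(microfluidic_percent_change(rep(-1, length(time)), time),
               "not positive")
})

test_that("signed lawn distance and distance binning", {
  lawn <- list(center = c(0, 0), radius = 2)
  expect_equal(distance_to_lawn(0, 0, lawn), -2)
  expect_equal(distance_to_lawn(2, 0, lawn), 0)
  expect_equal(distance_to_lawn(3.3, 0, lawn), 1.3)

  bins <- bin_dff_by_distance(c(1, 2, 3), c(0.2, 0.7, 1.2))
  expect_equal(bins$bin_lo[bins$n > 0], c(0, 0.5, 1))
  expect_equal(bins$mean[bins$n > 0], c(1, 2, 3))

  const <- bin_dff_by_distance(rep(4, 10), seq(-1, 1.2, length.out = 10))
  expect_true(all(const$mean[const$n > 0] == 4))

  set.seed(6)
  dff <- rnorm(300); d <- runif(300, -2, 4)
  got <- bin_dff_by_distance(dff, d, 0.5)
  idx <- floor(d / 0.5)
  for (r in which(got$n > 0)) {
    sel <- idx == got$bin_lo[r] / 0.5
    expect_equal(got$mean[r], mean(dff[sel]))
    expect_equal(got$n[r], sum(sel))
    expect_equal(got$sem[r], sd(dff[sel]) / sqrt(sum(sel)))
  }
  # empty bins inside the range are reported with n = 0
  gappy <- bin_dff_by_distance(c(1, 2), c(0.1, 2.1))
  expect_true(any(gappy$n == 0))
})

test_that("feeding-state ANOVA flags a planted state offset", {
  sim_binned <- function(offset, seed) {
    set.seed(seed)
    expand_animals <- function(state, shift, ids) {
      do.call(rbind, lapply(ids, function(a) {
        tibble::tibble(animal = paste0(state, a), state = state,
                       bin = seq(0, 2, 0.5),
                       dff = shift + 0.3 * exp(-seq(0, 2, 0.5)) +
                         rnorm(5, 0, 0.1))
      }))
    }
    rbind(expand_animals("fed", 0, 1:5),
          expand_animals("fasted", offset, 1:5))
  }
  null_fit <- state_effect_anova(sim_binned(0, 1))
  expect_gt(null_fit$p[null_fit$term == "state"], 0.001)

  hits <- sum(sapply(1:50, function(s) {
    fit <- state_effect_anova(sim_binned(0.5, 100 + s))
    fit$p[fit$term == "state"] < 0.01
  }))
  expect_gte(hits, 48)

  # literally identical groups: zero state sum of squares, p ~ 1
  half <- sim_binned(0, 2)
  half <- half[half$state == "fed", ]
  mirrored <- half
  mirrored$state <- "fasted"
  mirrored$animal <- paste0("m", mirrored$animal)
  fit0 <- state_effect_anova(rbind(half, mirrored))
  expect_lt(fit0$statistic[fit0$term == "state"], 1e-10)
  expect_gt(fit0$p[fit0$term == "state"], 0.999)

  bad <- sim_binned(0, 3)
  bad <- bad[!(bad$state == "fed" & bad$bin == 0), ]
  expect_error(state_effect_anova(bad), "empty cell")
})

test_that("the fasted > fed binned-signal pattern is reproduced end to end", {
  run_state <- function(state, amp, seeds) {
    do.call(rbind, lapply(seeds, function(s) {
      tr <- rbind(transient(-4, amp), transient(2, amp))
      sim <- sim_gcamp_recording(duration = 40, transients = tr,
                                 onsets_relative_to_encounter = TRUE,
                                 start_distance = 1.2, seed = s)
      trace <- compute_dff(sim$rec)
      d <- distance_to_lawn(trace$x, trace$y, trace$lawn)
      near <- abs(d) <= 1
      tibble::tibble(state = state, animal = paste0(state, s),
                     near_mean = mean(trace$dff[near]))
    }))
  }
  fed <- run_state("fed", 0.75, 1:6)
  fasted <- run_state("fasted", 1.5, 11:16)
  expect_gt(mean(fasted$near_mean), mean(fed$near_mean))
})
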