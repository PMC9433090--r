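test_that("expression generator is deterministic and honours null settings", {
  a <- sim_expression_table(seed = 7)
  b <- sim_expression_table(seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, sim_expression_table(seed = 8)))

  null <- sim_expression_table(n_genes = 200, n_up_chemo = 0, n_up_other = 0,
                               noise_cv = 0, seed = 1)
  expect_true(all(null$truth$true_ratio == 1))
  fc <- compute_fold_changes(null$table, pseudocount = 0.5)
  expect_equal(fc$ratio, rep(1, 200))
  expect_true(all(null$table$abundance >= 0))
})

test_that("planted expression ratios are unbiased within sampling error", {
  cv <- 0.1; reps <- 3
  sim <- sim_expression_table(n_genes = 500, n_up_chemo = 20, fold_range = c(5, 8),
                              noise_cv = cv, n_replicates = reps, seed = 3)
  fc <- compute_fold_changes(sim$table, pseudocount = 0)
  planted <- sim$truth[sim$truth$true_ratio > 1, ]
  est <- fc$ratio[match(planted$gene_id, fc$gene_id)]
  # SE of the ratio of two 3-replicate lognormal means, delta method
  se <- planted$true_ratio * cv * sqrt(2 / reps)
  expect_true(all(abs(est - planted$true_ratio) < 3 * se))

  expect_error(sim_expression_table(n_genes = 100, chemo_fraction = 0.05,
                                    n_up_chemo = 10), "exceeds")
})

test_that("atlas generator covers null, saturated, and planted regimes", {
  genes <- sprintf("g%03d", 1:400)
  a <- sim_neuron_atlas(genes, seed = 5)
  expect_identical(a, sim_neuron_atlas(genes, seed = 5))
  expect_equal(rownames(a), amphid_neurons)
  expect_true(all(a %in% 0:1))

  ones <- sim_neuron_atlas(genes, expressed_prob = 1, seed = 1)
  expect_true(all(ones == 1))

  planted <- sim_neuron_atlas(genes, expressed_prob = 0.1,
                              planted_neuron = "AWA", planted_excess = 5,
                              target_genes = genes, seed = 2)
  rate <- mean(planted["AWA", ])
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / length(genes)))
  other_rate <- mean(planted[rownames(planted) != "AWA", ])
  expect_lt(abs(other_rate - 0.1), 3 * sqrt(0.1 * 0.9 / (11 * length(genes))))

  expect_error(sim_neuron_atlas(genes, planted_neuron = "nope",
                                target_genes = genes), "not among")
  expect_error(sim_neuron_atlas(genes, expressed_prob = 0), "strictly")
})

test_that("image stacks carry an exact soma peak and reproduce under a seed", {
  flat <- sim_image_stack(shape = c(4, 30, 30), soma_amplitude = 0,
                          noise_sd = 0, seed = 1)
  expect_true(all(flat$stack == 100))

  bright <- sim_image_stack(shape = c(8, 40, 40), background_level = 50,
                            soma_amplitude = 100, noise_sd = 0, seed = 2)
  expect_equal(max(bright$stack), 150)
  peak_at <- which(bright$stack == 150, arr.ind = TRUE)
  expect_equal(as.integer(peak_at[1, ]), bright$truth$center)

  expect_identical(sim_image_stack(seed = 9), sim_image_stack(seed = 9))
  expect_error(sim_image_stack(shape = c(4, 10, 10), soma_sigma = 3),
               "too small")
})

test_that("GCaMP generator: null traces, kernel amplitudes, trajectory contract", {
  quiet <- sim_gcamp_recording(duration = 30, noise_sd = 0,
                               trajectory_mode = "stationary", seed = 1)
  dff <- compute_dff(quiet$rec)
  expect_true(all(abs(dff$dff) < 1e-12))

  one <- sim_gcamp_recording(duration = 60, transients = transient(20, 1.0),
                             noise_sd = 0, trajectory_mode = "stationary",
                             seed = 1)
  trace <- compute_dff(one$rec)
  # closed-form kernel maximum on the sampled grid
  time <- one$rec$time
  grid_max <- max(transient_kernel(time - 20, 0.5, 2))
  expect_equal(max(trace$dff), grid_max, tolerance = 0.05)
  expect_equal(max(trace$dff), 1.0, tolerance = 0.05)

  # stationary animals occupy a single distance bin
  d <- distance_to_lawn(quiet$rec$x, quiet$rec$y, quiet$rec$lawn)
  bins <- bin_dff_by_distance(dff$dff, d)
  expect_equal(sum(bins$n > 0), 1L)

  # approach mode crosses the boundary exactly once, at the recorded frame
  appr <- sim_gcamp_recording(duration = 60, seed = 4)
  dist <- distance_to_lawn(appr$rec$x, appr$rec$y, appr$rec$lawn)
  inside <- which(dist <= 0)
  expect_equal(inside[1], appr$truth$encounter_frame)
  expect_equal(inside, inside[1]:length(dist))  # never leaves again

  expect_identical(sim_gcamp_recording(seed = 3), sim_gcamp_recording(seed = 3))
  expect_error(sim_gcamp_recording(frame_rate = 0), "frame_rate")
  expect_error(sim_gcamp_recording(duration = 10, transients = transient(50, 1),
                                   trajectory_mode = "stationary"),
               "outside the recording")
})

test_that("assay-count generator hits its planted index in expectation", {
  even <- sim_assay_counts("chemotaxis", true_index = 0, other_prob = 0,
                           n_animals = 200, n_plates = 40, seed = 1)
  ci <- chemotaxis_index(even$n_odor, even$n_control, even$n_other)
  expect_lt(abs(mean(ci)), 3 * stats::sd(ci) / sqrt(length(ci)))
  expect_true(all(even$n_other == 0))

  all_odor <- sim_assay_counts("chemotaxis", true_index = 1, other_prob = 0,
                               n_animals = 50, n_plates = 5, seed = 2)
  expect_true(all(all_odor$n_odor == 50))

  theta <- 0.6
  many <- sim_assay_counts("chemotaxis", true_index = theta, n_plates = 50,
                           n_animals = 100, seed = 3)
  ci2 <- chemotaxis_index(many$n_odor, many$n_control, many$n_other)
  expect_lt(abs(mean(ci2) - theta), 3 * stats::sd(ci2) / sqrt(50))

  fc <- sim_assay_counts("food_choice", true_index = 0.75, n_plates = 50,
                         n_animals = 100, seed = 4)
  fci <- food_choice_index(fc$n_exp, fc$n_control)
  expect_lt(abs(mean(fci) - 0.75), 3 * stats::sd(fci) / sqrt(50))

  expect_identical(sim_assay_counts("chemotaxis", 0.5, seed = 6),
                   sim_assay_counts("chemotaxis", 0.5, seed = 6))
  expect_error(sim_assay_counts("chemotaxis", 1.5), "\\[-1, 1\\]")
  expect_error(sim_assay_counts("food_choice", -0.1), "\\[0, 1\\]")
})
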