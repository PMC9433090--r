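#' @name olfstate-benchmarks
#' @title Parameter-recovery benchmarks on synthetic ground truth
#'
#' @description Each benchmark regenerates synthetic fixtures across seeds,
#' runs the consuming analysis stage, and scores recovery of the planted
#' parameters. They double as the package's acceptance checks and as a
#' template for users who want to probe the pipeline's operating range.
#' All randomness derives from the single `seed` argument via
#' [derive_seed()].
NULL

#' @describeIn olfstate-benchmarks Fraction of simulated expression tables
#'   (20 planted >4-fold genes, replicate CV 0.05, 3 replicates) whose
#'   planted gene set is recovered *exactly* by fold-change selection at the
#'   fourfold cutoff.
#' @param n_seeds,n_sims Number of simulated datasets.
#' @param seed Master seed.
#' @export
benchmark_de_recovery <- function(n_seeds = 100, seed = 1) {
  hits <- vapply(seq_len(n_seeds), function(i) {
    sim <- sim_expression_table(n_genes = 1000, n_up_chemo = 20,
                                n_up_other = 0, fold_range = c(5, 8),
                                noise_cv = 0.05, n_replicates = 3,
                                seed = derive_seed(seed, i))
    fc <- compute_fold_changes(sim$table, pseudocount = 0.5)
    sets <- select_regulated(fc, threshold = 4)
    planted <- sim$truth$gene_id[sim$truth$true_ratio > 1]
    setequal(sets$upregulated, planted) && length(sets$downregulated) == 0
  }, logical(1))
  mean(hits)
}

#' @describeIn olfstate-benchmarks Fraction of planted-neuron atlases
#'   (one neuron with 5x expression excess for the upregulated family genes,
#'   12 amphid neurons, chemoreceptor repertoire at realistic scale: 133
#'   upregulated of 1365 family genes, 8% baseline expression) in which the
#'   planted neuron — and no other — is Bonferroni-significant at
#'   `alpha = 0.05`.
#' @param planted_excess Expression-probability multiplier for the planted
#'   neuron.
#' @export
benchmark_neuron_specificity <- function(n_seeds = 100, planted_excess = 5,
                                         seed = 1) {
  genes <- sprintf("chem%04d", 1:1365)
  up <- genes[1:133]
  hits <- vapply(seq_len(n_seeds), function(i) {
    atlas <- sim_neuron_atlas(genes, planted_neuron = "AWA",
                              planted_excess = planted_excess,
                              target_genes = up,
                              seed = derive_seed(seed, 1000 + i))
    res <- neuron_enrichment(up, genes, atlas, alpha = 0.05)
    identical(res$neuron[res$significant], "AWA")
  }, logical(1))
  mean(hits)
}

#' @describeIn olfstate-benchmarks Family-wise error rate of the per-neuron
#'   enrichment test under null atlases (no planted neuron): the fraction of
#'   simulated atlases with at least one Bonferroni-significant neuron.
#' @export
benchmark_null_fwer <- function(n_sims = 1000, seed = 1) {
  genes <- sprintf("chem%04d", 1:1365)
  up <- genes[1:133]
  any_sig <- vapply(seq_len(n_sims), function(i) {
    atlas <- sim_neuron_atlas(genes, seed = derive_seed(seed, 5000 + i))
    res <- neuron_enrichment(up, genes, atlas, alpha = 0.05)
    any(res$significant)
  }, logical(1))
  mean(any_sig)
}

#' @describeIn olfstate-benchmarks Mean session-normalized reporter score of
#'   synthetic stacks whose soma amplitude is five times the control
#'   amplitude; unbiased scoring returns 5.
#' @param n_controls Control stacks per simulated session.
#' @export
benchmark_reporter_recovery <- function(n_seeds = 100, n_controls = 3,
                                        seed = 1) {
  norm <- vapply(seq_len(n_seeds), function(i) {
    ctrl <- vapply(seq_len(n_controls), function(j) {
      sim <- sim_image_stack(soma_amplitude = 500,
                             seed = derive_seed(seed, 100 * i + j))
      score_stack(sim$stack)$score
    }, numeric(1))
    trt <- sim_image_stack(soma_amplitude = 2500,
                           seed = derive_seed(seed, 100 * i + 99))
    score_stack(trt$stack)$score / mean(ctrl)
  }, numeric(1))
  mean(norm)
}

#' @describeIn olfstate-benchmarks Sensitivity and relative amplitude error
#'   of peak detection on recordings with 10 planted transients per seed
#'   (amplitudes 0.5-2.0 dF/F0). A planted transient counts as recovered when
#'   a detected peak lies within 1 s of its expected peak time.
#' @export
benchmark_calcium_recovery <- function(n_seeds = 50, seed = 1) {
  found <- 0L; total <- 0L; rel_err <- numeric(0)
  amps <- seq(0.5, 2.0, length.out = 10)
  for (i in seq_len(n_seeds)) {
    onsets <- 10 + 28 * (0:9)
    tr <- do.call(rbind, Map(transient, onsets, amps))
    sim <- sim_gcamp_recording(duration = 300, transients = tr,
                               trajectory_mode = "stationary",
                               seed = derive_seed(seed, 7000 + i))
    peaks <- detect_peaks(compute_dff(sim$rec))
    total <- total + length(amps)
    for (j in seq_along(amps)) {
      hit <- which(abs(peaks$time - sim$truth$transients$peak_time[j]) < 1)
      if (length(hit)) {
        found <- found + 1L
        rel_err <- c(rel_err,
                     abs(peaks$amplitude[hit[1]] - amps[j]) / amps[j])
      }
    }
  }
  list(sensitivity = found / total, mean_rel_amp_error = mean(rel_err))
}

#' @describeIn olfstate-benchmarks Bias of the computed behavioral index
#'   against the generator's planted index, in units of its standard error
#'   over plates.
#' @param assay `"chemotaxis"` or `"food_choice"`.
#' @param thetas Planted index values to test.
#' @param n_plates,n_animals Assay size per theta.
#' @export
benchmark_index_recovery <- function(assay, thetas, n_plates = 200,
                                     n_animals = 100, seed = 1) {
  rows <- lapply(seq_along(thetas), function(i) {
    counts <- sim_assay_counts(assay, thetas[i], n_animals = n_animals,
                               n_plates = n_plates,
                               seed = derive_seed(seed, 9000 + i))
    idx <- if (assay == "chemotaxis") {
      chemotaxis_index(counts$n_odor, counts$n_control, counts$n_other)
    } else {
      food_choice_index(counts$n_exp, counts$n_control)
    }
    sem <- stats::sd(idx) / sqrt(length(idx))
    tibble::tibble(theta = thetas[i], mean = mean(idx), sem = sem,
                   z = (mean(idx) - thetas[i]) / sem)
  })
  do.call(rbind, rows)
}

#' @describeIn olfstate-benchmarks Empirical type-I error of the two-sample
#'   t-test at alpha = 0.05 under the null (both groups standard normal,
#'   n = 10 per group).
#' @param n Per-group sample size for the null simulations.
#' @export
benchmark_t_type1 <- function(n_sims = 10000, n = 10, seed = 1) {
  withr::with_seed(derive_seed(seed, 42), {
    rejections <- vapply(seq_len(n_sims), function(i) {
      two_sample_t(stats::rnorm(n), stats::rnorm(n))$p_raw < 0.05
    }, logical(1))
    mean(rejections)
  })
}
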