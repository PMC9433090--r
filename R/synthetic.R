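#' Derive a reproducible sub-seed
#'
#' All generators take an explicit seed; pipelines that need several
#' independent streams derive one sub-seed per stage from a master seed with
#' this fixed affine scheme. Results stay within the 32-bit integer range
#' expected by [set.seed()].
#'
#' @param seed Master seed (integer).
#' @param offset Stream index (integer >= 0).
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %%
               .Machine$integer.max)
}

#' The 12 amphid neuron classes
#'
#' Default row labels for simulated expression atlases.
#' @export
amphid_neurons <- c("ADF", "ADL", "AFD", "ASE", "ASG", "ASH",
                    "ASI", "ASJ", "ASK", "AWA", "AWB", "AWC")

lognormal_draw <- function(n, mean, cv) {
  # lognormal with the requested mean and coefficient of variation
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a two-condition expression table with planted fold changes
#'
#' Generates a fed/fasted gene-abundance table emulating a neuronal
#' ribotagging experiment. A fixed fraction of genes is labelled
#' `"chemoreceptor"`; `n_up_chemo` chemoreceptor genes and `n_up_other` other
#' genes are planted with fasted/fed abundance ratios drawn uniformly from
#' `fold_range`, all remaining genes have true ratio 1. Per-gene baseline
#' (fed) means are lognormal across genes (median `exp(base_meanlog)`);
#' replicate abundances are lognormal around the condition mean with
#' coefficient of variation `noise_cv`, so every planted gene's *expected*
#' fasted/fed ratio equals its true ratio exactly.
#'
#' @param n_genes Number of genes.
#' @param chemo_fraction Fraction of genes labelled chemoreceptor
#'   (default 0.085, the family's genome-wide prevalence).
#' @param n_up_chemo,n_up_other Planted upregulated genes per family.
#' @param fold_range Length-2 range of planted ratios; the lower bound must
#'   exceed the downstream selection threshold of 4 (default `c(5, 8)`).
#' @param noise_cv Replicate-level coefficient of variation (0 = noise-free).
#' @param n_replicates Replicates per condition.
#' @param seed Integer seed; identical seeds reproduce the table exactly.
#' @param base_meanlog,base_sdlog Log-scale location/spread of per-gene
#'   baseline means.
#' @return List with `table` (long tibble: `gene_id`, `family`, `condition`,
#'   `replicate`, `abundance`) and `truth` (tibble: `gene_id`, `true_ratio`,
#'   `family`).
#' @export
sim_expression_table <- function(n_genes = 1000, chemo_fraction = 0.085,
                                 n_up_chemo = 20, n_up_other = 0,
                                 fold_range = c(5, 8), noise_cv = 0.1,
                                 n_replicates = 3, seed = 1,
                                 base_meanlog = log(100), base_sdlog = 1) {
  n_chemo <- round(chemo_fraction * n_genes)
  if (n_up_chemo > n_chemo) {
    stop("n_up_chemo exceeds the number of chemoreceptor genes", call. = FALSE)
  }
  if (n_up_other > n_genes - n_chemo) {
    stop("n_up_other exceeds the number of non-chemoreceptor genes",
         call. = FALSE)
  }
  if (length(fold_range) != 2 || fold_range[1] > fold_range[2] ||
      fold_range[1] <= 1) {
    stop("fold_range must be an increasing interval above 1", call. = FALSE)
  }
  withr::with_seed(seed, {
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    family <- rep(c("chemoreceptor", "other"), c(n_chemo, n_genes - n_chemo))
    up <- c(sample(which(family == "chemoreceptor"), n_up_chemo),
            sample(which(family == "other"), n_up_other))
    true_ratio <- rep(1, n_genes)
    true_ratio[up] <- stats::runif(length(up), fold_range[1], fold_range[2])
    fed_mean <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    fasted_mean <- fed_mean * true_ratio
    rows <- lapply(seq_len(n_replicates), function(r) {
      tibble::tibble(
        gene_id = rep(gene_id, 2),
        family = rep(family, 2),
        condition = rep(c("fed", "fasted"), each = n_genes),
        replicate = r,
        abundance = c(lognormal_draw(n_genes, 1, noise_cv) * fed_mean,
                      lognormal_draw(n_genes, 1, noise_cv) * fasted_mean)
      )
    })
    list(
      table = do.call(rbind, rows),
      truth = tibble::tibble(gene_id = gene_id, true_ratio = true_ratio,
                             family = family)
    )
  })
}

#' Simulate a binary neuron x gene expression atlas
#'
#' Each (neuron, gene) entry is an independent Bernoulli draw at
#' `expressed_prob`, emulating a thresholded single-cell expression atlas.
#' Optionally one neuron is planted as enriched: for the genes in
#' `target_genes` (e.g. the fasting-upregulated chemoreceptors) its
#' expression probability is multiplied by `planted_excess` (capped at 1).
#'
#' @param genes Character vector of gene ids (atlas columns).
#' @param n_neurons Number of neurons; 12 (default) uses the amphid labels.
#' @param expressed_prob Baseline expression probability (0 < p < 1).
#' @param planted_neuron Optional neuron label to enrich.
#' @param planted_excess Probability multiplier for target genes in the
#'   planted neuron (1 = null).
#' @param target_genes Genes subject to the planted excess (required when
#'   `planted_neuron` is set).
#' @param seed Integer seed.
#' @return Integer 0/1 matrix with neuron row names and gene column names.
#' @export
sim_neuron_atlas <- function(genes, n_neurons = 12, expressed_prob = 0.08,
                             planted_neuron = NULL, planted_excess = 1,
                             target_genes = NULL, seed = 1) {
  if (expressed_prob <= 0 || expressed_prob > 1) {
    stop("expressed_prob must lie strictly above 0 and at most 1", call. = FALSE)
  }
  neurons <- if (n_neurons == 12) amphid_neurons else
    sprintf("N%02d", seq_len(n_neurons))
  if (!is.null(planted_neuron)) {
    if (!planted_neuron %in% neurons) {
      stop("planted_neuron '", planted_neuron, "' not among the neuron labels",
           call. = FALSE)
    }
    if (is.null(target_genes)) {
      stop("target_genes required when planting an enriched neuron",
           call. = FALSE)
    }
  }
  prob <- matrix(expressed_prob, n_neurons, length(genes),
                 dimnames = list(neurons, genes))
  if (!is.null(planted_neuron)) {
    prob[planted_neuron, colnames(prob) %in% target_genes] <-
      min(1, expressed_prob * planted_excess)
  }
  withr::with_seed(seed, {
    draws <- stats::runif(length(prob))
    atlas <- matrix(as.integer(draws < prob), n_neurons, length(genes),
                    dimnames = dimnames(prob))
    atlas
  })
}

#' Simulate a confocal z-stack with one fluorescent soma
#'
#' A uniform background plus one isotropic Gaussian-profile soma and additive
#' Gaussian noise (clipped at zero). The soma centre sits on integer voxel
#' coordinates, so with zero noise the brightest voxel equals
#' `background_level + soma_amplitude` exactly.
#'
#' @param shape `(z, y, x)` stack dimensions.
#' @param background_level Uniform background intensity.
#' @param soma_amplitude Peak soma intensity above background.
#' @param soma_sigma Soma Gaussian sigma in pixels.
#' @param noise_sd Additive Gaussian noise SD.
#' @param center Optional `(z, y, x)` soma centre; by default drawn uniformly
#'   from the central region, at least `3 * soma_sigma + 1` pixels from the
#'   y/x borders.
#' @param seed Integer seed.
#' @return List with `stack` (3-D array) and `truth` (list: `amplitude`,
#'   `center`, `sigma`, `background`).
#' @export
sim_image_stack <- function(shape = c(12, 48, 48), background_level = 100,
                            soma_amplitude = 500, soma_sigma = 3,
                            noise_sd = 5, center = NULL, seed = 1) {
  if (any(shape < 1)) stop("stack dimensions must be >= 1", call. = FALSE)
  if (background_level < 0 || soma_amplitude < 0 || noise_sd < 0) {
    stop("intensity levels must be >= 0", call. = FALSE)
  }
  margin <- ceiling(3 * soma_sigma) + 1
  if (!is.null(center)) {
    if (any(center < 1) || any(center > shape)) {
      stop("soma centre outside the stack", call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    if (is.null(center)) {
      if (2 * margin >= shape[2] || 2 * margin >= shape[3]) {
        stop("stack too small for the soma at this sigma", call. = FALSE)
      }
      center <- c(sample(seq(max(1, shape[1] %/% 3), min(shape[1], shape[1] - shape[1] %/% 3 + 1)), 1),
                  sample(seq(margin, shape[2] - margin), 1),
                  sample(seq(margin, shape[3] - margin), 1))
    }
    z <- seq_len(shape[1]); y <- seq_len(shape[2]); x <- seq_len(shape[3])
    gz <- exp(-(z - center[1])^2 / (2 * soma_sigma^2))
    gy <- exp(-(y - center[2])^2 / (2 * soma_sigma^2))
    gx <- exp(-(x - center[3])^2 / (2 * soma_sigma^2))
    soma <- soma_amplitude * outer(gz, outer(gy, gx))
    stack <- background_level + array(soma, dim = shape)
    if (noise_sd > 0) {
      stack <- stack + array(stats::rnorm(prod(shape), 0, noise_sd), dim = shape)
    }
    stack <- pmax(stack, 0)
    list(stack = stack,
         truth = list(amplitude = soma_amplitude, center = center,
                      sigma = soma_sigma, background = background_level))
  })
}

#' Double-exponential transient kernel, unit peak
#'
#' `(exp(-t/decay) - exp(-t/rise))`, normalized so the maximum over
#' continuous time equals 1; zero for `t < 0`. With unit-peak normalization a
#' planted transient's amplitude is directly comparable to the detected
#' dF/F0 peak amplitude, up to sampling of the peak.
#'
#' @param t Time since transient onset (seconds; vectorized).
#' @param rise_tau,decay_tau Rise and decay time constants (s),
#'   `decay_tau > rise_tau > 0`.
#' @return Kernel values in \[0, 1\].
#' @export
transient_kernel <- function(t, rise_tau = 0.5, decay_tau = 2) {
  if (!(decay_tau > rise_tau && rise_tau > 0)) {
    stop("require decay_tau > rise_tau > 0", call. = FALSE)
  }
  t_peak <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  norm <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  out <- (exp(-t / decay_tau) - exp(-t / rise_tau)) / norm
  out[t < 0] <- 0
  out
}

#' Describe a planted calcium transient
#'
#' @param onset_time Onset in seconds (see `onsets_relative_to_encounter` in
#'   [sim_gcamp_recording()]).
#' @param amplitude Peak amplitude in dF/F0 units (>= 0).
#' @param rise_tau,decay_tau Kernel time constants (s).
#' @return One-row tibble.
#' @export
transient <- function(onset_time, amplitude, rise_tau = 0.5, decay_tau = 2) {
  if (any(amplitude < 0)) stop("amplitude must be >= 0", call. = FALSE)
  if (any(!(decay_tau > rise_tau & rise_tau > 0))) {
    stop("require decay_tau > rise_tau > 0", call. = FALSE)
  }
  tibble::tibble(onset_time = onset_time, amplitude = amplitude,
                 rise_tau = rise_tau, decay_tau = decay_tau)
}

#' Simulate a freely-moving (or stationary) GCaMP recording
#'
#' Neuron fluorescence is
#' `background + baseline * (1 + sum of transient kernels) + noise`, with the
#' background channel `background + noise`, so background subtraction leaves
#' `baseline * (1 + sum of kernels)` plus noise and the planted amplitudes
#' are recoverable as dF/F0 peak heights. In `approach_lawn` mode the
#' trajectory is a biased random walk toward the lawn centre with fixed step
#' length; the radial component of every step is positive while outside the
#' lawn, so the boundary is crossed exactly once, at the recorded encounter
#' frame. Inside the lawn the walk continues toward the centre and then
#' wanders without leaving the inner 80% of the radius. In `stationary` mode
#' the animal sits `start_distance` mm outside the boundary.
#'
#' @param duration Recording length in seconds.
#' @param frame_rate Frames per second (default 10).
#' @param transients Tibble of planted transients (rows from [transient()]);
#'   may be empty.
#' @param baseline Neuron fluorescence above background at rest.
#' @param background Shared background fluorescence level.
#' @param trajectory_mode `"approach_lawn"` or `"stationary"`.
#' @param lawn Lawn geometry `list(center = c(x, y), radius = r)` (mm).
#' @param noise_sd Additive Gaussian noise SD (both channels, independent).
#' @param start_distance Start distance outside the lawn boundary (mm).
#' @param step_length Walk step length per frame (mm; default 0.02 = 0.2 mm/s
#'   at 10 fps).
#' @param heading_jitter Max deviation (radians) of each step from the
#'   to-centre heading while approaching.
#' @param onsets_relative_to_encounter Interpret transient onsets as seconds
#'   relative to the lawn encounter instead of absolute time.
#' @param seed Integer seed.
#' @return List with `rec` (a [recording()]) and `truth` (list: `transients`
#'   with absolute onsets and expected peak times, `encounter_frame`,
#'   `encounter_time`, `baseline`, `background`).
#' @export
sim_gcamp_recording <- function(duration = 120, frame_rate = 10,
                                transients = transient(numeric(0), numeric(0)),
                                baseline = 100, background = 50,
                                trajectory_mode = c("approach_lawn", "stationary"),
                                lawn = list(center = c(0, 0), radius = 2),
                                noise_sd = 3, start_distance = 1.5,
                                step_length = 0.02, heading_jitter = pi / 3,
                                onsets_relative_to_encounter = FALSE,
                                seed = 1) {
  trajectory_mode <- match.arg(trajectory_mode)
  if (frame_rate <= 0) stop("frame_rate must be positive", call. = FALSE)
  if (baseline <= 0) stop("baseline must be positive", call. = FALSE)
  n <- floor(duration * frame_rate)
  time <- (seq_len(n) - 1) / frame_rate
  withr::with_seed(seed, {
    # trajectory first, so transient onsets can be tied to the encounter
    cx <- lawn$center[1]; cy <- lawn$center[2]; R <- lawn$radius
    start_angle <- stats::runif(1, 0, 2 * pi)
    x <- numeric(n); y <- numeric(n)
    x[1] <- cx + (R + start_distance) * cos(start_angle)
    y[1] <- cy + (R + start_distance) * sin(start_angle)
    if (trajectory_mode == "stationary") {
      x[] <- x[1]; y[] <- y[1]
      encounter_frame <- NA_integer_
    } else {
      for (i in 2:n) {
        r <- sqrt((x[i - 1] - cx)^2 + (y[i - 1] - cy)^2)
        to_center <- atan2(cy - y[i - 1], cx - x[i - 1])
        if (r > 0.5 * R) {
          heading <- to_center + stats::runif(1, -heading_jitter, heading_jitter)
        } else {
          heading <- stats::runif(1, 0, 2 * pi)
        }
        nx <- x[i - 1] + step_length * cos(heading)
        ny <- y[i - 1] + step_length * sin(heading)
        if (sqrt((nx - cx)^2 + (ny - cy)^2) > 0.8 * R && r <= 0.5 * R) {
          # wandering step would leave the inner zone: step toward centre
          nx <- x[i - 1] + step_length * cos(to_center)
          ny <- y[i - 1] + step_length * sin(to_center)
        }
        x[i] <- nx; y[i] <- ny
      }
      dist <- sqrt((x - cx)^2 + (y - cy)^2) - R
      encounter_frame <- which(dist <= 0)[1]
    }
    transients <- tibble::as_tibble(transients)
    if (nrow(transients)) {
      onset_abs <- transients$onset_time
      if (onsets_relative_to_encounter) {
        if (is.na(encounter_frame)) {
          stop("no encounter in this mode; absolute onsets required",
               call. = FALSE)
        }
        onset_abs <- onset_abs + time[encounter_frame]
      }
      if (any(onset_abs < 0 | onset_abs > duration)) {
        stop("transient onset outside the recording", call. = FALSE)
      }
      transients$onset_time <- onset_abs
      t_peak <- log(transients$decay_tau / transients$rise_tau) *
        transients$rise_tau * transients$decay_tau /
        (transients$decay_tau - transients$rise_tau)
      transients$peak_time <- onset_abs + t_peak
    } else {
      transients$peak_time <- numeric(0)
    }
    activity <- rep(0, n)
    for (j in seq_len(nrow(transients))) {
      activity <- activity + transients$amplitude[j] *
        transient_kernel(time - transients$onset_time[j],
                         transients$rise_tau[j], transients$decay_tau[j])
    }
    f_neuron <- background + baseline * (1 + activity)
    f_background <- rep(background, n)
    if (noise_sd > 0) {
      f_neuron <- f_neuron + stats::rnorm(n, 0, noise_sd)
      f_background <- f_background + stats::rnorm(n, 0, noise_sd)
    }
    rec <- recording(time, f_neuron, f_background, x = x, y = y, lawn = lawn,
                     encounter_frame = encounter_frame)
    list(rec = rec,
         truth = list(transients = transients,
                      encounter_frame = encounter_frame,
                      encounter_time = if (is.na(encounter_frame)) NA_real_
                        else time[encounter_frame],
                      baseline = baseline, background = background))
  })
}

#' Simulate endpoint behavioral assay counts
#'
#' Draws per-plate multinomial counts whose expected computed index equals
#' `true_index`. For chemotaxis the per-animal probabilities are
#' `p_odor = (1 - other_prob + theta) / 2`, `p_control = (1 - other_prob - theta) / 2`,
#' so `E[(n_odor - n_control)/n] = theta` exactly. For food choice the
#' experimental/control split among patch animals is Binomial(`theta`), so the
#' index is conditionally unbiased.
#'
#' @param assay `"chemotaxis"` or `"food_choice"`.
#' @param true_index Target index: in \[-1, 1\] for chemotaxis (and
#'   `|theta| <= 1 - other_prob` to keep probabilities valid), in \[0, 1\]
#'   for food choice.
#' @param n_animals Animals per plate.
#' @param n_plates Number of plates.
#' @param other_prob Probability an animal ends up outside the scored spots
#'   (chemotaxis) or outside both patches (food choice).
#' @param seed Integer seed.
#' @return Tibble: `plate_id`, `n_odor`/`n_exp`, `n_control`, `n_other`.
#' @export
sim_assay_counts <- function(assay = c("chemotaxis", "food_choice"),
                             true_index, n_animals = 100, n_plates = 10,
                             other_prob = 0.1, seed = 1) {
  assay <- match.arg(assay)
  if (other_prob < 0 || other_prob >= 1) {
    stop("other_prob must lie in [0, 1)", call. = FALSE)
  }
  if (assay == "chemotaxis") {
    if (abs(true_index) > 1) stop("chemotaxis index must lie in [-1, 1]",
                                  call. = FALSE)
    if (abs(true_index) > 1 - other_prob) {
      stop("|true_index| cannot exceed 1 - other_prob", call. = FALSE)
    }
    probs <- c((1 - other_prob + true_index) / 2,
               (1 - other_prob - true_index) / 2,
               other_prob)
  } else {
    if (true_index < 0 || true_index > 1) {
      stop("food-choice index must lie in [0, 1]", call. = FALSE)
    }
    probs <- c(true_index * (1 - other_prob),
               (1 - true_index) * (1 - other_prob),
               other_prob)
  }
  withr::with_seed(seed, {
    draws <- stats::rmultinom(n_plates, n_animals, probs)
    counts <- tibble::tibble(
      plate_id = sprintf("plate%03d", seq_len(n_plates)),
      n_control = draws[2, ],
      n_other = draws[3, ]
    )
    if (assay == "chemotaxis") {
      counts$n_odor <- draws[1, ]
      counts <- counts[, c("plate_id", "n_odor", "n_control", "n_other")]
    } else {
      counts$n_exp <- draws[1, ]
      counts <- counts[, c("plate_id", "n_exp", "n_control", "n_other")]
    }
    counts
  })
}
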