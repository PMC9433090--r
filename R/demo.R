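#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one serializable list, at the
#' printed defaults of the original assays: fourfold regulation cutoff, 5%
#' reporter tails, 10-frame (1 s) moving median, 5th-percentile baseline,
#' 0.5 mm distance bins, 3.5 mm exploration squares. Unknown keys passed via
#' `...` are an error, so configuration drift fails fast.
#'
#' @param ... Overrides for any listed field.
#' @return Named list of class `pipeline_config`.
#' @export
demo_config <- function(...) {
  cfg <- list(
    schema_version = 1L,
    de_threshold = 4,
    de_pseudocount = 0.5,
    family_label = "chemoreceptor",
    atlas_alpha = 0.05,
    reporter_tail_percent = 5,
    reporter_control_group = "fed_WT",
    reporter_box_halfwidth = 9L,
    calcium_window = 10L,
    calcium_baseline_percentile = 5,
    calcium_bin_width = 0.5,
    peak_min_amplitude = 0.2,
    peak_min_separation = 2,
    behavior_square_mm = 3.5,
    plate_diameter = 60,
    n_expression_genes = 1000,
    n_replicates = 3,
    noise_cv = 0.05
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  # polynomial rolling hash of the deparsed config; a stable fingerprint,
  # not a crypto hash
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full synthetic-data demonstration pipeline
#'
#' Generates one fixture of every input class with planted ground truth, runs
#' each analysis stage on it, and writes a machine-readable `results.json`
#' plus per-stage tables under `out_dir`. The whole run is a deterministic
#' function of `(config, seed)`: sub-seeds for each stage are derived from
#' the master seed with [derive_seed()].
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param config Configuration from [demo_config()].
#' @return The results list, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1, config = demo_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list(
    meta = list(package_version = as.character(utils::packageVersion("olfstate")),
                seed = seed, config_hash = config_hash(config),
                config = unclass(config))
  )

  run_stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    out
  }

  # -- differential expression and enrichment -------------------------------
  results$enrichment <- run_stage("enrichment", function() {
    sim <- sim_expression_table(
      n_genes = config$n_expression_genes, n_up_chemo = 20, n_up_other = 10,
      noise_cv = config$noise_cv, n_replicates = config$n_replicates,
      seed = derive_seed(seed, 1)
    )
    write_expression_tsv(sim$table, file.path(out_dir, "expression.tsv"))
    fc <- compute_fold_changes(sim$table, pseudocount = config$de_pseudocount)
    sets <- select_regulated(fc, threshold = config$de_threshold)
    fam <- family_enrichment_test(sets, config$family_label, sim$table)
    planted_up <- sim$truth$gene_id[sim$truth$true_ratio > 1]
    up_chemo <- intersect(sets$upregulated,
                          sim$truth$gene_id[sim$truth$family == "chemoreceptor"])
    chemo_genes <- sim$truth$gene_id[sim$truth$family == "chemoreceptor"]
    atlas <- sim_neuron_atlas(chemo_genes, planted_neuron = "AWA",
                              planted_excess = 5, target_genes = up_chemo,
                              seed = derive_seed(seed, 2))
    write_atlas_tsv(atlas, file.path(out_dir, "atlas.tsv"))
    ne <- neuron_enrichment(up_chemo, chemo_genes, atlas,
                            alpha = config$atlas_alpha)
    readr::write_tsv(ne, file.path(out_dir, "neuron_enrichment.tsv"))
    writeLines(sets$upregulated, file.path(out_dir, "upregulated_genes.txt"))
    list(n_up = length(sets$upregulated), n_down = length(sets$downregulated),
         planted_recovered = setequal(sets$upregulated, planted_up),
         family_odds_ratio = fam$odds_ratio, family_p = fam$p,
         significant_neurons = ne$neuron[ne$significant])
  })

  # -- reporter quantification ----------------------------------------------
  results$reporter <- run_stage("reporter", function() {
    groups <- rep(c("fed_WT", "fasted"), each = 4)
    sessions <- rep(c("s1", "s2"), times = 4)
    amplitude <- ifelse(groups == "fed_WT", 500, 2500)
    scores <- do.call(rbind, lapply(seq_along(groups), function(i) {
      sim <- sim_image_stack(soma_amplitude = amplitude[i],
                             seed = derive_seed(seed, 10 + i))
      tibble::tibble(sample = sprintf("worm%02d", i),
                     session_id = sessions[i], group = groups[i],
                     raw = score_stack(sim$stack,
                                       box_halfwidth = config$reporter_box_halfwidth,
                                       tail_percent = config$reporter_tail_percent)$score)
    }))
    scores <- normalize_by_control(scores, config$reporter_control_group)
    readr::write_csv(scores, file.path(out_dir, "reporter_scores.csv"))
    cmp <- compare_conditions(scores, list(c("fasted", "fed_WT")))
    readr::write_csv(cmp, file.path(out_dir, "reporter_comparisons.csv"))
    list(mean_normalized_fasted = mean(scores$normalized[scores$group == "fasted"]),
         p_adj = cmp$p_adj)
  })

  # -- calcium, freely moving ------------------------------------------------
  results$calcium <- run_stage("calcium", function() {
    make_animal <- function(i, amp) {
      tr <- rbind(transient(-5, amp), transient(5, amp), transient(20, amp))
      sim <- sim_gcamp_recording(duration = 60, transients = tr,
                                 onsets_relative_to_encounter = TRUE,
                                 start_distance = 1.2,
                                 seed = derive_seed(seed, 100 + i))
      dff <- compute_dff(sim$rec, window = config$calcium_window,
                         baseline_percentile = config$calcium_baseline_percentile)
      dist <- distance_to_lawn(dff$x, dff$y, dff$lawn)
      bins <- bin_dff_by_distance(dff$dff, dist,
                                  bin_width = config$calcium_bin_width)
      list(dff = dff, bins = bins)
    }
    animals <- lapply(1:8, function(i) {
      state <- if (i <= 4) "fed" else "fasted"
      amp <- if (state == "fed") 0.75 else 1.5
      out <- make_animal(i, amp)
      occupied <- out$bins[out$bins$n > 0, ]
      tibble::tibble(animal = sprintf("a%02d", i), state = state,
                     bin = occupied$bin_lo, dff = occupied$mean)
    })
    binned <- do.call(rbind, animals)
    # restrict to bins every animal visited so the two-way design is complete
    full_bins <- names(which(table(binned$bin) == 8))
    binned <- binned[binned$bin %in% full_bins, ]
    an <- state_effect_anova(binned)
    readr::write_csv(binned, file.path(out_dir, "calcium_binned.csv"))
    readr::write_csv(an, file.path(out_dir, "calcium_anova.csv"))
    # microfluidic path on a 30 s stationary trial
    tr <- transient(6, 1.0)
    sim <- sim_gcamp_recording(duration = 30, transients = tr,
                               trajectory_mode = "stationary", noise_sd = 1,
                               seed = derive_seed(seed, 200))
    epochs <- microfluidic_percent_change(subtract_background(sim$rec),
                                          sim$rec$time)
    list(anova_state_p = an$p[an$term == "state"],
         stim_max_percent = epochs$stim_max, pre_max_percent = epochs$pre_max)
  })

  # -- behavior --------------------------------------------------------------
  results$behavior <- run_stage("behavior", function() {
    ct <- sim_assay_counts("chemotaxis", true_index = 0.6, n_plates = 10,
                           seed = derive_seed(seed, 300))
    fc <- sim_assay_counts("food_choice", true_index = 0.75, n_plates = 10,
                           seed = derive_seed(seed, 301))
    write_counts_csv(ct, file.path(out_dir, "chemotaxis_counts.csv"))
    write_counts_csv(fc, file.path(out_dir, "food_choice_counts.csv"))
    ci <- chemotaxis_index(ct$n_odor, ct$n_control, ct$n_other)
    fci <- food_choice_index(fc$n_exp, fc$n_control)
    list(ci_mean = index_summary(ci)$mean, fci_mean = index_summary(fci)$mean)
  })

  write_truth_json(results, file.path(out_dir, "results.json"))
  invisible(results)
}
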