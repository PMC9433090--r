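make_table <- function(fed, fasted, family = NULL) {
  genes <- names(fed)
  if (is.null(family)) family <- setNames(rep("other", length(genes)), genes)
  do.call(rbind, lapply(genes, function(g) {
    tibble::tibble(
      gene_id = g, family = family[[g]],
      condition = rep(c("fed", "fasted"), c(length(fed[[g]]), length(fasted[[g]]))),
      replicate = c(seq_along(fed[[g]]), seq_along(fasted[[g]])),
      abundance = c(fed[[g]], fasted[[g]])
    )
  }))
}

test_that("fold changes follow the pseudocounted ratio of condition means", {
  tab <- make_table(fed = list(a = 10, b = 5, c = 0),
                    fasted = list(a = 50, b = 5, c = 9))
  fc0 <- compute_fold_changes(tab, pseudocount = 0)
  expect_equal(fc0$ratio[fc0$gene_id == "a"], 5)
  expect_equal(fc0$ratio[fc0$gene_id == "b"], 1)

  fc1 <- compute_fold_changes(tab, pseudocount = 1)
  expect_equal(fc1$ratio[fc1$gene_id == "c"], 10)

  # replicate averaging is arithmetic
  tab2 <- make_table(fed = list(a = c(8, 12)), fasted = list(a = c(30, 70)))
  expect_equal(compute_fold_changes(tab2, pseudocount = 0)$ratio, 5)

  missing <- tab[tab$condition == "fed" | tab$gene_id != "a", ]
  expect_error(compute_fold_changes(missing), "missing a condition.*[abc]")
})

test_that("gene-set selection is strict at the threshold and order-invariant", {
  records <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                            ratio = c(5, 4, 0.2, 1))
  sets <- select_regulated(records, threshold = 4)
  expect_equal(sets$upregulated, "a")
  expect_equal(sets$downregulated, "c")

  shuffled <- select_regulated(records[c(3, 1, 4, 2), ], threshold = 4)
  expect_setequal(shuffled$upregulated, sets$upregulated)
  expect_setequal(shuffled$downregulated, sets$downregulated)
  expect_length(intersect(sets$upregulated, sets$downregulated), 0)

  empty <- select_regulated(records[0, ], threshold = 4)
  expect_length(empty$upregulated, 0)
  expect_length(empty$downregulated, 0)
  expect_error(select_regulated(records, threshold = 1), "> 1")
})

test_that("planted fold changes are recovered exactly at low noise", {
  sim <- sim_expression_table(n_genes = 400, n_up_chemo = 10, n_up_other = 5,
                              noise_cv = 0.05, n_replicates = 3, seed = 42)
  fc <- compute_fold_changes(sim$table)
  sets <- select_regulated(fc, threshold = 4)
  planted <- sim$truth$gene_id[sim$truth$true_ratio > 1]
  expect_setequal(sets$upregulated, planted)
  expect_length(sets$downregulated, 0)
})

test_that("family enrichment builds the right 2x2 table and one-sided p", {
  fam <- setNames(rep(c("chemoreceptor", "other"), c(3, 7)),
                  paste0("g", 1:10))
  tab <- make_table(fed = as.list(setNames(rep(10, 10), paste0("g", 1:10))),
                    fasted = as.list(setNames(c(rep(100, 4), rep(10, 6)),
                                              paste0("g", 1:10))),
                    family = fam)
  fc <- compute_fold_changes(tab, pseudocount = 0)
  sets <- select_regulated(fc, threshold = 4)  # g1..g4 upregulated
  res <- family_enrichment_test(sets, "chemoreceptor", tab)
  expect_equal(res$table, rbind(c(3, 1), c(0, 6)))
  expect_equal(res$p, oracle_fisher_p(res$table, "greater"), tolerance = 1e-10)

  # family absent from the set: no overrepresentation is possible
  no_fam <- fisher_exact_2x2(rbind(c(0, 100), c(50, 850)), "greater")
  expect_gt(no_fam$p, 0.999)

  empty_sets <- select_regulated(fc, threshold = 100)
  expect_warning(res_empty <- family_enrichment_test(empty_sets, "chemoreceptor", tab),
                 "empty")
  expect_equal(res_empty$p, 1)
})

test_that("per-neuron enrichment ratio, correction, and edge cases behave", {
  # consistent counts: neuron X expresses 12/20 upregulated and 20/100 family
  genes <- paste0("g", 1:100)
  up <- genes[1:20]
  atlas <- matrix(0L, 2, 100, dimnames = list(c("X", "Y"), genes))
  atlas["X", c(genes[1:12], genes[21:28])] <- 1L   # k = 12, m = 20
  atlas["Y", genes[21:24]] <- 1L                   # k = 0,  m = 4
  res <- neuron_enrichment(up, genes, atlas)
  rx <- res[res$neuron == "X", ]
  expect_equal(rx$ratio, (12 / 20) / (20 / 100))  # = 3
  expect_equal(rx$k, 12L)
  expect_equal(rx$m, 20L)
  expect_equal(res$p_adj, pmin(1, res$p_raw * 2))

  # proportional membership: ratio 1, p near 1
  atlas2 <- matrix(0L, 1, 100, dimnames = list("Z", genes))
  atlas2["Z", c(genes[1:4], genes[21:36])] <- 1L   # k/K = 4/20 = m/M = 20/100
  res2 <- neuron_enrichment(up, genes, atlas2)
  expect_equal(res2$ratio, 1)
  expect_gt(res2$p_raw, 0.99)
  expect_false(res2$significant)

  # neuron expressing no family gene is reported untested
  atlas3 <- rbind(atlas, none = 0L)
  rownames(atlas3) <- c("X", "Y", "none")
  res3 <- neuron_enrichment(up, genes, atlas3)
  expect_false(res3$tested[res3$neuron == "none"])
  expect_true(is.na(res3$ratio[res3$neuron == "none"]))
  # Bonferroni family size counts only tested neurons
  expect_equal(res3$p_adj[res3$tested], pmin(1, res3$p_raw[res3$tested] * 2))

  expect_error(neuron_enrichment(c("zz"), genes, atlas), "subset")
})

test_that("enrichment ratio is scale-free", {
  # doubling k, K, m, M leaves the ratio unchanged
  r1 <- (12 / 20) / (20 / 100)
  r2 <- (24 / 40) / (40 / 200)
  expect_equal(r1, r2)
})

test_that("the planted atlas neuron is detected and named", {
  fx <- atlas_fixture_genes()
  atlas <- sim_neuron_atlas(fx$genes, planted_neuron = "AWA",
                            planted_excess = 5, target_genes = fx$up,
                            seed = 7)
  res <- neuron_enrichment(fx$up, fx$genes, atlas)
  expect_true(res$significant[res$neuron == "AWA"])
  expect_gt(res$ratio[res$neuron == "AWA"], 1.5)
})
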