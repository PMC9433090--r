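#' Fold changes between fasted and fed conditions
#'
#' Computes, per gene, the ratio of mean fasted to mean fed abundance with a
#' pseudocount added to both means: `(mean_fasted + pc) / (mean_fed + pc)`.
#' Replicates are averaged arithmetically. The pseudocount keeps ratios finite
#' for genes undetected in one condition; at the default 0.5 it barely moves
#' well-expressed genes.
#'
#' @param table Expression table: a data frame with columns `gene_id`,
#'   `family`, `condition` (`"fed"` or `"fasted"`), `replicate`, `abundance`
#'   (non-negative).
#' @param pseudocount Non-negative value added to both condition means.
#' @return Tibble with one row per gene: `gene_id`, `family`, `fed_mean`,
#'   `fasted_mean`, `ratio`, `pseudocount`.
#' @examples
#' tab <- tibble::tibble(
#'   gene_id = rep(c("a", "b"), each = 2), family = "other",
#'   condition = rep(c("fed", "fasted"), 2), replicate = 1L,
#'   abundance = c(10, 50, 8, 8)
#' )
#' compute_fold_changes(tab, pseudocount = 0)
#' @export
compute_fold_changes <- function(table, pseudocount = 0.5) {
  table <- as.data.frame(table)
  req <- c("gene_id", "condition", "abundance")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop("expression table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (any(table$abundance < 0)) stop("abundances must be >= 0", call. = FALSE)
  bad_cond <- setdiff(unique(table$condition), c("fed", "fasted"))
  if (length(bad_cond)) {
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }
  genes <- unique(table$gene_id)
  fed <- table[table$condition == "fed", ]
  fasted <- table[table$condition == "fasted", ]
  missing_fed <- setdiff(genes, unique(fed$gene_id))
  missing_fasted <- setdiff(genes, unique(fasted$gene_id))
  if (length(missing_fed) || length(missing_fasted)) {
    stop("gene(s) missing a condition: ",
         paste(utils::head(c(missing_fed, missing_fasted), 5), collapse = ", "),
         call. = FALSE)
  }
  fed_mean <- tapply(fed$abundance, factor(fed$gene_id, levels = genes), mean)
  fasted_mean <- tapply(fasted$abundance, factor(fasted$gene_id, levels = genes), mean)
  fam <- if ("family" %in% names(table)) {
    table$family[match(genes, table$gene_id)]
  } else rep(NA_character_, length(genes))
  tibble::tibble(
    gene_id = genes,
    family = fam,
    fed_mean = as.numeric(fed_mean),
    fasted_mean = as.numeric(fasted_mean),
    ratio = (as.numeric(fasted_mean) + pseudocount) /
      (as.numeric(fed_mean) + pseudocount),
    pseudocount = pseudocount
  )
}

#' Select up- and downregulated gene sets by fold-change cutoff
#'
#' Genes whose fasted/fed ratio is strictly greater than `threshold` are
#' upregulated; strictly less than `1/threshold`, downregulated. Genes exactly
#' at the boundary are excluded ("more than"-fold regulation is strict).
#'
#' @param records Fold-change tibble from [compute_fold_changes()] (needs
#'   `gene_id` and `ratio`).
#' @param threshold Fold-change cutoff, > 1 (default 4).
#' @return List of class `gene_sets` with `upregulated`, `downregulated`
#'   (character vectors of gene ids) and `threshold`.
#' @export
select_regulated <- function(records, threshold = 4) {
  if (threshold <= 1) stop("threshold must be > 1", call. = FALSE)
  records <- as.data.frame(records)
  if (nrow(records) && any(records$ratio <= 0)) {
    stop("fold-change ratios must be positive", call. = FALSE)
  }
  up <- records$gene_id[records$ratio > threshold]
  down <- records$gene_id[records$ratio < 1 / threshold]
  structure(
    list(upregulated = as.character(up), downregulated = as.character(down),
         threshold = threshold),
    class = "gene_sets"
  )
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("Regulated gene sets (fold-change threshold ", x$threshold, ")\n",
      "  upregulated:   ", length(x$upregulated), " genes\n",
      "  downregulated: ", length(x$downregulated), " genes\n", sep = "")
  invisible(x)
}

#' Gene-family enrichment in a regulated set (Fisher exact test)
#'
#' Tests whether a gene family (e.g. chemoreceptors) is overrepresented among
#' the up- (or down-) regulated genes relative to the full detected-gene
#' universe, with a one-sided Fisher exact test. The 2x2 table is
#' `[in-set & family, in-set & not; out-of-set & family, out-of-set & not]`.
#'
#' @param sets `gene_sets` object from [select_regulated()].
#' @param family_label Family annotation to test (e.g. `"chemoreceptor"`).
#' @param universe Expression table (or any data frame with `gene_id` and
#'   `family`) defining the detected-gene universe.
#' @param direction Test the `"up"` or `"down"` set.
#' @return List with `odds_ratio`, `p` (one-sided, greater), `table` and the
#'   counts `k` (family in set) and `n_set`.
#' @export
family_enrichment_test <- function(sets, family_label, universe,
                                   direction = c("up", "down")) {
  direction <- match.arg(direction)
  universe <- as.data.frame(universe)
  ann <- unique(universe[, c("gene_id", "family")])
  if (!family_label %in% ann$family) {
    stop("family '", family_label, "' absent from universe annotations",
         call. = FALSE)
  }
  set_genes <- if (direction == "up") sets$upregulated else sets$downregulated
  in_set <- ann$gene_id %in% set_genes
  in_fam <- ann$family == family_label
  tab <- rbind(
    c(sum(in_set & in_fam), sum(in_set & !in_fam)),
    c(sum(!in_set & in_fam), sum(!in_set & !in_fam))
  )
  if (sum(tab[1, ]) == 0) {
    warning("empty ", direction, "regulated set; enrichment undefined (p = 1)",
            call. = FALSE)
    return(list(odds_ratio = NA_real_, p = 1, table = tab,
                k = 0L, n_set = 0L))
  }
  fit <- fisher_exact_2x2(tab, alternative = "greater")
  list(odds_ratio = fit$odds_ratio, p = fit$p, table = tab,
       k = tab[1, 1], n_set = sum(tab[1, ]))
}

#' Per-neuron enrichment of upregulated family genes against an atlas
#'
#' For each neuron in a binary neuron x gene expression atlas, compares the
#' fraction of upregulated family genes it expresses (`k/K`) with the fraction
#' of all family genes it expresses (`m/M`). The enrichment ratio is
#' `(k/K)/(m/M)`; its null is 1 if upregulation is uniform over the family.
#' Each neuron is tested on the 2x2 table
#' `[k, K-k; m-k, (M-K)-(m-k)]` (upregulated vs not x expressed vs not, within
#' the family) with a chi-squared test (no continuity correction), falling
#' back to Fisher exact when any expected count is below 5. P-values are
#' Bonferroni-corrected over the neurons actually tested (those with `m > 0`),
#' and a neuron is flagged significant when `p_adj < alpha` *and* its ratio
#' exceeds 1 (the claim is enrichment, not depletion).
#'
#' @param up_family_genes Character vector: upregulated genes of the family.
#' @param family_genes Character vector: all family genes in the universe;
#'   must contain `up_family_genes` and be covered by the atlas columns.
#' @param atlas Binary matrix, neurons in rows, genes in columns (dimnames
#'   required), as produced by [sim_neuron_atlas()] or [read_atlas_tsv()].
#' @param alpha Significance level applied after Bonferroni correction.
#' @param correct Yates continuity correction for the chi-squared test.
#' @return Tibble with one row per neuron: `neuron`, `k`, `K`, `m`, `M`,
#'   `ratio`, `p_raw`, `p_adj`, `method`, `tested`, `significant`.
#' @export
neuron_enrichment <- function(up_family_genes, family_genes, atlas,
                              alpha = 0.05, correct = FALSE) {
  if (!all(up_family_genes %in% family_genes)) {
    stop("up_family_genes must be a subset of family_genes", call. = FALSE)
  }
  if (is.null(rownames(atlas)) || is.null(colnames(atlas))) {
    stop("atlas needs neuron row names and gene column names", call. = FALSE)
  }
  missing_genes <- setdiff(family_genes, colnames(atlas))
  if (length(missing_genes)) {
    stop("atlas does not cover ", length(missing_genes), " family gene(s)",
         call. = FALSE)
  }
  K <- length(unique(up_family_genes))
  M <- length(unique(family_genes))
  up <- unique(up_family_genes)
  fam <- unique(family_genes)
  neurons <- rownames(atlas)
  k <- as.integer(rowSums(atlas[, up, drop = FALSE] > 0))
  m <- as.integer(rowSums(atlas[, fam, drop = FALSE] > 0))
  tested <- m > 0
  n_tested <- sum(tested)
  p_raw <- rep(NA_real_, length(neurons))
  method <- rep(NA_character_, length(neurons))
  for (i in seq_along(neurons)) {
    if (!tested[i]) next
    tab <- rbind(c(k[i], K - k[i]), c(m[i] - k[i], (M - K) - (m[i] - k[i])))
    res <- suppressWarnings(chi_squared_2x2(tab, correct = correct))
    p_raw[i] <- res$p
    method[i] <- res$method
  }
  ratio <- ifelse(tested, (k / K) / (m / M), NA_real_)
  p_adj <- ifelse(tested, pmin(1, p_raw * n_tested), NA_real_)
  tibble::tibble(
    neuron = neurons, k = k, K = K, m = m, M = M,
    ratio = ratio, p_raw = p_raw, p_adj = p_adj, method = method,
    tested = tested,
    significant = tested & !is.na(p_adj) & p_adj < alpha & ratio > 1
  )
}
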