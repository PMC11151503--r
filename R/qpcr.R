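#' Simulate a qPCR Ct table
#'
#' Generates cycle-threshold (Ct) replicates for target genes across
#' conditions such that the expected fold change of each gene versus the
#' baseline condition (computed by the 2^-ddCt method with the housekeeping
#' gene) equals the programmed `true_fold_changes`: the target Ct is lowered
#' by `log2(fold)` cycles in the non-baseline condition while the
#' housekeeping Ct stays flat.
#'
#' @param genes character vector of gene names (must include
#'   `housekeeping`).
#' @param conditions character vector of condition tags; the first is the
#'   baseline unless `baseline` says otherwise.
#' @param true_fold_changes named numeric vector (gene -> fold change in the
#'   non-baseline condition) or named list of per-condition named vectors.
#'   Fold changes must be > 0; genes not named get fold 1.
#' @param ct_noise_sd Gaussian noise on each Ct replicate (cycles).
#' @param seed integer seed.
#' @param n_replicates replicates per (condition, gene).
#' @param housekeeping housekeeping gene (default `"ACTB"`).
#' @param baseline baseline condition tag.
#' @param base_ct_target,base_ct_housekeeping baseline mean Ct values.
#' @return a `ct_table`: data frame with `sample_id`, `condition`, `gene`,
#'   `ct`; the housekeeping gene is recorded as an attribute.
#' @export
simulate_ct_table <- function(genes, conditions, true_fold_changes = NULL,
                              ct_noise_sd = 0, seed = NULL,
                              n_replicates = 3, housekeeping = "ACTB",
                              baseline = conditions[1],
                              base_ct_target = 25, base_ct_housekeeping = 20) {
  if (!housekeeping %in% genes) {
    stop(sprintf("housekeeping gene '%s' missing from genes", housekeeping),
         call. = FALSE)
  }
  fold_for <- function(gene, condition) {
    if (condition == baseline || gene == housekeeping) return(1)
    f <- if (is.list(true_fold_changes)) {
      (true_fold_changes[[condition]] %||% c())[gene]
    } else {
      true_fold_changes[gene]
    }
    f <- unname(f)
    if (length(f) == 0 || is.na(f)) 1 else f
  }
  for (cond in conditions) for (g in genes) {
    if (fold_for(g, cond) <= 0) stop_field("true_fold_changes", "must be > 0")
  }
  rows <- with_seed(seed, {
    out <- list()
    for (cond in conditions) for (g in genes) {
      mean_ct <- if (g == housekeeping) base_ct_housekeeping else {
        base_ct_target - log2(fold_for(g, cond))
      }
      ct <- mean_ct + stats::rnorm(n_replicates, 0, ct_noise_sd)
      out[[length(out) + 1]] <- data.frame(
        sample_id = paste0(cond, "_", seq_len(n_replicates)),
        condition = cond, gene = g, ct = ct)
    }
    do.call(rbind, out)
  })
  structure(rows, housekeeping_gene = housekeeping,
            class = c("ct_table", "data.frame"))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_housekeeping`; per gene and condition,
#' `ddCt = mean dCt(condition) - mean dCt(baseline)` and the fold change is
#' `2^-ddCt` (condition-mean convention). Per-sample fold changes
#' `2^-(dCt - mean dCt baseline)` are also emitted for dispersion estimates.
#' Samples missing the housekeeping gene are dropped with a warning.
#'
#' @param table a `ct_table` (data frame with `sample_id`, `condition`,
#'   `gene`, `ct`).
#' @param baseline_condition baseline condition tag.
#' @param housekeeping housekeeping gene; defaults to the table attribute or
#'   `"ACTB"`.
#' @return list with `per_gene` (gene, condition, ddct, fold_change, n) and
#'   `per_sample` (sample-level fold changes).
#' @export
ddct_fold_change <- function(table, baseline_condition, housekeeping = NULL) {
  housekeeping <- housekeeping %||% attr(table, "housekeeping_gene") %||% "ACTB"
  if (!baseline_condition %in% table$condition) {
    stop(sprintf("baseline condition '%s' not present", baseline_condition),
         call. = FALSE)
  }
  if (!housekeeping %in% table$gene) {
    stop(sprintf("housekeeping gene '%s' not present", housekeeping),
         call. = FALSE)
  }
  # mean housekeeping Ct per sample (technical replicates averaged)
  hk <- table[table$gene == housekeeping, ]
  hk_mean <- tapply(hk$ct, hk$sample_id, mean)
  targets <- table[table$gene != housekeeping, ]
  has_hk <- targets$sample_id %in% names(hk_mean)
  if (!all(has_hk)) {
    warning(sprintf("dropping sample(s) without housekeeping Ct: %s",
                    paste(unique(targets$sample_id[!has_hk]), collapse = ",")),
            call. = FALSE)
    targets <- targets[has_hk, ]
  }
  targets$dct <- targets$ct - as.numeric(hk_mean[targets$sample_id])
  agg <- stats::aggregate(dct ~ gene + condition, data = targets, FUN = mean)
  nrep <- stats::aggregate(dct ~ gene + condition, data = targets, FUN = length)
  base <- agg[agg$condition == baseline_condition, c("gene", "dct")]
  names(base)[2] <- "dct_baseline"
  per_gene <- merge(agg, base, by = "gene")
  per_gene$ddct <- per_gene$dct - per_gene$dct_baseline
  per_gene$fold_change <- 2^(-per_gene$ddct)
  per_gene$n <- nrep$dct[match(paste(per_gene$gene, per_gene$condition),
                               paste(nrep$gene, nrep$condition))]
  per_sample <- targets
  base_mean <- base$dct_baseline[match(per_sample$gene, base$gene)]
  per_sample$fold_change <- 2^(-(per_sample$dct - base_mean))
  list(per_gene = per_gene[order(per_gene$gene, per_gene$condition),
                           c("gene", "condition", "ddct", "fold_change", "n")],
       per_sample = per_sample[, c("sample_id", "condition", "gene", "dct",
                                   "fold_change")])
}
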