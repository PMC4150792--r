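#' Log2 fold change between mutant and wild type
#'
#' Positive values denote up-regulation in the mutant relative to the wild
#' type, negative values down-regulation.
#'
#' @param mut,wt strictly positive hybridization intensities (vectorized).
#' @return `log2(mut / wt)`.
#' @examples
#' log2_fold_change(32, 1)  # 5
#' @export
log2_fold_change <- function(mut, wt) {
  if (any(mut <= 0) || any(wt <= 0))
    stop("intensities must be strictly positive", call. = FALSE)
  log2(mut / wt)
}

# Resolve a log2 fold-change column from an expression table that carries
# either `log2fc` or raw `wt`/`mut` intensities.
table_log2fc <- function(records) {
  stopifnot(is.data.frame(records))
  if ("log2fc" %in% names(records)) return(records$log2fc)
  if (all(c("wt", "mut") %in% names(records)))
    return(log2_fold_change(records$mut, records$wt))
  stop("expression table needs a 'log2fc' column or 'wt' and 'mut' columns",
       call. = FALSE)
}

fold_cutoff <- function(fold_threshold, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  # "5-fold (log2) or more" is read as a 5-fold change reported on the
  # log2 scale, i.e. |log2fc| >= log2(5); scale = "log2" instead treats
  # the threshold as a log2 cutoff directly.
  if (scale == "linear") log2(fold_threshold) else fold_threshold
}

#' Count fold-change-affected genes
#'
#' Counts genes whose expression changed `fold_threshold`-fold or more
#' (|log2 fold change| >= log2(`fold_threshold`) under the default linear
#' reading), split into up- and down-regulated.
#'
#' @param records expression table (data frame) with a `log2fc` column or
#'   `wt`/`mut` intensity columns; must be non-empty.
#' @param fold_threshold fold-change threshold (default 5).
#' @param scale `"linear"` (threshold is a fold change) or `"log2"`
#'   (threshold is already a log2 cutoff).
#' @return A list with `up`, `down` and `total` counts.
#' @examples
#' tab <- data.frame(gene_id = c("a", "b"), log2fc = c(3, -0.1))
#' count_affected(tab)
#' @export
count_affected <- function(records, fold_threshold = 5,
                           scale = c("linear", "log2")) {
  if (nrow(records) == 0L) stop("records must be non-empty", call. = FALSE)
  fc <- table_log2fc(records)
  cut <- fold_cutoff(fold_threshold, scale)
  list(up = sum(fc >= cut), down = sum(fc <= -cut),
       total = sum(abs(fc) >= cut))
}

#' Average expression replicates
#'
#' Combines replicate expression tables (e.g. two independent mutants of
#' the same binding site) by the arithmetic mean of their log2 fold
#' changes per gene.
#'
#' @param ... two or more expression tables with `gene_id` and `log2fc`
#'   (or `wt`/`mut`) columns.
#' @return A data frame with `gene_id` and mean `log2fc`.
#' @export
combine_replicates <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  long <- do.call(rbind, lapply(tabs, function(t)
    data.frame(gene_id = t$gene_id, log2fc = table_log2fc(t))))
  out <- aggregate(log2fc ~ gene_id, data = long, FUN = mean)
  out[order(out$gene_id), , drop = FALSE]
}

#' Overlay classification of PBS- versus SBS-affected genes
#'
#' Overlays fold changes observed with primary-binding-site (PBS) mutants
#' onto those observed with secondary-binding-site (SBS) mutants for the
#' shared gene universe, and classifies each gene by where it crosses the
#' fold-change threshold: `sbs_only` genes are affected by SBS but not by
#' PBS mutants (the signature of terminators that do not need robust rut
#' recognition), and so on.
#'
#' @param records_pbs,records_sbs expression tables with `gene_id` and
#'   `log2fc` (or `wt`/`mut`) columns; the intersection of their gene sets
#'   must be non-empty (mismatches are dropped and counted).
#' @inheritParams count_affected
#' @return A data frame of class `"overlay_classes"` with `gene_id`,
#'   `log2fc_pbs`, `log2fc_sbs` and `class` (one of `sbs_only`,
#'   `pbs_and_sbs`, `pbs_only`, `neither`); the number of unmatched gene
#'   ids is recorded in the `"n_unmatched"` attribute.
#' @export
overlay_classify <- function(records_pbs, records_sbs, fold_threshold = 5,
                             scale = c("linear", "log2")) {
  fc_p <- data.frame(gene_id = records_pbs$gene_id,
                     log2fc_pbs = table_log2fc(records_pbs))
  fc_s <- data.frame(gene_id = records_sbs$gene_id,
                     log2fc_sbs = table_log2fc(records_sbs))
  m <- merge(fc_p, fc_s, by = "gene_id")
  if (nrow(m) == 0L)
    stop("empty intersection of gene ids between the two tables",
         call. = FALSE)
  n_unmatched <- (nrow(fc_p) - nrow(m)) + (nrow(fc_s) - nrow(m))
  cut <- fold_cutoff(fold_threshold, scale)
  hit_p <- abs(m$log2fc_pbs) >= cut
  hit_s <- abs(m$log2fc_sbs) >= cut
  m$class <- ifelse(hit_p & hit_s, "pbs_and_sbs",
             ifelse(hit_s, "sbs_only",
             ifelse(hit_p, "pbs_only", "neither")))
  attr(m, "n_unmatched") <- n_unmatched
  class(m) <- c("overlay_classes", "data.frame")
  m
}

#' Relative quantification by the 2^-ddCt method
#'
#' Computes the fold change of a target gene in a mutant relative to the
#' wild type from qPCR threshold cycles, normalized by an internal control
#' gene (rpoC-style): dCt = Ct(target) - Ct(control) within each strain,
#' ddCt = dCt(mutant) - dCt(WT), fold = 2^-ddCt. The internal control
#' cancels exactly, so equal target dCt values give a fold of 1 for any
#' control Cts.
#'
#' @param ct_target_mut,ct_control_mut,ct_target_wt,ct_control_wt
#'   threshold cycle values (finite, positive; vectorized).
#' @return Fold change(s), `2^-ddCt`.
#' @examples
#' ddct_fold_change(20, 15, 24, 15)  # 16
#' @export
ddct_fold_change <- function(ct_target_mut, ct_control_mut,
                             ct_target_wt, ct_control_wt) {
  cts <- list(ct_target_mut, ct_control_mut, ct_target_wt, ct_control_wt)
  for (ct in cts)
    if (any(!is.finite(ct)) || any(ct <= 0))
      stop("Ct values must be finite and positive", call. = FALSE)
  ddct <- (ct_target_mut - ct_control_mut) - (ct_target_wt - ct_control_wt)
  2^(-ddct)
}
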