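#' Configuration for the synthetic-data generators
#'
#' One seeded configuration object drives every generator, so each
#' synthetic data set is a pure function of its config (identical configs
#' give byte-identical output). Defaults describe the study conditions the
#' package's benchmarks assume: gel-band noise of 0.02 on the fraction
#' scale; an expression chip with 4294 coding genes of which ~550 respond
#' to SBS mutants and only one fifth of those to PBS mutants; 300-nt
#' untranslated regions with one planted 60-nt C-rich, weakly structured
#' rut window in a hairpin-rich background; and qPCR Ct noise of 0.2
#' cycles.
#'
#' @param seed integer seed (required).
#' @param noise_sd multiplicative lognormal sdlog applied to gel band
#'   intensities (fraction-scale noise).
#' @param n_genes number of coding genes on the synthetic chip.
#' @param n_affected number of genes carrying a planted SBS effect.
#' @param frac_pbs_insensitive fraction of affected genes whose effect is
#'   absent in the PBS tables (PBS-insensitive terminators).
#' @param effect_log2_mean,effect_log2_sd mean and sd of the planted
#'   |log2 fold change| distribution (truncated below at the detection
#'   cutoff `log2(fold_threshold)`).
#' @param sigma_null sd (log2 units) of measurement noise added to every
#'   gene; 0.3 keeps false positives at a 5-fold cutoff essentially at
#'   zero on 4294 genes.
#' @param fold_threshold fold-change cutoff the planted effects must
#'   exceed.
#' @param seq_count,seq_length,rut_length sizes for sequence generation
#'   (nt).
#' @param sigma_ct sd of qPCR Ct noise (cycles).
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(seed, noise_sd = 0.02, n_genes = 4294,
                         n_affected = 550, frac_pbs_insensitive = 0.8,
                         effect_log2_mean = 4, effect_log2_sd = 1,
                         sigma_null = 0.3, fold_threshold = 5,
                         seq_count = 100, seq_length = 300,
                         rut_length = 60, sigma_ct = 0.2) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("a single integer seed is required", call. = FALSE)
  stopifnot(noise_sd >= 0, n_affected <= n_genes,
            frac_pbs_insensitive >= 0, frac_pbs_insensitive <= 1,
            sigma_null >= 0, seq_count >= 1, rut_length <= seq_length,
            sigma_ct >= 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Synthetic release time course (gel-band form)
#'
#' Computes the true released fraction from the kinetic model, converts it
#' back to the two gel bands of the release assay -- half supernatant (S)
#' and the rest of the sample (S+P), with the total RNA fixed at 100
#' units, so that 2S/(S + (S+P)) equals the true fraction -- and applies
#' multiplicative lognormal noise to each band.
#'
#' @param params a [rate_parameters()] object.
#' @param chain a [chain_spec()] object.
#' @param times sampling times (s).
#' @param cfg a [synth_config()].
#' @param nusg logical NusG flag passed to the kinetic model.
#' @return A data frame of class `"release_measurement"` with columns
#'   `time`, `s_half`, `s_plus_p` and `true_fraction`.
#' @export
gen_release_timecourse <- function(params, chain, times, cfg,
                                   nusg = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  truth <- simulate_release_analytic(params, chain, times, nusg)$value
  total <- 100
  s <- truth * total / 2
  sp <- total * (1 - truth / 2)
  if (cfg$noise_sd > 0) {
    s <- s * rlnorm(length(s), 0, cfg$noise_sd)
    sp <- sp * rlnorm(length(sp), 0, cfg$noise_sd)
  }
  out <- data.frame(time = times, s_half = s, s_plus_p = sp,
                    true_fraction = truth)
  class(out) <- c("release_measurement", "data.frame")
  out
}

#' Measured time course from synthetic gel bands
#'
#' Applies [release_fraction()] to a `"release_measurement"` table and
#' returns a [timecourse()] ready for [fit_kinetics()].
#'
#' @param m a data frame from [gen_release_timecourse()].
#' @param kind passed to [timecourse()].
#' @return A [timecourse()].
#' @export
measured_timecourse <- function(m, kind = "release") {
  timecourse(m$time, release_fraction(m$s_half, m$s_plus_p), kind = kind)
}

# Truncated-normal magnitudes via the inverse-CDF map (seed-deterministic).
rtrunc_norm_lower <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Synthetic two-condition expression tables with planted effects
#'
#' Builds SBS- and PBS-mutant expression tables over the same gene
#' universe. `n_affected` genes carry a planted |log2 fold change| drawn
#' above the detection cutoff (random sign) in the SBS table; only a
#' fraction `1 - frac_pbs_insensitive` of those genes carry the same
#' effect in the PBS table, emulating terminators whose function survives
#' the loss of primary RNA binding. Every gene additionally receives
#' Normal(0, `sigma_null`) measurement noise.
#'
#' @param cfg a [synth_config()].
#' @return A list with `pbs` and `sbs` tables (`gene_id`, `category`,
#'   `wt`, `mut`, `log2fc`) and `truth` (gene-id sets `affected_sbs`,
#'   `affected_pbs`, `sbs_only`).
#' @export
gen_expression_tables <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  ids <- sprintf("gene%05d", seq_len(n))
  cut <- log2(cfg$fold_threshold)
  affected <- sort(sample(n, cfg$n_affected))
  n_pbs <- round((1 - cfg$frac_pbs_insensitive) * cfg$n_affected)
  pbs_carriers <- sort(sample(affected, n_pbs))
  mag <- rtrunc_norm_lower(cfg$n_affected, cfg$effect_log2_mean,
                           cfg$effect_log2_sd, cut)
  eff <- mag * sample(c(-1, 1), cfg$n_affected, replace = TRUE)
  effect_sbs <- numeric(n); effect_sbs[affected] <- eff
  effect_pbs <- numeric(n)
  effect_pbs[pbs_carriers] <- effect_sbs[pbs_carriers]
  wt <- 2^rnorm(n, 10, 1)
  mk_table <- function(effect) {
    fc <- effect + rnorm(n, 0, cfg$sigma_null)
    data.frame(gene_id = ids, category = "coding", wt = wt,
               mut = wt * 2^fc, log2fc = fc, stringsAsFactors = FALSE)
  }
  sbs <- mk_table(effect_sbs)
  pbs <- mk_table(effect_pbs)
  list(pbs = pbs, sbs = sbs,
       truth = list(affected_sbs = ids[affected],
                    affected_pbs = ids[pbs_carriers],
                    sbs_only = ids[setdiff(affected, pbs_carriers)]))
}

rna_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

sample_bases <- function(n, probs) {
  paste(sample(c("C", "A", "U", "G"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Hairpin-rich background: concatenated stem-loop cassettes (random
# GC-biased stem + 4-nt loop + reverse complement) with short linkers.
gen_background <- function(len) {
  out <- character()
  total <- 0L
  while (total < len) {
    stem <- sample_bases(12, probs = c(0.35, 0.15, 0.15, 0.35))
    cassette <- paste0(stem, sample_bases(4, rep(0.25, 4)),
                       rna_revcomp(stem), sample_bases(3, rep(0.25, 4)))
    out <- c(out, cassette)
    total <- total + nchar(cassette)
  }
  substr(paste(out, collapse = ""), 1L, len)
}

#' Synthetic untranslated regions with planted rut windows
#'
#' Generates `seq_count` RNA sequences consisting of strongly structured
#' stem-loop background with one planted rut window per sequence drawn
#' from the C-rich, G-poor composition C 0.45, A 0.25, U 0.20, G 0.10
#' (expected C/G ratio 4.5, weak folding propensity).
#'
#' @param cfg a [synth_config()].
#' @return A list with `sequences` (named character vector, RNA spelling)
#'   and `truth` (BED-like data frame of planted rut coordinates, 0-based
#'   half-open).
#' @export
gen_rut_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  rut_probs <- c(0.45, 0.25, 0.20, 0.10)  # C, A, U, G
  seqs <- character(cfg$seq_count)
  starts <- integer(cfg$seq_count)
  names(seqs) <- sprintf("synthutr%03d", seq_len(cfg$seq_count))
  for (i in seq_len(cfg$seq_count)) {
    s <- gen_background(cfg$seq_length)
    start <- sample.int(cfg$seq_length - cfg$rut_length + 1L, 1L) - 1L
    rut <- sample_bases(cfg$rut_length, rut_probs)
    substr(s, start + 1L, start + cfg$rut_length) <- rut
    seqs[i] <- s
    starts[i] <- start
  }
  list(sequences = seqs,
       truth = data.frame(name = names(seqs), start = starts,
                          end = starts + as.integer(cfg$rut_length),
                          stringsAsFactors = FALSE))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (RNA or DNA spelling).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Synthetic qPCR Ct table with planted fold changes
#'
#' Emulates qRT-PCR validation inputs: for each gene with true fold change
#' f, the mutant target Ct is shifted by -log2(f) cycles relative to the
#' wild type (perfect doubling efficiency) plus Normal(0, `sigma_ct`)
#' noise; the internal-control Cts are constant, so
#' [ddct_fold_change()] recovers f in expectation.
#'
#' @param cfg a [synth_config()].
#' @param true_folds named or unnamed vector of true fold changes (> 0).
#' @param ct_target_wt,ct_control baseline threshold cycles.
#' @return A data frame with one row per gene: `gene_id`, `true_fold` and
#'   the four Ct columns consumed by [ddct_fold_change()].
#' @export
gen_ct_table <- function(cfg, true_folds, ct_target_wt = 22,
                         ct_control = 15) {
  stopifnot(inherits(cfg, "synth_config"))
  if (any(true_folds <= 0))
    stop("true fold changes must be > 0", call. = FALSE)
  set.seed(cfg$seed)
  n <- length(true_folds)
  ids <- if (!is.null(names(true_folds))) names(true_folds)
         else sprintf("target%02d", seq_len(n))
  data.frame(
    gene_id = ids, true_fold = as.numeric(true_folds),
    ct_target_mut = ct_target_wt - log2(true_folds) +
      rnorm(n, 0, cfg$sigma_ct),
    ct_control_mut = ct_control,
    ct_target_wt = ct_target_wt,
    ct_control_wt = ct_control,
    stringsAsFactors = FALSE)
}
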