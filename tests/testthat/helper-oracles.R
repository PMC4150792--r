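# Independent oracle for the folding DP: recursive interval enumeration
# of every nested pairing (with interval caching so short sequences stay
# fast), written against the stated energy model only.
bf_pair_energy <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(-3)
  if (key %in% c("AU", "UA")) return(-2)
  if (key %in% c("GU", "UG")) return(-1)
  NA_real_
}

bf_fold_energy <- function(seq, min_loop = 3L) {
  ch <- strsplit(toupper(chartr("Tt", "Uu", seq)), "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0)
    key <- paste0(i, "_", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1L)  # j unpaired
    for (k in i:(j - min_loop - 1L)) {
      e <- bf_pair_energy(ch[k], ch[j])
      if (is.na(e)) next
      left <- if (k > i) rec(i, k - 1L) else 0
      inner <- if (k + 1L <= j - 1L) rec(k + 1L, j - 1L) else 0
      best <- min(best, left + inner + e)
    }
    memo[[key]] <- best
    best
  }
  rec(1L, length(ch))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# Study conditions for the lag-phenomenology pipeline: the 0.25-10 min
# sampling grid of the release assay and the number of replicate time
# courses averaged before fitting.
release_time_grid <- function() c(seq(15, 180, by = 15), 240, 300, 420, 600)
n_release_replicates <- 10L

# Well-separated generator seeds for replicate gels (nearby integer seeds
# can leave residual structure in the first draws of the stream that
# replicate averaging does not cancel).
replicate_seeds <- function(base) base + 104729L * seq_len(n_release_replicates)

# Average the released fractions of seeded replicate gel measurements and
# return a fit-ready timecourse.
averaged_release_tc <- function(params, chain, times, seeds, nusg = FALSE,
                                noise_sd = 0.02) {
  ys <- vapply(seeds, function(s) {
    m <- gen_release_timecourse(params, chain, times,
                                synth_config(seed = s, noise_sd = noise_sd),
                                nusg = nusg)
    release_fraction(m$s_half, m$s_plus_p)
  }, numeric(length(times)))
  timecourse(times, rowMeans(ys))
}

# Overlap-based sensitivity/precision of called intervals against planted
# truth (both BED-like, 0-based half-open, one planted interval per name).
interval_sens_prec <- function(called, truth) {
  hits <- 0L; good_calls <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    cc <- called[called$name == tr$name, , drop = FALSE]
    ov <- cc$start < tr$end & cc$end > tr$start
    if (any(ov)) hits <- hits + 1L
    good_calls <- good_calls + sum(ov)
  }
  c(sens = hits / nrow(truth),
    prec = if (nrow(called)) good_calls / nrow(called) else NA_real_)
}
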