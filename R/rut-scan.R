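#' Minimum folding free energy of an RNA sequence
#'
#' Self-contained minimum-free-energy dynamic program over all nested
#' (pseudoknot-free) secondary structures under a documented simple pair
#' energy model: GC -3, AU -2, GU -1 kcal/mol, with a minimum hairpin loop
#' of `min_loop` unpaired nucleotides. It is meant as a reproducible
#' *propensity* score for secondary-structure formation in rut-site
#' scanning -- rut sites are C-rich and weakly structured -- not as a
#' thermodynamically calibrated folding energy, so its values are not
#' comparable with nearest-neighbour folding tools.
#'
#' @param seq a single character string over A, C, G, U (T is accepted and
#'   read as U; case-insensitive).
#' @param min_loop minimum hairpin loop length in nucleotides (default 3).
#' @return Minimum total energy in kcal/mol (<= 0; 0 when no pair can
#'   form).
#' @examples
#' fold_energy("GGGAAACCC")   # -9: three GC pairs closing a 3-nt loop
#' fold_energy("CCCCCCCCCC")  # 0: no complementary partners
#' @export
fold_energy <- function(seq, min_loop = 3L) {
  seq <- normalize_rna(seq)
  fold_energy_cpp(seq, as.integer(min_loop))
}

normalize_rna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L)
    stop("seq must be a single character string", call. = FALSE)
  s <- chartr("t", "u", tolower(seq))
  s <- toupper(s)
  if (nchar(s) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  bad <- gsub("[ACGU]", "", s)
  if (nchar(bad) > 0L)
    stop("invalid characters in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  s
}

#' Scan a transcript for candidate rut windows
#'
#' Slides a window along the (sense-strand) transcript and reports, for
#' each position, the C and G counts, the C/G ratio (with a pseudocount of
#' 1 in the denominator so G-free windows score finitely), the minimum
#' folding energy of the window under the simple energy model of
#' [fold_energy()], and a combined rank score. Candidate rut sites are
#' windows that combine a high C/G ratio with a weak folding propensity.
#'
#' @param seq a single sequence (character; T read as U).
#' @param window window width in nt (default 60, matching the scale of
#'   experimentally delineated Rho-loading segments).
#' @param step step size in nt (default 1).
#' @param name sequence name carried into the output (default
#'   `"seq"`).
#' @param min_loop passed to [fold_energy()].
#' @return A `data.frame` of class `"rut_windows"` with one row per
#'   window: `name`, 0-based half-open `start`/`end`, `c_count`,
#'   `g_count`, `cg_ratio`, `delta_g` and `score` (sum of the within-scan
#'   ranks of `cg_ratio` and `delta_g`, scaled to 0--1000; higher is more
#'   rut-like).
#' @export
scan_windows <- function(seq, window = 60L, step = 1L, name = "seq",
                         min_loop = 3L) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L)
    stop("window and step must be positive", call. = FALSE)
  if (window > n)
    stop("window exceeds sequence length", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  cum_c <- c(0L, cumsum(chars == "C"))
  cum_g <- c(0L, cumsum(chars == "G"))
  starts <- seq.int(0L, n - window, by = step)  # 0-based
  c_count <- cum_c[starts + window + 1L] - cum_c[starts + 1L]
  g_count <- cum_g[starts + window + 1L] - cum_g[starts + 1L]
  dg <- as.numeric(fold_energy_windows_cpp(s, window, step,
                                           as.integer(min_loop)))
  cg_ratio <- c_count / pmax(g_count, 1L)
  combined <- rank(cg_ratio, ties.method = "average") +
    rank(dg, ties.method = "average")  # higher (less negative) dg is better
  score <- if (length(combined) > 1L)
    1000 * (combined - min(combined)) / diff(range(combined))
  else rep(1000, length(combined))
  out <- data.frame(name = name, start = starts, end = starts + window,
                    c_count = c_count, g_count = g_count,
                    cg_ratio = cg_ratio, delta_g = dg,
                    score = score, stringsAsFactors = FALSE)
  class(out) <- c("rut_windows", "data.frame")
  out
}

#' Call rut sites from scanned windows
#'
#' Flags windows whose C/G ratio is at least `cg_min` *and* whose folding
#' energy is at least (i.e. no more negative than) `dg_min`, then merges
#' overlapping or book-ended flagged windows into maximal intervals. The
#' two thresholds operationalize the field's definition of a rut site --
#' C-richness and lack of secondary structure. `dg_min` is expressed in
#' the units of the package's own energy model.
#'
#' @param windows a `"rut_windows"` data frame from [scan_windows()]
#'   (one or more sequences row-bound together).
#' @param cg_min minimum C/G ratio (default 1.5).
#' @param dg_min minimum (least negative) folding energy in kcal/mol.
#' @return A BED-like `data.frame` (`name`, `start`, `end`, 0-based
#'   half-open) of merged rut intervals, with a `score` column carrying
#'   the maximum window score inside each interval.
#' @examples
#' w <- scan_windows(paste(rep("C", 80), collapse = ""), window = 60)
#' call_rut_sites(w)
#' @export
call_rut_sites <- function(windows, cg_min = 1.5, dg_min = -50) {
  stopifnot(is.data.frame(windows))
  flagged <- windows[windows$cg_ratio >= cg_min &
                       windows$delta_g >= dg_min, , drop = FALSE]
  empty <- data.frame(name = character(), start = integer(),
                      end = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(flagged) == 0L) return(empty)
  out <- empty
  for (nm in unique(flagged$name)) {
    f <- flagged[flagged$name == nm, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    cur_s <- f$start[1]; cur_e <- f$end[1]; cur_sc <- f$score[1]
    for (i in seq_len(nrow(f))[-1]) {
      if (f$start[i] <= cur_e) {  # overlap or book-ended
        cur_e <- max(cur_e, f$end[i])
        cur_sc <- max(cur_sc, f$score[i])
      } else {
        out <- rbind(out, data.frame(name = nm, start = cur_s, end = cur_e,
                                     score = cur_sc))
        cur_s <- f$start[i]; cur_e <- f$end[i]; cur_sc <- f$score[i]
      }
    }
    out <- rbind(out, data.frame(name = nm, start = cur_s, end = cur_e,
                                 score = cur_sc))
  }
  rownames(out) <- NULL
  out
}

#' Scan a FASTA file for rut sites
#'
#' Convenience wrapper: reads sequences with `Biostrings`, scans each with
#' [scan_windows()] and calls merged rut intervals with
#' [call_rut_sites()].
#'
#' @param fasta path to a FASTA file (DNA or RNA spelling).
#' @inheritParams scan_windows
#' @inheritParams call_rut_sites
#' @return A list with `windows` (row-bound window table) and `sites`
#'   (merged BED-like intervals).
#' @export
rut_scan_fasta <- function(fasta, window = 60L, step = 1L,
                           cg_min = 1.5, dg_min = -50, min_loop = 3L) {
  ss <- Biostrings::readBStringSet(fasta)
  wins <- do.call(rbind, lapply(seq_along(ss), function(i)
    scan_windows(as.character(ss[[i]]), window = window, step = step,
                 name = names(ss)[i], min_loop = min_loop)))
  list(windows = wins,
       sites = call_rut_sites(wins, cg_min = cg_min, dg_min = dg_min))
}

#' Write intervals as BED
#'
#' @param x BED-like data frame with columns `name`, `start`, `end` and
#'   optionally `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  score <- if ("score" %in% names(x)) as.integer(round(x$score)) else 0L
  bed <- data.frame(chrom = x$name, start = x$start, end = x$end,
                    name = sprintf("rut_%d", seq_len(nrow(x))),
                    score = score, strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
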