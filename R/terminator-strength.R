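#' Termination-zone description
#'
#' A termination zone is the stretch of transcript positions at which
#' Rho-released transcripts end; its distance from the 3' end of the rut
#' site is used as a terminator-strength metric (long distances indicate
#' slow formation of translocase-competent Rho).
#'
#' @param rut_end transcript coordinate of the rut 3' end (nt).
#' @param zone_start,zone_end transcript coordinates of the zone
#'   (half-open, `zone_start <= zone_end`); `rut_end` must not lie inside
#'   the zone.
#' @param name optional terminator name.
#' @return An object of class `"termination_zone"`.
#' @examples
#' termination_zone(120, 190, 265)
#' @export
termination_zone <- function(rut_end, zone_start, zone_end, name = NA_character_) {
  if (zone_start > zone_end)
    stop("zone_start must be <= zone_end", call. = FALSE)
  if (rut_end > zone_start)
    stop("coordinate error: rut_end lies inside or beyond the termination zone",
         call. = FALSE)
  structure(list(name = name, rut_end = rut_end,
                 zone_start = zone_start, zone_end = zone_end),
            class = "termination_zone")
}

#' @export
print.termination_zone <- function(x, ...) {
  s <- distance_stats(x)
  cat(sprintf("Termination zone%s: rut 3' end %d, zone [%d, %d); distance %d-%d nt (mean %.1f)\n",
              if (is.na(x$name)) "" else paste0(" ", x$name),
              x$rut_end, x$zone_start, x$zone_end, s$min, s$max, s$mean))
  invisible(x)
}

#' Distance statistics of a termination zone
#'
#' @param zone a [termination_zone()].
#' @return A list with `min`, `max` and `mean` distances (nt) from the rut
#'   3' end to the zone.
#' @examples
#' distance_stats(termination_zone(120, 190, 265))  # 70-145 nt
#' @export
distance_stats <- function(zone) {
  stopifnot(inherits(zone, "termination_zone"))
  list(min = zone$zone_start - zone$rut_end,
       max = zone$zone_end - zone$rut_end,
       mean = (zone$zone_start + zone$zone_end) / 2 - zone$rut_end)
}

#' Classify a terminator by its rut-to-zone distance
#'
#' Rho-dependent terminators fall into two classes: classical, fast
#' isomerizing terminators whose termination zones sit close to the rut
#' site (t_R1-like), and slowly isomerizing, NusG-dependent terminators
#' that terminate unusually far downstream (t_rac-like). The default
#' threshold, 265 nt, is the midpoint between the two experimentally
#' observed distance ranges (roughly 70--145 nt versus 385--425 nt).
#'
#' @param mean_distance mean rut-to-zone distance(s) in nt (>= 0).
#' @param threshold class boundary in nt; distances at or above it are
#'   called t_rac-like.
#' @return Character vector: `"tR1-like"` or `"trac-like"`.
#' @examples
#' classify_terminator(c(107, 405))
#' @export
classify_terminator <- function(mean_distance, threshold = 265) {
  if (any(mean_distance < 0))
    stop("distances must be non-negative", call. = FALSE)
  ifelse(mean_distance >= threshold, "trac-like", "tR1-like")
}

#' Invert the termination-distance model to a commitment time
#'
#' Solves the mean-distance formula of [predict_termination_zone()] for
#' the mean commitment time:
#' \deqn{E[T] = [(d - v_{RNAP}/k_{dislodge}) (\rho - v_{RNAP})/\rho - start\_offset]/v_{RNAP}.}
#' Long termination distances thus translate into long times to form a
#' translocase-competent Rho, conditional on the supplied speeds (which
#' are not experimentally pinned down and must be treated as scenario
#' parameters).
#'
#' @param mean_distance mean rut-to-zone distance (nt).
#' @param rnap_speed,rho_speed RNAP and Rho speeds (nt/s);
#'   `rho_speed > rnap_speed` required.
#' @param k_dislodge EC dissociation rate (1/s; `Inf` for instant
#'   dislodging).
#' @param start_offset nt head start of RNAP past the rut 3' end.
#' @return Mean commitment time E\[T\] in seconds.
#' @examples
#' infer_commitment_time(300, rnap_speed = 20, rho_speed = 60,
#'                       k_dislodge = Inf)  # 10 s
#' @export
infer_commitment_time <- function(mean_distance, rnap_speed = 20,
                                  rho_speed = 60, k_dislodge = Inf,
                                  start_offset = 0) {
  if (!(rnap_speed > 0)) stop("rnap_speed must be > 0", call. = FALSE)
  if (rho_speed <= rnap_speed)
    stop("no catch-up: rho_speed must exceed rnap_speed", call. = FALSE)
  drift <- if (is.finite(k_dislodge)) rnap_speed / k_dislodge else 0
  et <- ((mean_distance - drift) * (rho_speed - rnap_speed) / rho_speed -
           start_offset) / rnap_speed
  if (any(et <= 0))
    stop("infeasible parameters: the whole distance is explained by ",
         "dislodging drift and the start offset", call. = FALSE)
  et
}

#' Terminator-strength table
#'
#' Applies [distance_stats()], [classify_terminator()] and
#' [infer_commitment_time()] to a table of annotated zones.
#'
#' @param zones data frame with columns `name`, `rut_end`, `zone_start`,
#'   `zone_end`.
#' @inheritParams infer_commitment_time
#' @param threshold classification threshold (nt).
#' @return The input with `dist_min`, `dist_max`, `dist_mean`, `class`
#'   and `commitment_time_s` columns appended.
#' @export
terminator_strength_table <- function(zones, rnap_speed = 20, rho_speed = 60,
                                      k_dislodge = Inf, start_offset = 0,
                                      threshold = 265) {
  stopifnot(all(c("name", "rut_end", "zone_start", "zone_end") %in%
                  names(zones)))
  stats <- lapply(seq_len(nrow(zones)), function(i)
    distance_stats(termination_zone(zones$rut_end[i], zones$zone_start[i],
                                    zones$zone_end[i], zones$name[i])))
  zones$dist_min <- vapply(stats, `[[`, numeric(1), "min")
  zones$dist_max <- vapply(stats, `[[`, numeric(1), "max")
  zones$dist_mean <- vapply(stats, `[[`, numeric(1), "mean")
  zones$class <- classify_terminator(zones$dist_mean, threshold)
  zones$commitment_time_s <- vapply(zones$dist_mean, function(d)
    tryCatch(infer_commitment_time(d, rnap_speed, rho_speed, k_dislodge,
                                   start_offset),
             error = function(e) NA_real_), numeric(1))
  zones
}
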