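#' Count-weighted leaf disease index
#'
#' A plant's (or replicate's) disease index is the count-weighted mean of its
#' leaf categories on the ordinal 0--4 scale (0 dark green, 1 pale green,
#' 2 yellow, 3 brown spots, 4 dead):
#' \deqn{D.I. = \frac{0 N_0 + 1 N_1 + 2 N_2 + 3 N_3 + 4 N_4}{N_0+N_1+N_2+N_3+N_4}}
#'
#' @param counts numeric vector of length 5 (leaves in categories 0--4), or a
#'   data.frame/matrix with columns \code{n0..n4} (one row per observation).
#' @return disease index in [0, 4]; a vector when given multiple rows.
#' @examples
#' weighted_disease_index(c(2, 1, 1, 0, 0)) # 0.75
#' @export
weighted_disease_index <- function(counts) {
  if (is.data.frame(counts) || is.matrix(counts)) {
    m <- as.matrix(as.data.frame(counts)[, c("n0", "n1", "n2", "n3", "n4")])
  } else {
    if (length(counts) != 5) stop("counts must have 5 categories (n0..n4)")
    m <- matrix(as.numeric(counts), nrow = 1)
  }
  if (any(is.na(m)) || any(m < 0)) stop("leaf counts must be non-negative and complete")
  if (any(m != floor(m))) stop("leaf counts must be whole numbers")
  tot <- rowSums(m)
  if (any(tot < 1)) {
    stop("unscoreable observation: total leaf count is zero")
  }
  as.vector(m %*% 0:4) / tot
}

# shared exclusion rules for seedling time courses:
#  (1) drop observations older than max_day;
#  (2) death truncation: if the index reaches the scale maximum (4.0, all
#      leaves dead), keep only the first two such observations.
# `day` must be sorted ascending; returns logical keep mask.
timecourse_keep <- function(day, di, max_day, scale_max = 4) {
  if (is.unsorted(day, strictly = TRUE)) {
    stop("observation days must be strictly increasing")
  }
  keep <- day <= max_day
  dead <- keep & di >= scale_max
  if (any(dead)) {
    dead_idx <- which(dead)
    if (length(dead_idx) > 2) keep[dead_idx[-(1:2)]] <- FALSE
  }
  keep
}

# slope of a no-intercept least-squares line y = b * x:
#   b = sum(x * y) / sum(x^2)
slope_through_origin <- function(x, y) {
  sxx <- sum(x^2)
  if (sxx == 0) stop("insufficient data: slope through origin undefined (all days zero)")
  sum(x * y) / sxx
}

#' Fit the disease-progression line for one seedling time course
#'
#' Disease symptoms progress approximately linearly in time during the
#' infection phase, so each replicate's time course is summarised by the slope
#' of a regression of disease index on plant age, forced through the origin
#' (an uninoculated plant starts symptom-free). Two cleanup rules are applied
#' first: observations from plants older than \code{max_day} days are dropped,
#' and when the microbe kills every leaf (index pinned at 4.0) only the first
#' two fully-dead observations are kept so the plateau does not drag the slope
#' down. The standardized 10-day disease index is 10 times the slope, clipped
#' to the 0--4 scale.
#'
#' @param day numeric vector of plant ages (days), strictly increasing.
#' @param di per-observation disease indices (same length); alternatively
#'   supply \code{counts}, a 5-column matrix/data.frame of leaf tallies from
#'   which indices are computed.
#' @param counts optional leaf-category counts used when \code{di} is missing.
#' @param thresholds a \code{\link{classification_thresholds}} object.
#' @param origin fit through the origin (default TRUE, the standard protocol);
#'   \code{FALSE} fits ordinary least squares with an intercept and returns
#'   its slope (provided for sensitivity analysis).
#' @return a list with elements \code{slope} (index units/day), \code{di10_raw}
#'   (10 x slope) and \code{di10} (clipped to [0, scale max]), \code{n_used},
#'   and \code{excluded} (count of dropped observations).
#' @seealso [standardized_di_10day()], [growth_rate()]
#' @export
fit_timecourse <- function(day, di = NULL, counts = NULL,
                           thresholds = classification_thresholds(),
                           origin = TRUE) {
  if (is.null(di)) {
    if (is.null(counts)) stop("supply either di or counts")
    di <- weighted_disease_index(counts)
  }
  if (length(day) != length(di) || length(day) == 0) {
    stop("day and di must be non-empty and the same length")
  }
  o <- order(day)
  day <- day[o]; di <- di[o]
  keep <- timecourse_keep(day, di, thresholds$max_day,
                          thresholds$seedling_scale_max)
  if (!any(keep)) stop("insufficient data: no observations left after exclusions")
  x <- day[keep]; y <- di[keep]
  b <- if (origin) {
    slope_through_origin(x, y)
  } else {
    if (length(x) < 2) stop("insufficient data: OLS with intercept needs >= 2 points")
    stats::cov(x, y) / stats::var(x)
  }
  raw <- 10 * b
  list(slope = b,
       di10_raw = raw,
       di10 = min(max(raw, 0), thresholds$seedling_scale_max),
       n_used = length(x),
       excluded = sum(!keep))
}

#' Standardized 10-day disease index
#'
#' Convenience wrapper around \code{\link{fit_timecourse}} returning just the
#' clipped 10-day value: ten times the through-origin slope of disease index
#' on plant age, after the age-exclusion and death-truncation rules.
#'
#' @inheritParams fit_timecourse
#' @return a number on the 0--4 seedling scale.
#' @examples
#' standardized_di_10day(c(3, 6, 9), di = c(0.6, 1.2, 1.8)) # 2.0
#' @export
standardized_di_10day <- function(day, di = NULL, counts = NULL,
                                  thresholds = classification_thresholds(),
                                  origin = TRUE) {
  fit_timecourse(day, di, counts, thresholds, origin)$di10
}

#' Seedling growth rate in leaves/day
#'
#' The same through-origin standardization applied to total leaf count instead
#' of the disease index; the exclusion rules (age cutoff, death truncation on
#' the disease index) are identical, so a disease index must be supplied (or
#' derivable from counts) whenever the death rule could bite.
#'
#' @param day plant ages, strictly increasing.
#' @param leaves total leaf counts per observation; derived from \code{counts}
#'   when omitted.
#' @param di per-observation disease indices used for death truncation;
#'   defaults to 0 (no truncation) when neither \code{di} nor \code{counts}
#'   is given.
#' @inheritParams fit_timecourse
#' @return growth rate in leaves/day (through-origin slope, not clipped).
#' @examples
#' growth_rate(c(5, 10), leaves = c(4, 4)) # 0.48
#' @export
growth_rate <- function(day, leaves = NULL, counts = NULL, di = NULL,
                        thresholds = classification_thresholds(),
                        origin = TRUE) {
  if (is.null(leaves)) {
    if (is.null(counts)) stop("supply either leaves or counts")
    m <- as.matrix(as.data.frame(counts)[, c("n0", "n1", "n2", "n3", "n4")])
    leaves <- rowSums(m)
  }
  if (is.null(di)) {
    di <- if (!is.null(counts)) weighted_disease_index(counts) else rep(0, length(day))
  }
  if (length(day) != length(leaves) || length(day) == 0) {
    stop("day and leaves must be non-empty and the same length")
  }
  o <- order(day)
  day <- day[o]; leaves <- leaves[o]; di <- di[o]
  keep <- timecourse_keep(day, di, thresholds$max_day,
                          thresholds$seedling_scale_max)
  if (!any(keep)) stop("insufficient data: no observations left after exclusions")
  x <- day[keep]; y <- leaves[keep]
  if (origin) {
    slope_through_origin(x, y)
  } else {
    if (length(x) < 2) stop("insufficient data: OLS with intercept needs >= 2 points")
    stats::cov(x, y) / stats::var(x)
  }
}

#' Mean lesion score of mature-leaf sections
#'
#' Each inoculated 2 x 2 cm leaf section is scored 0 (healthy), 0.5
#' (discolored areas no larger than the inoculation disk) or 1 (larger
#' discolored/necrotic areas); the isolate's lesion score is the mean across
#' replicate sections. The protocol uses between three and seven replicates;
#' other replicate counts are accepted with a warning.
#'
#' @param scores numeric vector of section scores, each in {0, 0.5, 1}.
#' @return mean score in [0, 1].
#' @examples
#' mean_lesion_score(c(0, 0.5, 1, 0.5)) # 0.5
#' @export
mean_lesion_score <- function(scores) {
  if (length(scores) == 0) stop("no section scores supplied")
  if (!all(scores %in% c(0, 0.5, 1))) {
    stop("section scores must be 0, 0.5 or 1")
  }
  if (length(scores) < 3 || length(scores) > 7) {
    warning(sprintf("replicate count %d outside the usual 3-7 range",
                    length(scores)))
  }
  mean(scores)
}

#' Classify a seedling-assay disease index
#'
#' The standardized 10-day index is rounded half-up to one decimal, then
#' mapped: Strong Pathogen at or above \code{seedling_strong_min} (4.1),
#' Pathogen at or above \code{seedling_pathogen_min} (2.0), Weak Pathogen for
#' smaller values that clear both the iron-chlorosis symptom floor (0.03) and
#' the minor-lesion floor (0.1), otherwise Nonpathogen. The Weak Pathogen
#' band on the seedling scale is an extension of the published two-threshold
#' scheme; set \code{seedling_weak_min} above the scale maximum to disable it.
#'
#' @param di standardized disease index (or vector thereof), each >= 0.
#' @param thresholds a \code{\link{classification_thresholds}} object.
#' @return factor with levels Nonpathogen < Weak Pathogen < Pathogen <
#'   Strong Pathogen.
#' @examples
#' classify_seedling(c(6.6, 2.2, 0.0))
#' @export
classify_seedling <- function(di, thresholds = classification_thresholds()) {
  if (any(is.na(di)) || any(di < 0)) stop("disease index must be non-negative")
  r <- round_half_up(di, 1)
  lab <- ifelse(r >= thresholds$seedling_strong_min, "Strong Pathogen",
         ifelse(r >= thresholds$seedling_pathogen_min, "Pathogen",
         ifelse(di > thresholds$symptom_floor & r >= thresholds$seedling_weak_min,
                "Weak Pathogen", "Nonpathogen")))
  factor(lab, levels = pathogen_classes, ordered = TRUE)
}

#' Classify a mature-leaf lesion score
#'
#' Half-open bands on the 0--1 lesion scale: [0, 0.2) Nonpathogen,
#' [0.2, 0.5) Weak Pathogen, [0.5, 0.8) Pathogen, [0.8, 1] Strong Pathogen.
#' No rounding is applied; replicate means are exact multiples of 1/(2n).
#'
#' @param score mean lesion score(s) in [0, 1].
#' @inheritParams classify_seedling
#' @return ordered factor as in \code{\link{classify_seedling}}.
#' @examples
#' classify_mature(c(0.05, 0.2, 1.0))
#' @export
classify_mature <- function(score, thresholds = classification_thresholds()) {
  if (any(is.na(score)) || any(score < 0) || any(score > thresholds$mature_scale_max)) {
    stop("lesion score must lie in [0, ", thresholds$mature_scale_max, "]")
  }
  lab <- ifelse(score >= thresholds$mature_strong_min, "Strong Pathogen",
         ifelse(score >= thresholds$mature_pathogen_min, "Pathogen",
         ifelse(score >= thresholds$mature_weak_min, "Weak Pathogen",
                "Nonpathogen")))
  factor(lab, levels = pathogen_classes, ordered = TRUE)
}

#' Count isolates at or above a disease-index threshold
#'
#' @param di numeric vector of per-isolate standardized indices; NA entries
#'   (isolate not tested on that lineage) are dropped.
#' @param threshold inclusive lower bound (default 2.0, the pathogen cut).
#' @return integer count.
#' @examples
#' count_above_threshold(c(6.6, 1.2, 2.2), 2.0) # 2
#' @export
count_above_threshold <- function(di, threshold = 2.0) {
  di <- di[!is.na(di)]
  sum(di >= threshold)
}

#' Score a seedling-assay observation table
#'
#' Applies \code{\link{fit_timecourse}} and \code{\link{growth_rate}} per
#' replicate, then averages replicates within isolate x lineage and classifies
#' the result.
#'
#' @param obs data.frame with columns \code{isolate_id}, \code{lineage},
#'   \code{replicate}, \code{day}, \code{n0}..\code{n4} (the seedling CSV
#'   schema, see \code{\link{read_seedling_table}}).
#' @param thresholds a \code{\link{classification_thresholds}} object.
#' @return data.frame with one row per isolate x lineage: mean
#'   \code{standardized_di}, \code{raw_slope_di10}, \code{growth_rate},
#'   \code{n_replicates} and \code{seedling_class}.
#' @export
score_seedling_assay <- function(obs, thresholds = classification_thresholds()) {
  need <- c("isolate_id", "lineage", "replicate", "day", "n0", "n1", "n2", "n3", "n4")
  if (!all(need %in% names(obs))) {
    stop("seedling table must have columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(obs$isolate_id, obs$lineage, obs$replicate, drop = TRUE)
  per_rep <- lapply(split(obs, key), function(d) {
    d <- d[order(d$day), ]
    di <- weighted_disease_index(d[, c("n0", "n1", "n2", "n3", "n4")])
    fit <- fit_timecourse(d$day, di = di, thresholds = thresholds)
    gr <- growth_rate(d$day, leaves = rowSums(d[, c("n0", "n1", "n2", "n3", "n4")]),
                      di = di, thresholds = thresholds)
    data.frame(isolate_id = d$isolate_id[1], lineage = d$lineage[1],
               replicate = d$replicate[1], di10 = fit$di10,
               di10_raw = fit$di10_raw, growth = gr,
               stringsAsFactors = FALSE)
  })
  reps <- do.call(rbind, per_rep)
  grp <- interaction(reps$isolate_id, reps$lineage, drop = TRUE)
  out <- do.call(rbind, lapply(split(reps, grp), function(d) {
    data.frame(isolate_id = d$isolate_id[1], lineage = d$lineage[1],
               standardized_di = mean(d$di10),
               raw_slope_di10 = mean(d$di10_raw),
               growth_rate = mean(d$growth),
               n_replicates = nrow(d), stringsAsFactors = FALSE)
  }))
  out$seedling_class <- classify_seedling(out$standardized_di, thresholds)
  rownames(out) <- NULL
  out[order(out$isolate_id, out$lineage), ]
}

#' Score a mature-leaf assay table
#'
#' @param sections data.frame with columns \code{isolate_id}, \code{lineage},
#'   \code{abraded} (0/1 or logical) and \code{section_score} in {0, 0.5, 1}.
#' @param thresholds a \code{\link{classification_thresholds}} object.
#' @return data.frame with one row per isolate x lineage x abrasion state:
#'   \code{mean_lesion_score}, \code{n_sections}, \code{mature_class}.
#' @export
score_mature_assay <- function(sections, thresholds = classification_thresholds()) {
  need <- c("isolate_id", "lineage", "abraded", "section_score")
  if (!all(need %in% names(sections))) {
    stop("mature-leaf table must have columns: ", paste(need, collapse = ", "))
  }
  grp <- interaction(sections$isolate_id, sections$lineage,
                     as.logical(sections$abraded), drop = TRUE)
  out <- do.call(rbind, lapply(split(sections, grp), function(d) {
    m <- suppressWarnings(mean_lesion_score(d$section_score))
    data.frame(isolate_id = d$isolate_id[1], lineage = d$lineage[1],
               abraded = as.logical(d$abraded[1]),
               mean_lesion_score = m, n_sections = nrow(d),
               stringsAsFactors = FALSE)
  }))
  out$mature_class <- classify_mature(out$mean_lesion_score, thresholds)
  rownames(out) <- NULL
  out[order(out$isolate_id, out$lineage, out$abraded), ]
}
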