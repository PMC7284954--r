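#' Classification thresholds for the pathogenicity bioassays
#'
#' Bundles every cut-point used when turning bioassay measurements into
#' pathogenicity classes, with the study defaults:
#' \itemize{
#'   \item seedling scale (0--4 disease index): \code{>= 2.0} Pathogen,
#'     \code{>= 4.1} Strong Pathogen; values above the iron-chlorosis symptom
#'     floor (0.03) but below 2.0 are Weak Pathogen when \code{>= 0.1} (the
#'     minor-lesion floor), otherwise Nonpathogen.
#'   \item mature-leaf scale (0--1 lesion index): [0, 0.2) Nonpathogen,
#'     [0.2, 0.5) Weak Pathogen, [0.5, 0.8) Pathogen, [0.8, 1] Strong Pathogen.
#'   \item time-course cleanup: observations from plants older than
#'     \code{max_day} (16) days are excluded before regression.
#' }
#'
#' @param seedling_pathogen_min seedling index at or above which an isolate is
#'   a Pathogen (default 2.0).
#' @param seedling_strong_min seedling index for Strong Pathogen (default 4.1).
#' @param seedling_weak_min minor-lesion floor below which seedling symptoms
#'   are not called Weak Pathogen (default 0.1).
#' @param mature_weak_min,mature_pathogen_min,mature_strong_min mature-leaf
#'   class boundaries (defaults 0.2, 0.5, 0.8).
#' @param symptom_floor seedling index at or below which symptoms are
#'   attributed to iron-deficiency chlorosis, not the microbe (default 0.03).
#' @param max_day last plant age (days) retained in regressions (default 16;
#'   day 16 itself is kept).
#' @param seedling_scale_max,mature_scale_max scale maxima (4 and 1).
#' @return an object of class \code{phrag_thresholds} (a named list).
#' @examples
#' th <- classification_thresholds()
#' th$seedling_pathogen_min
#' @export
classification_thresholds <- function(seedling_pathogen_min = 2.0,
                                      seedling_strong_min = 4.1,
                                      seedling_weak_min = 0.1,
                                      mature_weak_min = 0.2,
                                      mature_pathogen_min = 0.5,
                                      mature_strong_min = 0.8,
                                      symptom_floor = 0.03,
                                      max_day = 16,
                                      seedling_scale_max = 4,
                                      mature_scale_max = 1) {
  th <- list(
    seedling_pathogen_min = seedling_pathogen_min,
    seedling_strong_min = seedling_strong_min,
    seedling_weak_min = seedling_weak_min,
    mature_weak_min = mature_weak_min,
    mature_pathogen_min = mature_pathogen_min,
    mature_strong_min = mature_strong_min,
    symptom_floor = symptom_floor,
    max_day = max_day,
    seedling_scale_max = seedling_scale_max,
    mature_scale_max = mature_scale_max
  )
  if (!(symptom_floor >= 0 && symptom_floor < seedling_pathogen_min &&
        seedling_pathogen_min < seedling_strong_min)) {
    stop("require 0 <= symptom_floor < seedling_pathogen_min < seedling_strong_min")
  }
  if (!(mature_weak_min > 0 && mature_weak_min < mature_pathogen_min &&
        mature_pathogen_min < mature_strong_min &&
        mature_strong_min <= mature_scale_max)) {
    stop("require 0 < mature_weak_min < mature_pathogen_min < mature_strong_min <= scale max")
  }
  structure(th, class = "phrag_thresholds")
}

#' @export
print.phrag_thresholds <- function(x, ...) {
  cat("Pathogenicity classification thresholds\n")
  cat(sprintf("  seedling (0-%g): Pathogen >= %g, Strong >= %g, weak floor %g, symptom floor %g\n",
              x$seedling_scale_max, x$seedling_pathogen_min,
              x$seedling_strong_min, x$seedling_weak_min, x$symptom_floor))
  cat(sprintf("  mature (0-%g): Weak >= %g, Pathogen >= %g, Strong >= %g\n",
              x$mature_scale_max, x$mature_weak_min, x$mature_pathogen_min,
              x$mature_strong_min))
  cat(sprintf("  time courses truncated after day %g\n", x$max_day))
  invisible(x)
}

# four-level severity scale shared by both assays
pathogen_classes <- c("Nonpathogen", "Weak Pathogen", "Pathogen", "Strong Pathogen")
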