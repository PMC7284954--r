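trophic_confidences <- c("possible", "probable", "highly probable")
ranks_family_up <- c("family", "order", "class", "phylum", "kingdom", "domain")

#' Read a guild lookup table
#'
#' The table is a local snapshot emulating guild-database assignments:
#' tab-separated with columns \code{taxon} (genus or "Genus species"),
#' \code{rank} of the matched name, \code{trophic_mode}
#' (Pathotroph/Symbiotroph/Saprotroph or "-" separated combinations),
#' \code{guild} free text, and \code{confidence} (possible/probable/highly
#' probable).
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_guild_table <- function(path) {
  gt <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_guild_table(gt)
}

validate_guild_table <- function(gt) {
  need <- c("taxon", "rank", "trophic_mode", "guild", "confidence")
  if (!all(need %in% names(gt))) {
    stop("guild table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!tolower(gt$confidence) %in% trophic_confidences)
  if (length(bad) > 0) {
    stop("malformed guild table: unknown confidence '", gt$confidence[bad[1]],
         "' at row ", bad[1])
  }
  bad <- which(is.na(gt$taxon) | !nzchar(trimws(gt$taxon)))
  if (length(bad) > 0) stop("malformed guild table: empty taxon at row ", bad[1])
  gt$confidence <- tolower(gt$confidence)
  gt$rank <- tolower(gt$rank)
  gt
}

#' Assign a predicted trophic mode from the guild table
#'
#' Look-up follows the guild-database convention: try the full species
#' binomial first, then fall back to the genus. Matches graded only
#' "possible" (the least reliable tier) and matches at family rank or higher
#' are discarded, returning \code{"unassigned"}.
#'
#' @param taxon character vector of taxon names ("Genus species" or genus).
#' @param guild_table data.frame from \code{\link{read_guild_table}}.
#' @return character vector of trophic modes, or \code{"unassigned"}.
#' @examples
#' gt <- data.frame(taxon = "Alternaria", rank = "genus",
#'                  trophic_mode = "Pathotroph-Saprotroph", guild = "",
#'                  confidence = "probable")
#' assign_guild("Alternaria alternata", gt)
#' @export
assign_guild <- function(taxon, guild_table) {
  gt <- validate_guild_table(guild_table)
  usable <- gt$confidence != "possible" & !gt$rank %in% ranks_family_up
  gt <- gt[usable, , drop = FALSE]
  key <- tolower(trimws(gt$taxon))
  vapply(taxon, function(tx) {
    tx <- tolower(gsub("\\s+", " ", trimws(tx)))
    hit <- which(key == tx)
    if (length(hit) == 0) {
      genus <- strsplit(tx, " ")[[1]][1]
      hit <- which(key == genus)
    }
    if (length(hit) == 0) "unassigned" else gt$trophic_mode[hit[1]]
  }, character(1), USE.NAMES = FALSE)
}

#' Pathogen:Endophyte:Saprophyte ratio
#'
#' Normalizes raw counts to endophyte = 1 and rounds each term half-up to the
#' nearest whole number, the convention used for reporting community-level
#' trophic structure (e.g. "roughly 6:1:9"). When the endophyte count is
#' zero the normalization is undefined and flagged.
#'
#' @param pathogen,endophyte,saprophyte non-negative counts.
#' @return list with \code{counts}, \code{normalized} (integer P:E:S with E=1,
#'   or NULL), \code{ratio_string}, \code{defined} (logical).
#' @examples
#' trophic_ratio(12, 2, 24)$ratio_string # "6:1:12"
#' @export
trophic_ratio <- function(pathogen, endophyte, saprophyte) {
  counts <- c(pathogen = pathogen, endophyte = endophyte, saprophyte = saprophyte)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (endophyte == 0) {
    return(list(counts = counts, normalized = NULL, ratio_string = NA_character_,
                defined = FALSE))
  }
  norm <- round_half_up(counts / endophyte, 0)
  list(counts = counts, normalized = norm,
       ratio_string = paste(norm, collapse = ":"), defined = TRUE)
}

#' Experimentally supported trophic class of one isolate
#'
#' Combines the three bioassays into a single trophic call with an explicit
#' precedence (the published account does not state its exact decision rule;
#' this reconstruction is isolated here so alternatives can be swapped):
#' \enumerate{
#'   \item \strong{Pathogen} if the seedling class is Pathogen or Strong
#'     Pathogen, or the mature-leaf class is Strong Pathogen;
#'   \item else \strong{Saprophyte} if the isolate sporulated (conidia or
#'     micro-sclerotia) on autoclaved leaves, i.e. completed its life cycle on
#'     dead tissue;
#'   \item else \strong{Endophyte} if it grew only as sterile hyphae, or
#'     failed to grow saprophytically despite having been isolated from
#'     living tissue;
#'   \item else \strong{Unclassified}.
#' }
#'
#' @param seedling_class,mature_class pathogenicity class labels (character or
#'   factor); NA for a missing assay.
#' @param saprophyte_outcome one of \code{"sporulating"},
#'   \code{"sterile_hyphae_only"}, \code{"no_growth"}; NA for missing.
#' @param from_living_tissue was the isolate originally cultured from living
#'   plant tissue (default TRUE; all collection isolates were).
#' @return one of "Pathogen", "Endophyte", "Saprophyte", "Unclassified".
#' @export
experimental_trophic_class <- function(seedling_class, mature_class,
                                       saprophyte_outcome,
                                       from_living_tissue = TRUE) {
  sc <- as.character(seedling_class)
  mc <- as.character(mature_class)
  so <- as.character(saprophyte_outcome)
  if (is.na(sc) || is.na(mc) || is.na(so)) {
    warning("missing assay outcome; returning Unclassified")
    return("Unclassified")
  }
  if (!so %in% c("sporulating", "sterile_hyphae_only", "no_growth")) {
    stop("unknown saprophyte outcome: ", so)
  }
  if (sc %in% c("Pathogen", "Strong Pathogen") || mc == "Strong Pathogen") {
    return("Pathogen")
  }
  if (so == "sporulating") return("Saprophyte")
  if (so == "sterile_hyphae_only") return("Endophyte")
  if (so == "no_growth" && from_living_tissue) return("Endophyte")
  "Unclassified"
}

#' Summarise saprophyte-assay outcomes
#'
#' @param outcomes data.frame with columns \code{isolate_id} and
#'   \code{outcome} (sporulating / sterile_hyphae_only / no_growth), one row
#'   per isolate.
#' @return list with \code{tallies} (named integer vector),
#'   \code{n_total}, and \code{sporulating_fraction} (isolates completing
#'   their life cycle on dead tissue / total).
#' @export
saprophyte_summary <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("no saprophyte outcomes supplied")
  if (anyDuplicated(outcomes$isolate_id)) {
    stop("duplicate isolate ids: ",
         paste(unique(outcomes$isolate_id[duplicated(outcomes$isolate_id)]),
               collapse = ", "))
  }
  lev <- c("sporulating", "sterile_hyphae_only", "no_growth")
  if (!all(outcomes$outcome %in% lev)) {
    stop("unknown outcome value(s): ",
         paste(setdiff(unique(outcomes$outcome), lev), collapse = ", "))
  }
  tal <- table(factor(outcomes$outcome, levels = lev))
  list(tallies = stats::setNames(as.integer(tal), lev),
       n_total = nrow(outcomes),
       sporulating_fraction = as.integer(tal["sporulating"]) / nrow(outcomes))
}
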