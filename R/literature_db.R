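#' @name literature_db
#' @title Literature microbe-report modelling
#' @description
#' A literature report is one record of a microbe identified on, in, or near a
#' common-reed plant: taxon name and rank, microbial group, optional UNITE
#' species-hypothesis (SH) code, study identity, culture dependence, geography
#' (continent/country/region hint, optional coordinates and collection year),
#' optional author-stated host lineage, and tissue of origin. The functions in
#' this file implement the classification, filtering and overlap rules used in
#' the meta-analysis.
NULL

lineage_levels <- c("americanus", "australis", "altissimus", "gulf_excluded", "uncertain")
continent_levels <- c("north_america", "south_america", "europe", "asia",
                      "africa", "australia")
microbe_groups <- c("fungus", "oomycete", "bacterium", "archaeon", "virus")

# Mediterranean-basin countries hosting the altissimus lineage
altissimus_countries <- c("spain", "portugal", "italy", "egypt", "morocco")

# Curated central/western states & provinces, used when no longitude is given.
# The native-range boundary is operationalized as longitude west of -85.
central_western_na <- c(
  "michigan", "wisconsin", "illinois", "indiana", "minnesota", "iowa",
  "missouri", "kansas", "nebraska", "north dakota", "south dakota",
  "oklahoma", "texas", "colorado", "wyoming", "montana", "idaho", "utah",
  "nevada", "arizona", "new mexico", "california", "oregon", "washington",
  "manitoba", "saskatchewan", "alberta", "british columbia"
)

#' Assign a host-plant lineage to a literature report
#'
#' Applies the geographic/temporal lineage rules with a fixed precedence:
#' \enumerate{
#'   \item an author-stated lineage always wins;
#'   \item the Gulf lineage (an interspecific hybrid) is excluded
#'     (\code{"gulf_excluded"});
#'   \item central/western North American reports collected before 1910
#'     predate the invasion and are the native \code{"americanus"};
#'   \item Spain, Portugal, Italy, Egypt and Morocco carry the Mediterranean
#'     \code{"altissimus"} lineage;
#'   \item Romania is \code{"uncertain"} (hybrid zone);
#'   \item all remaining European, Asian, Australian and African reports are
#'     assumed \code{"australis"}.
#' }
#' "Central/western" is decided by longitude < \code{west_of} when coordinates
#' exist, else by a curated state/province list matched against
#' \code{region_hint}.
#'
#' @param continent one of north_america, south_america, europe, asia, africa,
#'   australia (required).
#' @param country country name (case-insensitive), optional.
#' @param region_hint free-text state/province hint, optional.
#' @param collection_year optional calendar year.
#' @param stated_lineage author-stated lineage, optional; \code{"gulf"} maps
#'   to \code{"gulf_excluded"}.
#' @param longitude optional decimal degrees (negative = west).
#' @param west_of longitude boundary for central/western North America
#'   (default -85).
#' @return one of \code{americanus}, \code{australis}, \code{altissimus},
#'   \code{gulf_excluded}, \code{uncertain}.
#' @examples
#' assign_lineage("north_america", region_hint = "Michigan",
#'                collection_year = 1905) # americanus
#' assign_lineage("europe", country = "Spain") # altissimus
#' @export
assign_lineage <- function(continent, country = NA, region_hint = NA,
                           collection_year = NA, stated_lineage = NA,
                           longitude = NA, west_of = -85) {
  if (is.na(continent) || !nzchar(continent)) stop("continent is required")
  continent <- tolower(continent)
  if (!continent %in% continent_levels) {
    stop("unknown continent: ", continent)
  }
  if (!is.na(stated_lineage) && nzchar(stated_lineage)) {
    sl <- tolower(stated_lineage)
    if (sl %in% c("gulf", "gulf_excluded")) return("gulf_excluded")
    if (sl %in% lineage_levels) return(sl)
    warning("unrecognized stated lineage '", stated_lineage, "'; falling back to geography")
  }
  cn <- if (is.na(country)) "" else tolower(trimws(country))
  if (continent == "north_america") {
    cw <- if (!is.na(longitude)) {
      longitude < west_of
    } else if (!is.na(region_hint) && nzchar(region_hint)) {
      tolower(trimws(region_hint)) %in% central_western_na
    } else {
      FALSE
    }
    if (cw && !is.na(collection_year) && collection_year < 1910) {
      return("americanus")
    }
    return("australis")
  }
  if (continent == "europe") {
    if (cn %in% altissimus_countries) return("altissimus")
    if (cn == "romania") return("uncertain")
    return("australis")
  }
  if (cn %in% altissimus_countries) return("altissimus") # Egypt/Morocco in Africa
  if (continent %in% c("asia", "africa", "australia")) return("australis")
  # South America: no rule given; flagged uncertain
  warning("no lineage rule for continent '", continent, "'; returning uncertain")
  "uncertain"
}

# built-in tissue synonym dictionary; users can extend via normalize_tissue()
default_tissue_synonyms <- function() {
  c(
    "leaf" = "leaf", "leaves" = "leaf", "leaf blade" = "leaf",
    "leaf lamina" = "leaf", "lamina" = "leaf", "foliage" = "leaf",
    "sheath" = "sheath", "leaf sheath" = "sheath",
    "stem" = "stem", "culm" = "stem", "shoot" = "stem", "stalk" = "stem",
    "seed" = "seed", "seeds" = "seed", "caryopsis" = "seed", "grain" = "seed",
    "inflorescence" = "inflorescence", "panicle" = "inflorescence",
    "flower" = "inflorescence", "spikelet" = "inflorescence",
    "root" = "root_associated", "roots" = "root_associated",
    "rhizome" = "root_associated", "rhizomes" = "root_associated",
    "root mixture" = "root_associated", "primary root" = "root_associated",
    "secondary root" = "root_associated", "adventitious root" = "root_associated",
    "rhizosphere" = "rhizosphere_soil", "rhizosphere soil" = "rhizosphere_soil",
    "soil" = "rhizosphere_soil"
  )
}

tissue_levels <- c("leaf", "sheath", "stem", "seed", "inflorescence",
                   "root_associated", "rhizosphere_soil")

#' Normalize a free-text tissue description
#'
#' Maps free text to the closed tissue vocabulary (leaf, sheath, stem, seed,
#' inflorescence, root_associated, rhizosphere_soil). Reports from roots and
#' rhizomes are merged into a single root-associated category because the
#' underground organs are rarely described precisely enough to separate them.
#' Unknown terms raise an error naming the term; there is no silent catch-all
#' bucket.
#'
#' @param raw character vector of tissue descriptions.
#' @param synonyms named character vector mapping lower-case terms to
#'   categories; defaults to the built-in dictionary. A two-column data.frame
#'   (term, category) is also accepted.
#' @return character vector of tissue categories.
#' @examples
#' normalize_tissue(c("rhizome", "leaf blade", "culm"))
#' @export
normalize_tissue <- function(raw, synonyms = default_tissue_synonyms()) {
  if (is.data.frame(synonyms)) {
    synonyms <- stats::setNames(as.character(synonyms[[2]]),
                                tolower(trimws(as.character(synonyms[[1]]))))
  }
  if (!all(synonyms %in% tissue_levels)) {
    stop("synonym table maps to unknown categories: ",
         paste(setdiff(unique(synonyms), tissue_levels), collapse = ", "))
  }
  key <- tolower(trimws(raw))
  out <- synonyms[key]
  if (any(is.na(out))) {
    stop("unmapped tissue term(s): ",
         paste(unique(raw[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Compartment (phyllosphere/rhizosphere/soil) of a tissue category
#'
#' @param tissue character vector of normalized tissue categories.
#' @return "phyllosphere" for above-ground organs, "rhizosphere" for
#'   root-associated tissue, "soil" for rhizosphere soil.
#' @export
tissue_compartment <- function(tissue) {
  ifelse(tissue == "rhizosphere_soil", "soil",
         ifelse(tissue == "root_associated", "rhizosphere", "phyllosphere"))
}

# canonical taxon identity: SH code when present, else whitespace/case
# normalized name (synonymy resolution is out of scope)
taxon_key <- function(taxon_name, sh_code = NA) {
  sh <- !is.na(sh_code) & nzchar(trimws(as.character(sh_code)))
  name <- tolower(gsub("\\s+", " ", trimws(taxon_name)))
  ifelse(sh, trimws(as.character(sh_code)), name)
}

#' Restrict reports to species-level identifications
#'
#' Keeps reports identified fully to species OR carrying a UNITE species
#' hypothesis (SH) code, which serves as a species proxy for unnamed taxa.
#'
#' @param reports data.frame with at least \code{taxonomic_rank} and
#'   \code{sh_code} columns.
#' @return list with \code{reports} (the retained subset), \code{n_retained},
#'   \code{n_total}, and \code{percent} (whole percent, half-up).
#' @examples
#' df <- data.frame(taxonomic_rank = c("species", "genus", "genus"),
#'                  sh_code = c(NA, "SH123", NA))
#' species_level_subset(df)$percent # 67
#' @export
species_level_subset <- function(reports) {
  has_sh <- !is.na(reports$sh_code) & nzchar(trimws(as.character(reports$sh_code)))
  keep <- tolower(reports$taxonomic_rank) == "species" | has_sh
  keep[is.na(keep)] <- FALSE
  list(reports = reports[keep, , drop = FALSE],
       n_retained = sum(keep),
       n_total = nrow(reports),
       percent = percent_of(sum(keep), nrow(reports)))
}

#' Filter literature reports into comparable community samples
#'
#' Applies the meta-analysis community filters: keep only culture-dependent
#' studies (culture-independent surveys are excluded to avoid methodological
#' bias), group reports by study x tissue category x microbial group, keep
#' groups with at least \code{min_isolates} reports, and tabulate each
#' surviving group into one community sample of taxon counts.
#'
#' @param reports data.frame with columns \code{study_id},
#'   \code{culture_dependent} (logical or 0/1), \code{tissue} (normalized
#'   category), \code{group} (fungus/oomycete/bacterium/archaeon/virus),
#'   \code{taxon_name}; optional \code{sh_code}, \code{continent},
#'   \code{lineage}.
#' @param min_isolates minimum reports per community (default 10).
#' @return object of class \code{phrag_communities}: list with
#'   \code{abundance} (samples x taxa count matrix) and \code{metadata}
#'   (data.frame: sample_id, study_id, tissue, group, continent, lineage,
#'   n_isolates). Zero surviving communities yields a zero-row result with a
#'   message, not an error.
#' @export
filter_communities <- function(reports, min_isolates = 10) {
  need <- c("study_id", "culture_dependent", "tissue", "group", "taxon_name")
  if (!all(need %in% names(reports))) {
    stop("reports must have columns: ", paste(need, collapse = ", "))
  }
  reports <- reports[as.logical(reports$culture_dependent), , drop = FALSE]
  if (!"sh_code" %in% names(reports)) reports$sh_code <- NA
  if (nrow(reports) > 0) {
    reports$.key <- taxon_key(reports$taxon_name, reports$sh_code)
    grp <- interaction(reports$study_id, reports$tissue, reports$group, drop = TRUE)
    pieces <- split(reports, grp)
    pieces <- pieces[order(names(pieces))]
    pieces <- Filter(function(d) nrow(d) >= min_isolates, pieces)
  } else {
    pieces <- list()
  }
  if (length(pieces) == 0) {
    message("no communities survive the filters")
    return(structure(list(abundance = matrix(0, 0, 0),
                          metadata = data.frame(sample_id = character(0))),
                     class = "phrag_communities"))
  }
  all_taxa <- sort(unique(unlist(lapply(pieces, function(d) d$.key))))
  abundance <- t(vapply(pieces, function(d) {
    tab <- table(factor(d$.key, levels = all_taxa))
    as.numeric(tab)
  }, numeric(length(all_taxa))))
  colnames(abundance) <- all_taxa
  meta <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(study_id = as.character(d$study_id[1]),
               tissue = d$tissue[1], group = d$group[1],
               continent = if ("continent" %in% names(d)) as.character(d$continent[1]) else NA,
               lineage = if ("lineage" %in% names(d)) as.character(d$lineage[1]) else NA,
               n_isolates = nrow(d), stringsAsFactors = FALSE)
  }))
  meta$sample_id <- sprintf("%s|%s|%s", meta$study_id, meta$tissue, meta$group)
  rownames(abundance) <- meta$sample_id
  rownames(meta) <- NULL
  structure(list(abundance = abundance, metadata = meta),
            class = "phrag_communities")
}

#' @export
print.phrag_communities <- function(x, ...) {
  cat(sprintf("%d community samples x %d taxa\n",
              nrow(x$abundance), ncol(x$abundance)))
  if (nrow(x$metadata) > 0) print(table(x$metadata$group))
  invisible(x)
}

#' Exact region counts for 2-3 sets of taxa
#'
#' Computes the cardinality of every region of the Venn partition for two or
#' three named sets, plus pairwise shared counts and fractions. With more
#' than three sets only the pairwise output is produced (documented
#' limitation; the full 2^k lattice is rarely interpretable).
#'
#' @param sets named list of character vectors (taxon keys; duplicates are
#'   collapsed).
#' @return list with \code{regions} (named integer vector; names like
#'   \code{"A"}, \code{"A&B"} built from set names), \code{n_union},
#'   \code{n_shared_2plus} (taxa in at least two sets), and \code{pairwise}
#'   (data.frame: set_a, set_b, shared, frac_a, frac_b).
#' @examples
#' taxon_overlap(list(NA_ = c("a", "b", "c", "d"), EU = c("c", "d", "e")))
#' @export
taxon_overlap <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  sets <- lapply(sets, unique)
  k <- length(sets)
  nm <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, nm))
  n_shared <- sum(rowSums(member) >= 2)
  pairs <- utils::combn(k, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    shared <- length(intersect(sets[[i1]], sets[[i2]]))
    data.frame(set_a = nm[i1], set_b = nm[i2], shared = shared,
               frac_a = shared / length(sets[[i1]]),
               frac_b = shared / length(sets[[i2]]),
               stringsAsFactors = FALSE)
  }))
  regions <- NULL
  if (k <= 3) {
    pattern <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
    all_regions <- unlist(lapply(seq_len(k), function(m) {
      apply(utils::combn(nm, m), 2, paste, collapse = "&")
    }))
    regions <- stats::setNames(integer(length(all_regions)), all_regions)
    tab <- table(pattern)
    regions[names(tab)] <- as.integer(tab)
  }
  list(regions = regions, n_union = length(universe),
       n_shared_2plus = n_shared, pairwise = pairwise)
}

#' Fraction of reported taxa present in an isolate collection
#'
#' @param collection_taxa character vector of taxon keys held in culture.
#' @param reported_taxa character vector (or named list of vectors, e.g. per
#'   group or region) of taxa reported in the literature.
#' @return for a vector: list with \code{n_shared}, \code{n_reported},
#'   \code{fraction}, \code{percent}; for a list: data.frame with one row per
#'   element.
#' @examples
#' collection_coverage(letters[1:5], letters[1:20])$percent # 25
#' @export
collection_coverage <- function(collection_taxa, reported_taxa) {
  one <- function(reported) {
    reported <- unique(reported)
    if (length(reported) == 0) stop("reported taxon set is empty")
    shared <- length(intersect(unique(collection_taxa), reported))
    list(n_shared = shared, n_reported = length(reported),
         fraction = shared / length(reported),
         percent = percent_of(shared, length(reported)))
  }
  if (is.list(reported_taxa) && !is.data.frame(reported_taxa)) {
    do.call(rbind, lapply(names(reported_taxa), function(nm) {
      r <- one(reported_taxa[[nm]])
      data.frame(set = nm, n_shared = r$n_shared, n_reported = r$n_reported,
                 fraction = r$fraction, percent = r$percent,
                 stringsAsFactors = FALSE)
    }))
  } else {
    one(reported_taxa)
  }
}
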