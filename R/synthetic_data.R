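#' @name synthetic_data
#' @title Seed-deterministic synthetic bioassay and literature data
#' @description
#' Generators emulating the statistical structure of the study's raw data:
#' linear-in-time seedling disease progression scored as ordered leaf
#' categories with death truncation, mature-leaf lesion scores in
#' {0, 0.5, 1}, saprophyte outcomes, and literature report tables with
#' continental taxon pools, controlled overlap, and study/tissue structure.
#' Every generator is driven entirely by the seed in its config: the same
#' config yields identical output, and the global RNG state is never
#' disturbed. Class-mixture defaults echo the study's printed margins
#' (162 isolates; 2 strong / 20 weak / 140 nonpathogenic) as a familiar
#' fixture, not as a reproduction of the real data.
NULL

#' Configuration for the seedling-assay generator
#'
#' @param seed integer RNG seed.
#' @param n_isolates number of isolates (default 162).
#' @param class_mix named proportions for strong/weak/nonpathogen (defaults
#'   2/162, 20/162, 140/162).
#' @param slope_ranges list of c(min, max) true disease-progression slopes
#'   (index units/day) per class. Defaults give 10-day indices of 4.1--7 for
#'   strong pathogens, 0.5--2 for weak ones, and at most 0.03 (the chlorosis
#'   floor) for nonpathogens.
#' @param days observation days (default 4, 8, 12, 16); days beyond the
#'   16-day cutoff may be added to exercise the exclusion rule.
#' @param n_replicates replicates per isolate (default 3).
#' @param plants_per_replicate range of plants pressed per replicate
#'   (default 4--14).
#' @param leaf_rate mean leaf-production rate per plant (leaves/day,
#'   default 0.5).
#' @param noise logical; \code{FALSE} distributes leaves deterministically to
#'   the two categories bracketing the latent index, \code{TRUE} (default)
#'   draws the split binomially so the index is unbiased.
#' @param overdispersion beta-binomial overdispersion in (0, 1); 0 = pure
#'   binomial.
#' @return a \code{seedling_sim_config} list.
#' @export
seedling_sim_config <- function(seed = 1,
                                n_isolates = 162,
                                class_mix = c(strong = 2, weak = 20,
                                              nonpathogen = 140) / 162,
                                slope_ranges = list(strong = c(0.41, 0.70),
                                                    weak = c(0.05, 0.20),
                                                    nonpathogen = c(0, 0.003)),
                                days = c(4, 8, 12, 16),
                                n_replicates = 3,
                                plants_per_replicate = c(4, 14),
                                leaf_rate = 0.5,
                                noise = TRUE,
                                overdispersion = 0) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (any(unlist(slope_ranges) < 0)) stop("slope ranges must be non-negative")
  if (overdispersion < 0 || overdispersion >= 1) stop("overdispersion must be in [0, 1)")
  structure(as.list(environment()), class = "seedling_sim_config")
}

# split n leaves between categories floor(di) and floor(di)+1 so the
# expected index equals di; binomial when noisy, rounded when not
leaf_split <- function(n, di, noise, overdispersion) {
  di <- min(max(di, 0), 4)
  k <- floor(di)
  frac <- di - k
  if (k == 4) { k <- 3; frac <- 1 }
  m <- if (!noise) {
    round_half_up(frac * n, 0)
  } else if (overdispersion > 0 && frac > 0 && frac < 1) {
    shape <- (1 - overdispersion) / overdispersion
    stats::rbinom(1, n, stats::rbeta(1, frac * shape, (1 - frac) * shape))
  } else {
    stats::rbinom(1, n, frac)
  }
  counts <- integer(5)
  counts[k + 1] <- n - m
  counts[k + 2] <- m
  counts
}

#' Simulate a seedling-assay observation table
#'
#' Each replicate carries a latent disease trajectory DI(t) = min(4, beta t)
#' with beta drawn from its class's slope range. At each observation day the
#' replicate's leaves are distributed between the two ordinal categories
#' bracketing the latent index, so the count-weighted index is an unbiased
#' estimate of DI(t). Once the trajectory reaches 4 the plants are dead and
#' stay dead. Total leaf count follows the plant growth rate (truncated once
#' dead).
#'
#' @param config a \code{\link{seedling_sim_config}}.
#' @return list with \code{observations} (the seedling CSV schema:
#'   isolate_id, lineage, replicate, day, n0..n4) and \code{truth}
#'   (isolate_id, replicate, class, slope, di10 = min(4, 10 beta),
#'   growth_rate).
#' @export
simulate_seedling_assay <- function(config) {
  stopifnot(inherits(config, "seedling_sim_config"))
  with_seed(config$seed, {
    classes <- sample(names(config$class_mix), config$n_isolates,
                      replace = TRUE, prob = config$class_mix)
    obs <- list(); truth <- list()
    for (i in seq_len(config$n_isolates)) {
      iso <- sprintf("ISO%03d", i)
      rng <- config$slope_ranges[[classes[i]]]
      for (r in seq_len(config$n_replicates)) {
        beta <- stats::runif(1, rng[1], rng[2])
        n_plants <- sample(config$plants_per_replicate[1]:config$plants_per_replicate[2], 1)
        grate <- config$leaf_rate * n_plants
        dead_after <- if (beta > 0) 4 / beta else Inf
        rows <- lapply(config$days, function(t) {
          n_leaves <- max(1, round(grate * min(t, dead_after)))
          di_t <- min(4, beta * t)
          cc <- leaf_split(n_leaves, di_t, config$noise, config$overdispersion)
          data.frame(isolate_id = iso, lineage = "australis", replicate = r,
                     day = t, n0 = cc[1], n1 = cc[2], n2 = cc[3],
                     n3 = cc[4], n4 = cc[5], stringsAsFactors = FALSE)
        })
        obs[[length(obs) + 1]] <- do.call(rbind, rows)
        truth[[length(truth) + 1]] <- data.frame(
          isolate_id = iso, replicate = r, class = classes[i],
          slope = beta, di10 = min(4, 10 * beta), growth_rate = grate,
          stringsAsFactors = FALSE)
      }
    }
    list(observations = do.call(rbind, obs), truth = do.call(rbind, truth))
  })
}

#' Configuration for the mature-leaf assay generator
#'
#' @param seed integer RNG seed.
#' @param n_isolates number of isolates (default 162).
#' @param class_mix as in \code{\link{seedling_sim_config}}.
#' @param lesion_probs list of per-class probabilities over section scores
#'   {0, 0.5, 1} (abraded leaves; intact leaves never develop lesions, the
#'   cuticle being an effective barrier).
#' @param replicates_range replicate sections per isolate (default 3--7).
#' @return a \code{mature_sim_config} list.
#' @export
mature_sim_config <- function(seed = 1,
                              n_isolates = 162,
                              class_mix = c(strong = 2, weak = 20,
                                            nonpathogen = 140) / 162,
                              lesion_probs = list(
                                strong = c(0.05, 0.20, 0.75),
                                weak = c(0.55, 0.35, 0.10),
                                nonpathogen = c(0.95, 0.05, 0)),
                              replicates_range = c(3, 7)) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  for (p in lesion_probs) {
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("each lesion_probs entry must be 3 probabilities summing to 1")
    }
  }
  structure(as.list(environment()), class = "mature_sim_config")
}

#' Simulate a mature-leaf assay section table
#'
#' Abraded-leaf section scores are drawn from the class-specific multinomial
#' over {0, 0.5, 1}; intact (non-abraded) sections are always 0.
#'
#' @param config a \code{\link{mature_sim_config}}.
#' @return list with \code{sections} (isolate_id, lineage, abraded,
#'   section_score) and \code{truth} (isolate_id, class, expected_score =
#'   p(0.5)/2 + p(1)).
#' @export
simulate_mature_assay <- function(config) {
  stopifnot(inherits(config, "mature_sim_config"))
  with_seed(config$seed, {
    classes <- sample(names(config$class_mix), config$n_isolates,
                      replace = TRUE, prob = config$class_mix)
    sections <- list(); truth <- list()
    for (i in seq_len(config$n_isolates)) {
      iso <- sprintf("ISO%03d", i)
      p <- config$lesion_probs[[classes[i]]]
      nrep <- sample(config$replicates_range[1]:config$replicates_range[2], 1)
      sc <- sample(c(0, 0.5, 1), nrep, replace = TRUE, prob = p)
      sections[[length(sections) + 1]] <- data.frame(
        isolate_id = iso, lineage = "australis",
        abraded = rep(c(TRUE, FALSE), c(nrep, nrep)),
        section_score = c(sc, rep(0, nrep)), stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- data.frame(
        isolate_id = iso, class = classes[i],
        expected_score = p[2] * 0.5 + p[3], n_sections = nrep,
        stringsAsFactors = FALSE)
    }
    list(sections = do.call(rbind, sections), truth = do.call(rbind, truth))
  })
}

#' Configuration for the literature-report generator
#'
#' Defaults echo the meta-analysis margins: three well-sampled continents,
#' 119 studies of which a 98/119 fraction are culture-dependent, and 34 taxa
#' shared between two or more continents.
#'
#' @param seed integer RNG seed.
#' @param continents continents with taxon pools.
#' @param unique_taxa named count of continent-private taxa.
#' @param n_shared taxa occurring on >= 2 continents (default 34).
#' @param n_studies total studies (default 119).
#' @param culture_dependent_fraction fraction of culture-dependent studies
#'   (default 98/119).
#' @param isolates_per_study mean reports per study x tissue community
#'   (Poisson; default 18).
#' @param tissues tissue categories sampled per study.
#' @param group_probs mix of microbial groups among fungal-dominated reports.
#' @param species_level_fraction fraction of reports identified to species
#'   (default 0.27 echoes the 2829/10514 subset).
#' @param sh_fraction fraction of non-species reports that carry an SH code.
#' @param year_range collection years.
#' @return a \code{literature_sim_config} list.
#' @export
literature_sim_config <- function(seed = 1,
                                  continents = c("north_america", "europe", "asia"),
                                  unique_taxa = c(north_america = 234,
                                                  europe = 278, asia = 30),
                                  n_shared = 34,
                                  n_studies = 119,
                                  culture_dependent_fraction = 98 / 119,
                                  isolates_per_study = 18,
                                  tissues = c("leaf", "sheath", "stem",
                                              "root_associated", "rhizosphere_soil"),
                                  group_probs = c(fungus = 0.8,
                                                  bacterium = 0.12,
                                                  oomycete = 0.08),
                                  species_level_fraction = 0.27,
                                  sh_fraction = 0.5,
                                  year_range = c(1880, 2019)) {
  if (n_shared < 0) stop("n_shared must be non-negative")
  if (culture_dependent_fraction < 0 || culture_dependent_fraction > 1) {
    stop("culture_dependent_fraction must lie in [0, 1]")
  }
  if (species_level_fraction < 0 || species_level_fraction > 1) {
    stop("shared fraction must lie in [0, 1]")
  }
  if (!all(names(unique_taxa) %in% continents)) {
    stop("unique_taxa names must match continents")
  }
  structure(as.list(environment()), class = "literature_sim_config")
}

continent_countries <- list(
  north_america = c("USA", "Canada"),
  europe = c("Germany", "Poland", "Netherlands", "Spain", "Italy", "Romania",
             "United Kingdom", "Sweden"),
  asia = c("China", "Japan", "South Korea")
)

#' Simulate a literature microbe-report table
#'
#' Builds continental taxon pools with exactly \code{n_shared} taxa present on
#' two or more continents, then samples studies (continent, country, year,
#' culture dependence) and per-study tissue communities whose reports draw
#' from the continental pool. Taxon ranks and SH codes are assigned so a
#' configurable fraction of reports is species-level identifiable.
#'
#' @param config a \code{\link{literature_sim_config}}.
#' @return list with \code{reports} (report_id, taxon_name, taxonomic_rank,
#'   group, sh_code, study_id, culture_dependent, continent, country,
#'   collection_year, tissue, tissue_alive) and \code{truth} (taxon pools per
#'   continent, n_shared_2plus, expected community count at the 10-isolate
#'   filter).
#' @export
simulate_literature <- function(config) {
  stopifnot(inherits(config, "literature_sim_config"))
  with_seed(config$seed, {
    k <- length(config$continents)
    # continental pools: private taxa plus shared taxa on >= 2 continents
    pools <- lapply(config$continents, function(cn) {
      n <- config$unique_taxa[[cn]]
      if (n > 0) sprintf("%s_taxon_%03d", cn, seq_len(n)) else character(0)
    })
    names(pools) <- config$continents
    if (config$n_shared > 0) {
      for (s in seq_len(config$n_shared)) {
        nm <- sprintf("shared_taxon_%03d", s)
        n_on <- if (k >= 3) sample(2:k, 1) else 2
        on <- sample(config$continents, n_on)
        for (cn in on) pools[[cn]] <- c(pools[[cn]], nm)
      }
    }
    # species-level identity: a fixed per-taxon rank so identity is stable
    all_taxa <- unique(unlist(pools))
    is_species <- stats::runif(length(all_taxa)) < config$species_level_fraction
    has_sh <- !is_species & stats::runif(length(all_taxa)) < config$sh_fraction
    rank_of <- stats::setNames(ifelse(is_species, "species", "genus"), all_taxa)
    sh_of <- stats::setNames(ifelse(has_sh,
                                    sprintf("SH%07d.08FU", seq_along(all_taxa)),
                                    NA_character_), all_taxa)
    n_cd <- round(config$n_studies * config$culture_dependent_fraction)
    cd <- sample(rep(c(TRUE, FALSE),
                     c(n_cd, config$n_studies - n_cd)))
    rows <- list()
    rid <- 0
    for (s in seq_len(config$n_studies)) {
      cn <- sample(config$continents, 1)
      country <- sample(continent_countries[[cn]], 1)
      year <- sample(config$year_range[1]:config$year_range[2], 1)
      study_tissues <- sample(config$tissues, sample(1:3, 1))
      for (tis in study_tissues) {
        n_iso <- stats::rpois(1, config$isolates_per_study)
        if (n_iso == 0) next
        grp <- sample(names(config$group_probs), 1, prob = config$group_probs)
        taxa <- sample(pools[[cn]], n_iso, replace = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          report_id = sprintf("R%06d", rid + seq_len(n_iso)),
          taxon_name = taxa,
          taxonomic_rank = unname(rank_of[taxa]),
          group = grp,
          sh_code = unname(sh_of[taxa]),
          study_id = sprintf("S%03d", s),
          culture_dependent = cd[s],
          continent = cn, country = country,
          collection_year = year,
          tissue = tis, tissue_alive = TRUE,
          stringsAsFactors = FALSE)
        rid <- rid + n_iso
      }
    }
    reports <- do.call(rbind, rows)
    rownames(reports) <- NULL
    # generator-side truth for the community filter
    comm_sizes <- stats::aggregate(
      list(n = reports$report_id),
      by = list(study = reports$study_id, tissue = reports$tissue,
                group = reports$group, cd = reports$culture_dependent),
      FUN = length)
    n_comm <- sum(comm_sizes$cd & comm_sizes$n >= 10)
    shared_names <- grep("^shared_taxon_", all_taxa, value = TRUE)
    list(reports = reports,
         truth = list(pools = pools,
                      n_shared_2plus = length(shared_names),
                      shared_taxa = shared_names,
                      n_communities = n_comm))
  })
}

#' Simulate community abundance matrices with an optional group effect
#'
#' Small helper emulating the structure behind the dissimilarity/PerMANOVA
#' comparisons: log-normal taxon abundances per sample, with a configurable
#' multiplicative shift applied to a subset of taxa in one group. Effect 0
#' yields exchangeable groups (the null).
#'
#' @param n_per_group samples in each of two groups.
#' @param n_taxa number of taxa.
#' @param effect log-scale mean shift applied to half the taxa in group B
#'   (default 0).
#' @param seed RNG seed.
#' @return list with \code{abundance} (matrix, rownames encode the group) and
#'   \code{groups}.
#' @export
simulate_communities <- function(n_per_group = 5, n_taxa = 40, effect = 0,
                                 seed = 1) {
  with_seed(seed, {
    n <- 2 * n_per_group
    base_mu <- stats::rnorm(n_taxa, 0, 1)
    shift <- c(rep(effect, n_taxa %/% 2), rep(0, n_taxa - n_taxa %/% 2))
    ab <- t(vapply(seq_len(n), function(i) {
      mu <- base_mu + if (i > n_per_group) shift else 0
      stats::rlnorm(n_taxa, mu, 0.6)
    }, numeric(n_taxa)))
    rownames(ab) <- c(sprintf("A%02d", seq_len(n_per_group)),
                      sprintf("B%02d", seq_len(n_per_group)))
    colnames(ab) <- sprintf("taxon%03d", seq_len(n_taxa))
    list(abundance = ab, groups = rep(c("A", "B"), each = n_per_group))
  })
}
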