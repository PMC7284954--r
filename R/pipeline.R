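#' Vectorized lineage assignment over a report table
#'
#' Applies \code{\link{assign_lineage}} row-wise to a literature report table,
#' using whichever of the optional columns (country, region_hint,
#' collection_year, stated_lineage, longitude) are present.
#'
#' @param reports data.frame with at least a \code{continent} column.
#' @param west_of longitude boundary for central/western North America.
#' @return character vector of lineage labels.
#' @export
assign_lineage_table <- function(reports, west_of = -85) {
  get_col <- function(nm) {
    if (nm %in% names(reports)) reports[[nm]] else rep(NA, nrow(reports))
  }
  country <- get_col("country"); region <- get_col("region_hint")
  year <- get_col("collection_year"); stated <- get_col("host_lineage_stated")
  lon <- get_col("longitude")
  vapply(seq_len(nrow(reports)), function(i) {
    assign_lineage(reports$continent[i], country[i], region[i], year[i],
                   stated[i], lon[i], west_of = west_of)
  }, character(1))
}

#' Pipeline run configuration
#'
#' @param seedling,mature,saprophyte,reports data.frames (or file paths) in
#'   the schemas of the corresponding readers; any may be NULL to skip that
#'   stage.
#' @param guild_table guild lookup data.frame or TSV path (optional).
#' @param thresholds a \code{\link{classification_thresholds}} object.
#' @param n_permutations,alpha,seed statistical settings.
#' @param out_dir output directory (created if needed); NULL disables file
#'   output.
#' @return a \code{phrag_run_config} list.
#' @export
run_config <- function(seedling = NULL, mature = NULL, saprophyte = NULL,
                       reports = NULL, guild_table = NULL,
                       thresholds = classification_thresholds(),
                       n_permutations = 999, alpha = 0.05, seed = 1,
                       out_dir = NULL) {
  load_maybe <- function(x, reader) {
    if (is.character(x)) reader(x) else x
  }
  structure(list(
    seedling = load_maybe(seedling, read_seedling_table),
    mature = load_maybe(mature, read_mature_table),
    saprophyte = load_maybe(saprophyte, read_saprophyte_table),
    reports = load_maybe(reports, read_report_table),
    guild_table = load_maybe(guild_table, read_guild_table),
    thresholds = thresholds, n_permutations = n_permutations,
    alpha = alpha, seed = seed, out_dir = out_dir
  ), class = "phrag_run_config")
}

#' Run the full scoring and meta-analysis pipeline
#'
#' Executes, as configured: seedling scoring and classification; mature-leaf
#' scoring; paired between-lineage comparison with Bonferroni correction
#' (when isolates were assayed on both lineages); saprophyte summary and
#' experimental trophic classes; literature filtering, per-continent taxon
#' overlap, community Bray-Curtis + PerMANOVA, species-level subset, and
#' guild-predicted trophic ratios. Results are returned as a nested list and,
#' when \code{out_dir} is set, written as a JSON summary, TSV tables and a
#' plain-text log recording the package version, seed and thresholds.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisible list of stage results (also the JSON summary content).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "phrag_run_config"))
  th <- config$thresholds
  out <- list(meta = list(
    package = "phragpath",
    version = as.character(utils::packageVersion("phragpath")),
    seed = config$seed,
    alpha = config$alpha,
    n_permutations = config$n_permutations,
    thresholds = unclass(th)
  ))

  if (!is.null(config$seedling)) {
    scored <- tryCatch(score_seedling_assay(config$seedling, th),
                       error = function(e) abort_stage("score-seedling", conditionMessage(e)))
    out$seedling <- list(
      table = scored,
      class_counts = as.list(table(scored$seedling_class)),
      n_isolates = length(unique(scored$isolate_id)),
      n_pathogenic = count_above_threshold(scored$standardized_di,
                                           th$seedling_pathogen_min)
    )
    lineages <- unique(scored$lineage)
    if (length(lineages) >= 2) {
      wide <- stats::reshape(scored[, c("isolate_id", "lineage", "standardized_di")],
                             idvar = "isolate_id", timevar = "lineage",
                             direction = "wide")
      a <- wide[[paste0("standardized_di.", lineages[1])]]
      b <- wide[[paste0("standardized_di.", lineages[2])]]
      ok <- stats::complete.cases(a, b)
      if (sum(ok) >= 2) {
        tt <- paired_t_test(a[ok], b[ok])
        out$seedling$lineage_comparison <- c(tt, list(
          lineages = lineages[1:2],
          bonferroni = bonferroni(tt$p_value, config$alpha)))
      }
    }
  }

  if (!is.null(config$mature)) {
    mscored <- tryCatch(score_mature_assay(config$mature, th),
                        error = function(e) abort_stage("score-mature", conditionMessage(e)))
    abr <- mscored[mscored$abraded, , drop = FALSE]
    out$mature <- list(
      table = mscored,
      class_counts_abraded = as.list(table(abr$mature_class)),
      n_isolates = length(unique(mscored$isolate_id)),
      n_lesion_inducers = sum(abr$mean_lesion_score >= th$seedling_weak_min),
      percent_lesion_inducers = if (nrow(abr) > 0) {
        percent_of(sum(abr$mean_lesion_score >= th$seedling_weak_min), nrow(abr))
      } else NA
    )
  }

  if (!is.null(config$saprophyte)) {
    out$saprophyte <- tryCatch(saprophyte_summary(config$saprophyte),
                               error = function(e) abort_stage("saprophyte", conditionMessage(e)))
    if (!is.null(out$seedling) && !is.null(out$mature)) {
      scored <- out$seedling$table
      abr <- out$mature$table[out$mature$table$abraded, , drop = FALSE]
      ids <- Reduce(intersect, list(scored$isolate_id, abr$isolate_id,
                                    config$saprophyte$isolate_id))
      if (length(ids) > 0) {
        cls <- vapply(ids, function(id) {
          experimental_trophic_class(
            as.character(scored$seedling_class[match(id, scored$isolate_id)]),
            as.character(abr$mature_class[match(id, abr$isolate_id)]),
            config$saprophyte$outcome[match(id, config$saprophyte$isolate_id)])
        }, character(1))
        counts <- table(factor(cls, levels = c("Pathogen", "Endophyte",
                                               "Saprophyte", "Unclassified")))
        out$trophic_experimental <- list(
          classes = stats::setNames(as.character(cls), ids),
          counts = as.list(counts),
          ratio = trophic_ratio(counts[["Pathogen"]], counts[["Endophyte"]],
                                counts[["Saprophyte"]]))
      }
    }
  }

  if (!is.null(config$reports)) {
    rep_tab <- config$reports
    sl <- species_level_subset(rep_tab)
    out$literature <- list(species_level = sl[c("n_retained", "n_total", "percent")])
    keys <- taxon_key(sl$reports$taxon_name, sl$reports$sh_code)
    sets <- split(keys, sl$reports$continent)
    sets <- lapply(sets, unique)
    if (length(sets) >= 2) {
      out$literature$overlap_by_continent <-
        taxon_overlap(sets[seq_len(min(3, length(sets)))])
    }
    comm <- filter_communities(rep_tab)
    out$literature$n_communities <- nrow(comm$abundance)
    if (nrow(comm$abundance) >= 3 &&
        length(unique(comm$metadata$continent)) >= 2) {
      keep <- !is.na(comm$metadata$continent)
      grp <- comm$metadata$continent[keep]
      if (length(unique(grp)) >= 2 && sum(keep) - length(unique(grp)) > 0) {
        d <- bray_curtis_matrix(comm$abundance[keep, , drop = FALSE])
        pm <- permanova(d, grp, config$n_permutations, config$seed)
        out$literature$permanova_continent <- pm[c("pseudo_F", "r_squared",
                                                   "p_value", "n_permutations",
                                                   "seed")]
      }
    }
    if (!is.null(config$guild_table)) {
      fungi <- rep_tab[rep_tab$group == "fungus", , drop = FALSE]
      modes <- assign_guild(unique(fungi$taxon_name), config$guild_table)
      has <- function(m, what) grepl(what, m, ignore.case = TRUE)
      p <- sum(has(modes, "pathotroph")); e <- sum(has(modes, "symbiotroph"))
      s <- sum(has(modes, "saprotroph"))
      out$literature$trophic_predicted <- list(
        n_assigned = sum(modes != "unassigned"),
        ratio = trophic_ratio(p, e, s))
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    summary_out <- strip_tables(out)
    validate_summary(summary_out)
    jsonlite::write_json(summary_out, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    if (!is.null(out$seedling)) {
      utils::write.table(out$seedling$table,
                         file.path(config$out_dir, "seedling_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(out$mature)) {
      utils::write.table(out$mature$table,
                         file.path(config$out_dir, "mature_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(c(
      sprintf("phragpath %s", out$meta$version),
      sprintf("R %s", getRversion()),
      sprintf("seed %d, permutations %d, alpha %g",
              config$seed, config$n_permutations, config$alpha),
      utils::capture.output(print(th))
    ), file.path(config$out_dir, "run.log"))
  }
  invisible(out)
}

# drop large embedded tables before JSON serialization
strip_tables <- function(out) {
  if (!is.null(out$seedling)) out$seedling$table <- NULL
  if (!is.null(out$mature)) out$mature$table <- NULL
  out
}

#' Validate a pipeline summary against the published schema
#'
#' A lightweight structural check against
#' \code{inst/schema/summary.schema.json}: required top-level and meta keys
#' must be present with the declared types.
#'
#' @param summary list as produced by \code{\link{run_full_pipeline}}.
#' @return invisible TRUE, or an error describing the violation.
#' @export
validate_summary <- function(summary) {
  schema <- jsonlite::read_json(system.file("schema", "summary.schema.json",
                                            package = "phragpath"))
  req <- unlist(schema$required)
  missing <- setdiff(req, names(summary))
  if (length(missing) > 0) {
    stop("summary is missing required key(s): ", paste(missing, collapse = ", "))
  }
  meta_req <- unlist(schema$properties$meta$required)
  missing <- setdiff(meta_req, names(summary$meta))
  if (length(missing) > 0) {
    stop("summary$meta is missing required key(s): ",
         paste(missing, collapse = ", "))
  }
  if (!is.numeric(summary$meta$seed)) stop("summary$meta$seed must be numeric")
  invisible(TRUE)
}
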