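# Published seedling mean disease indices (Table 1 of the source study's
# confirmed-pathogen list), used as fixed inputs for classification tests.
table1_seedling <- data.frame(
  isolate_id = c("USGS23", "USGS32", "USGS30", "LSU0038", "USGS15", "USGS17",
                 "LSU0361", "LSU0719", "LSU0107", "LSU0172", "USGS07",
                 "LSU1247", "USGS34", "USGS42", "LSU0677", "USGS02", "LSU0240"),
  di_australis = c(6.6, 3.7, 3.5, 3.2, 2.9, 2.6, 2.6, 1.2, 0.2, 2.9, 1.7,
                   3.6, 3.1, 0.3, 4.6, 2.2, 2.3),
  di_americanus = c(5.8, 4.1, 2.2, 3.1, 2.5, 2.9, 1.6, 1.6, NA, 2.9, 2.8,
                    3.8, 2.3, 2.8, 3.7, 1.3, NA),
  stringsAsFactors = FALSE
)

# brute-force normal-equation oracle for the through-origin slope,
# independent of the package implementation
oracle_origin_slope <- function(x, y) {
  solve(t(x) %*% x, t(x) %*% y)[1, 1]
}

# reference reimplementation of the exclusion rules, used to cross-check
# fit_timecourse end to end
oracle_di10 <- function(day, di, max_day = 16, scale_max = 4) {
  keep <- day <= max_day
  dead <- which(keep & di >= scale_max)
  if (length(dead) > 2) keep[dead[-(1:2)]] <- FALSE
  x <- day[keep]; y <- di[keep]
  min(max(10 * oracle_origin_slope(cbind(x), y), 0), scale_max)
}

make_guild_table <- function() {
  data.frame(
    taxon = c("Alternaria", "Alternaria alternata", "Stagonospora",
              "Fusarium", "Cladosporium", "Pleosporaceae", "Epicoccum"),
    rank = c("genus", "species", "genus", "genus", "genus", "family", "genus"),
    trophic_mode = c("Pathotroph-Saprotroph", "Pathotroph",
                     "Pathotroph-Saprotroph-Symbiotroph", "Pathotroph",
                     "Saprotroph", "Pathotroph", "Saprotroph"),
    guild = "Plant Pathogen",
    confidence = c("probable", "highly probable", "probable", "probable",
                   "possible", "highly probable", "probable"),
    stringsAsFactors = FALSE
  )
}

# a tiny hand-countable report table: 3 studies x 2 tissues with community
# sizes {12, 10, 9, 15, 3, 11}; study S3 is culture-independent
make_report_fixture <- function() {
  sizes <- list(S1 = c(leaf = 12, stem = 10), S2 = c(leaf = 9, stem = 15),
                S3 = c(leaf = 3, stem = 11))
  cd <- c(S1 = TRUE, S2 = TRUE, S3 = FALSE)
  rows <- list()
  for (s in names(sizes)) {
    for (t in names(sizes[[s]])) {
      n <- sizes[[s]][[t]]
      rows[[paste(s, t)]] <- data.frame(
        report_id = sprintf("%s_%s_%02d", s, t, seq_len(n)),
        taxon_name = sprintf("Taxon %02d", seq_len(n) %% 6 + 1),
        taxonomic_rank = "species", group = "fungus", sh_code = NA,
        study_id = s, culture_dependent = cd[[s]],
        continent = "north_america", tissue = t, stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}
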