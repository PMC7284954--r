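#' Read a seedling-assay observation table
#'
#' CSV/TSV with columns isolate_id, lineage, replicate, day, n0..n4.
#' The delimiter is sniffed from the first line.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_seedling_table <- function(path) {
  d <- read_delim_auto(path)
  need <- c("isolate_id", "lineage", "replicate", "day", "n0", "n1", "n2", "n3", "n4")
  check_columns(d, need, "seedling table")
  d
}

#' Read a mature-leaf assay table
#'
#' CSV/TSV with columns isolate_id, lineage, abraded (0/1), section_score.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_mature_table <- function(path) {
  d <- read_delim_auto(path)
  check_columns(d, c("isolate_id", "lineage", "abraded", "section_score"),
                "mature-leaf table")
  d
}

#' Read a saprophyte-assay outcome table
#'
#' CSV/TSV with columns isolate_id, outcome (sporulating /
#' sterile_hyphae_only / no_growth).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_saprophyte_table <- function(path) {
  d <- read_delim_auto(path)
  check_columns(d, c("isolate_id", "outcome"), "saprophyte table")
  d
}

#' Read a literature microbe-report table
#'
#' TSV with the report columns (see \code{\link{filter_communities}} and
#' \code{\link{assign_lineage}} for the fields used downstream).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_report_table <- function(path) {
  d <- read_delim_auto(path)
  check_columns(d, c("taxon_name", "study_id", "continent", "tissue"),
                "report table")
  d
}

#' Read/write a square labelled distance matrix as TSV
#'
#' The format is a header row of labels and a leading label column, as
#' written by \code{write_distance_tsv}.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_distance_tsv <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  check_distance_matrix(m)
  m
}

#' @rdname read_distance_tsv
#' @param dist square matrix to write.
#' @export
write_distance_tsv <- function(dist, path) {
  check_distance_matrix(as.matrix(dist))
  utils::write.table(as.data.frame(as.matrix(dist)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

check_columns <- function(d, need, what) {
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(d)
}
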