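#' Screen barcode identification hits
#'
#' Database identification hits are screened the way the barcoding workflow
#' screens search results: keep the top \code{top_n} hits by score, then
#' retain those meeting both the length (query-coverage) and similarity
#' (percent-identity) thresholds. Retention is order-stable with respect to
#' the input.
#'
#' @param hits data.frame with columns \code{query_id}, \code{subject_name},
#'   \code{percent_identity} (0--100), \code{query_coverage} (0--1) and
#'   optionally \code{score}.
#' @param min_coverage minimum query coverage (default 0.95).
#' @param min_identity minimum percent identity (default 99.0).
#' @param top_n number of top-scoring hits considered per query (default 50).
#' @return the retained subset of \code{hits}.
#' @export
screen_hits <- function(hits, min_coverage = 0.95, min_identity = 99.0,
                        top_n = 50) {
  need <- c("query_id", "subject_name", "percent_identity", "query_coverage")
  if (!all(need %in% names(hits))) {
    stop("hits must have columns: ", paste(need, collapse = ", "))
  }
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop("percent_identity must lie in [0, 100]")
  }
  if (any(hits$query_coverage < 0 | hits$query_coverage > 1)) {
    stop("query_coverage must lie in [0, 1]")
  }
  keep_top <- unlist(lapply(split(seq_len(nrow(hits)), hits$query_id), function(idx) {
    if ("score" %in% names(hits)) {
      ord <- idx[order(-hits$score[idx])] # stable: ties keep input order
      sort(utils::head(ord, top_n))
    } else {
      utils::head(idx, top_n)
    }
  }))
  out <- hits[sort(keep_top), , drop = FALSE]
  out <- out[out$query_coverage >= min_coverage &
               out$percent_identity >= min_identity, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' WPGMA hierarchical clustering
#'
#' Weighted pair-group agglomeration with arithmetic mean: repeatedly merge
#' the closest pair of clusters, defining the distance from the merged
#' cluster to any other as the simple (unweighted by size) average of its two
#' children's distances. Node heights follow the ultrametric convention,
#' half the merge distance, so two leaves at distance d join at height d/2
#' and the cophenetic distance between leaves equals twice the height of
#' their join. Ties are broken deterministically by the lexicographically
#' smallest pair of cluster representatives (each cluster represented by its
#' smallest leaf label).
#'
#' @param dist square symmetric distance matrix with zero diagonal; labels
#'   from dimnames (defaults to L1, L2, ...).
#' @return object of class \code{phrag_wpgma}: list with \code{labels},
#'   \code{merge} (hclust convention: negative entries index leaves,
#'   positive entries earlier merges), \code{height} (ultrametric node
#'   heights, non-decreasing), \code{merge_distance} (= 2 x height).
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 6, 8, 6, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' wpgma(d)$height # 1.0, 3.5
#' @export
wpgma <- function(dist) {
  dist <- as.matrix(dist)
  check_distance_matrix(dist)
  n <- nrow(dist)
  if (n < 2) stop("need at least 2 labels")
  labels <- rownames(dist)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  d <- dist
  # active clusters: id (negative leaf / positive merge), representative label
  active <- data.frame(node = -seq_len(n), rep = labels,
                       row = seq_len(n), stringsAsFactors = FALSE)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- nrow(active)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- d[active$row[i], active$row[j]]
        pair_rep <- sort(c(active$rep[i], active$rep[j]))
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (pair_rep[1] < best$rep[1] ||
              (pair_rep[1] == best$rep[1] && pair_rep[2] < best$rep[2])))) {
          best <- list(i = i, j = j, d = dij, rep = pair_rep)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- c(active$node[i], active$node[j])
    height[step] <- best$d / 2
    # WPGMA update: average of the two children's distances
    ri <- active$row[i]; rj <- active$row[j]
    newd <- (d[ri, ] + d[rj, ]) / 2
    d[ri, ] <- newd
    d[, ri] <- newd
    d[ri, ri] <- 0
    active$node[i] <- step
    active$rep[i] <- best$rep[1]
    active <- active[-j, , drop = FALSE]
  }
  structure(list(labels = labels, merge = merge, height = height,
                 merge_distance = 2 * height),
            class = "phrag_wpgma")
}

# leaf indices under each internal node of a merge matrix
node_leaves <- function(merge) {
  out <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    kids <- merge[k, ]
    out[[k]] <- unlist(lapply(kids, function(ch) {
      if (ch < 0) -ch else out[[ch]]
    }))
  }
  out
}

#' Cophenetic distances of a WPGMA tree
#'
#' @param tree a \code{phrag_wpgma} object.
#' @return square matrix: twice the height of the lowest common merge.
#' @export
wpgma_cophenetic <- function(tree) {
  n <- length(tree$labels)
  co <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  leaves <- node_leaves(tree$merge)
  for (k in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[k, ]
    left <- if (kids[1] < 0) -kids[1] else leaves[[kids[1]]]
    right <- if (kids[2] < 0) -kids[2] else leaves[[kids[2]]]
    co[left, right] <- tree$merge_distance[k]
    co[right, left] <- tree$merge_distance[k]
  }
  co
}

#' Newick serialization of a WPGMA tree
#'
#' Branch lengths are differences of ultrametric node heights, so root-to-leaf
#' path lengths all equal the root height.
#'
#' @param tree a \code{phrag_wpgma} object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string terminated by ";".
#' @export
wpgma_newick <- function(tree, digits = 10) {
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  build <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%s", tree$labels[-node], fmt(parent_h))
    } else {
      h <- tree$height[node]
      sprintf("(%s,%s):%s",
              build(tree$merge[node, 1], h),
              build(tree$merge[node, 2], h),
              fmt(parent_h - h))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  sprintf("(%s,%s);",
          build(tree$merge[root, 1], h),
          build(tree$merge[root, 2], h))
}

#' @export
print.phrag_wpgma <- function(x, ...) {
  cat(sprintf("WPGMA tree on %d leaves; root height %.4g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Maximal monospecific clades of a WPGMA tree
#'
#' A clade is monospecific when all its leaves map to the same species name;
#' the function returns the maximal such clades (each leaf belongs to exactly
#' one), mirroring how barcoding workflows summarise a dendrogram of database
#' hits.
#'
#' @param tree a \code{phrag_wpgma} object.
#' @param species named character vector mapping leaf labels to species names.
#' @return data.frame with one row per clade: \code{species}, \code{n_leaves},
#'   and \code{leaves} (comma-separated labels).
#' @export
monospecific_clades <- function(tree, species) {
  if (!all(tree$labels %in% names(species))) {
    stop("species mapping missing for: ",
         paste(setdiff(tree$labels, names(species)), collapse = ", "))
  }
  sp <- species[tree$labels]
  leaves <- node_leaves(tree$merge)
  mono <- vapply(leaves, function(idx) length(unique(sp[idx])) == 1, logical(1))
  n_int <- nrow(tree$merge)
  # parent of each internal node
  parent <- rep(NA_integer_, n_int)
  leaf_parent <- rep(NA_integer_, length(tree$labels))
  for (k in seq_len(n_int)) {
    for (ch in tree$merge[k, ]) {
      if (ch > 0) parent[ch] <- k else leaf_parent[-ch] <- k
    }
  }
  maximal_int <- which(mono & vapply(seq_len(n_int), function(k) {
    p <- parent[k]
    is.na(p) || !mono[p]
  }, logical(1)))
  covered <- unlist(leaves[maximal_int])
  # leaves whose parent merge is not monospecific form their own clades
  singleton <- setdiff(seq_along(tree$labels), covered)
  rows <- c(
    lapply(maximal_int, function(k) {
      idx <- leaves[[k]]
      data.frame(species = unname(sp[idx[1]]), n_leaves = length(idx),
                 leaves = paste(sort(tree$labels[idx]), collapse = ","),
                 stringsAsFactors = FALSE)
    }),
    lapply(singleton, function(l) {
      data.frame(species = unname(sp[l]), n_leaves = 1L,
                 leaves = tree$labels[l], stringsAsFactors = FALSE)
    })
  )
  out <- do.call(rbind, rows)
  out[order(out$species, out$leaves), , drop = FALSE]
}

#' Fixed-threshold species-hypothesis clustering
#'
#' Single-linkage connected components of the graph joining every pair at
#' fractional dissimilarity at most \code{threshold} (default 0.015, the
#' 1.5\% species-hypothesis threshold). Single linkage is the closest local
#' analogue of the reference-database threshold clustering.
#'
#' @param dist square symmetric matrix of fractional dissimilarities.
#' @param threshold maximum within-cluster linking distance (default 0.015).
#' @return named integer vector of cluster ids, numbered by first appearance
#'   in label order.
#' @examples
#' d <- matrix(c(0, .01, .03, .01, 0, .01, .03, .01, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' sh_cluster(d) # all in cluster 1
#' @export
sh_cluster <- function(dist, threshold = 0.015) {
  if (threshold < 0) stop("threshold must be non-negative")
  dist <- as.matrix(dist)
  check_distance_matrix(dist)
  n <- nrow(dist)
  labels <- rownames(dist)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  adj <- dist <= threshold
  comp <- rep(NA_integer_, n)
  next_id <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    next_id <- next_id + 1L
    queue <- s
    comp[s] <- next_id
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- next_id
      queue <- c(queue, nb)
    }
  }
  stats::setNames(comp, labels)
}

#' Index a FASTA file for sequence bookkeeping
#'
#' Reads only identifiers and sequence lengths (no sequence analysis is done
#' in this package; alignment and database search are out of scope).
#'
#' @param path FASTA file.
#' @return data.frame with \code{id} (first token of each header) and
#'   \code{length}.
#' @export
fasta_index <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers found in ", path)
  idx <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  lens <- tapply(nchar(gsub("\\s", "", lines[!hdr])), idx[!hdr], sum)
  len <- integer(length(ids))
  len[as.integer(names(lens))] <- as.integer(lens)
  data.frame(id = ids, length = len, stringsAsFactors = FALSE)
}
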