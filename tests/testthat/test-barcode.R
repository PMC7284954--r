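make_hits <- function() {
  data.frame(
    query_id = "q1",
    subject_name = c("s1", "s2", "s3"),
    percent_identity = c(99.2, 98.9, 99.5),
    query_coverage = c(0.96, 0.99, 0.90),
    score = c(900, 850, 800),
    stringsAsFactors = FALSE)
}

test_that("screen_hits applies coverage, identity and top-n", {
  kept <- screen_hits(make_hits())
  expect_equal(kept$subject_name, "s1") # s2 fails identity, s3 coverage
  # top_n restriction by score before thresholding
  hits <- data.frame(query_id = "q", subject_name = paste0("s", 1:60),
                     percent_identity = 99.5, query_coverage = 0.99,
                     score = seq(600, 10, length.out = 60))
  expect_equal(nrow(screen_hits(hits)), 50)
  expect_equal(nrow(screen_hits(hits, top_n = 5)), 5)
  # retained set is a subset in input order
  set.seed(51)
  rand <- data.frame(query_id = sample(c("a", "b"), 40, TRUE),
                     subject_name = paste0("s", 1:40),
                     percent_identity = runif(40, 95, 100),
                     query_coverage = runif(40, 0.8, 1),
                     score = runif(40, 100, 1000))
  kept <- screen_hits(rand)
  expect_true(all(kept$subject_name %in% rand$subject_name))
  expect_false(is.unsorted(match(kept$subject_name, rand$subject_name)))
  expect_error(screen_hits(transform(rand, percent_identity = 101)), "100")
})

test_that("wpgma reproduces hand-traced merges", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- wpgma(d2)
  expect_equal(t2$height, 1.5) # two leaves join at half their distance
  d3 <- matrix(c(0, 2, 8,
                 2, 0, 6,
                 8, 6, 0), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- wpgma(d3)
  expect_equal(t3$height, c(1, 3.5)) # (a,b) at 1; ((ab),c) at (8+6)/2/2
  expect_equal(t3$merge[1, ], c(-1L, -2L))
})

test_that("wpgma heights are monotone and match hclust's WPGMA", {
  set.seed(52)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- paste0("t", seq_len(n))
    d <- as.matrix(dist(x))
    tr <- wpgma(d)
    expect_true(all(diff(tr$height) >= -1e-12))
    ref <- hclust(as.dist(d), method = "mcquitty")
    # merge heights agree (hclust reports the merge distance = 2 x height)
    expect_equal(sort(tr$merge_distance), sort(ref$height), tolerance = 1e-10)
    # cophenetic matrices agree fully
    expect_equal(wpgma_cophenetic(tr)[rownames(x), rownames(x)],
                 as.matrix(cophenetic(ref))[rownames(x), rownames(x)],
                 tolerance = 1e-10)
  }
})

test_that("wpgma recovers random ultrametrics exactly", {
  set.seed(53)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    base <- hclust(dist(matrix(rnorm(n * 2), n)), method = "average")
    base$labels <- paste0("u", seq_len(n))
    u <- as.matrix(cophenetic(base))
    tr <- wpgma(u)
    expect_equal(wpgma_cophenetic(tr)[rownames(u), colnames(u)], u,
                 tolerance = 1e-10)
  }
})

test_that("wpgma is invariant to label order up to isomorphism", {
  set.seed(54)
  x <- matrix(rnorm(12), 6)
  rownames(x) <- paste0("s", 1:6)
  d <- as.matrix(dist(x))
  t1 <- wpgma(d)
  perm <- sample(6)
  t2 <- wpgma(d[perm, perm])
  expect_equal(wpgma_cophenetic(t1)[rownames(x), rownames(x)],
               wpgma_cophenetic(t2)[rownames(x), rownames(x)],
               tolerance = 1e-10)
})

test_that("wpgma newick output round-trips through ape", {
  library(ape)
  set.seed(55)
  x <- matrix(rnorm(10), 5)
  rownames(x) <- paste0("n", 1:5)
  d <- as.matrix(dist(x))
  tr <- wpgma(d)
  phy <- read.tree(text = wpgma_newick(tr))
  expect_setequal(phy$tip.label, rownames(x))
  # ultrametric tree: root-to-tip distance equals the root height
  expect_equal(unname(node.depth.edgelength(phy)[seq_len(5)]),
               rep(max(tr$height), 5), tolerance = 1e-8)
  # ape cophenetic distances match ours
  expect_equal(cophenetic(phy)[rownames(x), rownames(x)],
               wpgma_cophenetic(tr)[rownames(x), rownames(x)],
               tolerance = 1e-8)
})

test_that("wpgma rejects bad matrices", {
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(wpgma(m), "symmetric")
  expect_error(wpgma(matrix(0, 1, 1)), "at least 2")
})

test_that("monospecific_clades finds maximal single-species subtrees", {
  # two species forming clean clades
  x <- c(a1 = 0, a2 = 0.1, b1 = 5, b2 = 5.1, b3 = 5.2)
  d <- as.matrix(dist(x))
  tr <- wpgma(d)
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", b3 = "B")
  cl <- monospecific_clades(tr, sp)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$species, c("A", "B"))
  expect_equal(sort(cl$n_leaves), c(2, 3))
  # all same species: one clade covering the tree
  one <- monospecific_clades(tr, setNames(rep("X", 5), names(x)))
  expect_equal(nrow(one), 1)
  expect_equal(one$n_leaves, 5)
  # all distinct: every leaf its own clade
  all_diff <- monospecific_clades(tr, setNames(LETTERS[1:5], names(x)))
  expect_equal(nrow(all_diff), 5)
  expect_true(all(all_diff$n_leaves == 1))
})

test_that("monospecific_clades agrees with a brute-force subtree scan", {
  set.seed(56)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    x <- rnorm(n)
    names(x) <- paste0("L", seq_len(n))
    d <- as.matrix(dist(x))
    sp <- setNames(sample(c("S1", "S2"), n, TRUE), names(x))
    tr <- wpgma(d)
    got <- monospecific_clades(tr, sp)
    # brute force: enumerate all subtree leaf sets, keep maximal monospecific
    leafsets <- c(lapply(seq_len(n), function(l) l),
                  phragpath:::node_leaves(tr$merge))
    mono <- Filter(function(s) length(unique(sp[s])) == 1, leafsets)
    maximal <- Filter(function(s) {
      !any(vapply(mono, function(t) length(t) > length(s) && all(s %in% t),
                  logical(1)))
    }, mono)
    # deduplicate
    keysets <- unique(lapply(maximal, sort))
    expect_equal(nrow(got), length(keysets))
    got_sets <- strsplit(got$leaves, ",")
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(keysets, function(s) paste(sort(names(x)[s]), collapse = ","), ""))
  }
})

test_that("sh_cluster forms single-linkage components at the 1.5% threshold", {
  lab <- c("a", "b", "c")
  chain <- matrix(c(0, 0.01, 0.03,
                    0.01, 0, 0.01,
                    0.03, 0.01, 0), 3, dimnames = list(lab, lab))
  expect_equal(unname(sh_cluster(chain)), c(1, 1, 1)) # transitive closure
  far <- matrix(0.5, 3, 3, dimnames = list(lab, lab)); diag(far) <- 0
  expect_equal(unname(sh_cluster(far)), 1:3)
  zero <- matrix(0, 3, 3, dimnames = list(lab, lab))
  expect_equal(unname(sh_cluster(zero)), c(1, 1, 1))
  expect_error(sh_cluster(zero, threshold = -1), "non-negative")
})

test_that("sh_cluster yields a partition and is idempotent on representatives", {
  set.seed(57)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    x <- runif(n)
    names(x) <- paste0("s", seq_len(n))
    d <- as.matrix(dist(x))
    cl <- sh_cluster(d, threshold = 0.1)
    expect_equal(length(cl), n) # every label in exactly one cluster
    expect_true(all(cl >= 1))
    # re-cluster one representative per cluster: all singletons stay distinct
    reps <- names(cl)[!duplicated(cl)]
    cl2 <- if (length(reps) >= 2) {
      sh_cluster(d[reps, reps, drop = FALSE], threshold = 0.1)
    } else {
      setNames(1L, reps)
    }
    expect_equal(length(unique(cl2)), length(unique(cl)))
  }
})

test_that("fasta_index reads ids and lengths only", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">iso1 some description", "ACGTACGT", "ACGT",
               ">iso2", "GGGCCC"), path)
  idx <- fasta_index(path)
  expect_equal(idx$id, c("iso1", "iso2"))
  expect_equal(idx$length, c(12L, 6L))
  bad <- tempfile()
  writeLines("ACGT", bad)
  expect_error(fasta_index(bad), "headers")
})
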