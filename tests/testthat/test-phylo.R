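test_that("p and K2P distances match direct counting and the ape closed forms", {
  m <- rbind(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"))
  expect_equal(unname(distance_matrix(m, "p")["a", "b"]), 0)
  m2 <- rbind(a = strsplit("ACGT", "")[[1]], b = strsplit("ACGA", "")[[1]])
  expect_equal(unname(distance_matrix(m2, "p")["a", "b"]), 0.25)

  set.seed(1)
  base <- sample(c("A", "C", "G", "T"), 400, TRUE)
  mut <- function(v, rate) {
    i <- which(runif(length(v)) < rate)
    v[i] <- vapply(v[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    v
  }
  mat <- rbind(s1 = base, s2 = mut(base, 0.05), s3 = mut(base, 0.15),
               s4 = mut(base, 0.30))
  mat[1, 3:9] <- "-"
  # direct-count oracle for p
  Dp <- distance_matrix(mat, "p")
  for (i in 1:3) for (j in (i + 1):4) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    expect_equal(unname(Dp[i, j]), sum(mat[i, ok] != mat[j, ok]) / sum(ok))
  }
  # independent implementation check for K2P
  skip_if_not_installed("ape")
  Dk <- distance_matrix(mat, "K2P")
  Da <- ape::dist.dna(ape::as.DNAbin(tolower(mat)), model = "K80",
                      as.matrix = TRUE, pairwise.deletion = TRUE)
  expect_equal(Dk, Da[rownames(Dk), colnames(Dk)], tolerance = 1e-10)
  # saturated pairs are NA, never fabricated
  sat <- rbind(x = rep(c("A", "C"), 50), y = rep(c("G", "T"), 50))
  expect_true(is.na(distance_matrix(sat, "K2P")["x", "y"]))
})

test_that("neighbor joining recovers a hand-built additive 4-taxon tree", {
  # tree ((a:2,b:3):1,c:4,d:5) -> additive distances
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 5
  D["a", "c"] <- D["c", "a"] <- 7
  D["a", "d"] <- D["d", "a"] <- 8
  D["b", "c"] <- D["c", "b"] <- 8
  D["b", "d"] <- D["d", "b"] <- 9
  D["c", "d"] <- D["d", "c"] <- 9
  tr <- nj_tree(D)
  expect_equal(sort(tree_bipartitions(tr)), sort(canon_split(c("a", "b"),
                                                            letters[1:4])))
  expect_equal(cophenetic(tr)[letters[1:4], letters[1:4]], D)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  D2 <- D; D2["a", "b"] <- 6
  expect_error(nj_tree(D2), "symmetric")
})

test_that("neighbor joining is exact on random additive matrices", {
  skip_if_not_installed("ape")
  set.seed(2)
  for (r in 1:40) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- cophenetic(tr)
    est <- nj_tree(D)
    expect_equal(sort(tree_bipartitions(est)),
                 sort(tree_bipartitions(ape::unroot(tr))))
    expect_equal(cophenetic(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-7)
  }
})

test_that("RF distance equals an independent implementation and is a metric", {
  skip_if_not_installed("phangorn")
  set.seed(3)
  trees <- lapply(1:8, function(i) ape::unroot(ape::rtree(8)))
  for (i in 1:7) for (j in (i + 1):8) {
    rf <- rf_incongruence(trees[[i]], trees[[j]])$rf
    expect_equal(rf, as.numeric(phangorn::RF.dist(trees[[i]], trees[[j]])))
    # symmetry
    expect_equal(rf, rf_incongruence(trees[[j]], trees[[i]])$rf)
  }
  # identity of indiscernibles
  expect_equal(rf_incongruence(trees[[1]], trees[[1]])$rf, 0)
  expect_false(rf_incongruence(trees[[1]], trees[[1]])$incongruent)
  # a single nearest-neighbour interchange changes one split: RF 2
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")     # splits ab | cd
  t2 <- ape::read.tree(text = "((a,(c,d)),b,e);")     # splits cd | acd
  expect_equal(rf_incongruence(t1, t2)$rf, 2)
  expect_equal(rf_incongruence(t1, t2)$rf,
               as.numeric(phangorn::RF.dist(t1, t2)))
  # disjoint leaf sets are rejected
  t3 <- ape::read.tree(text = "((v,w),(x,y),z);")
  expect_error(rf_incongruence(t1, t3), "shared leaves")
})

test_that("bootstrap supports are percentages, deterministic, and saturate on clean splits", {
  set.seed(4)
  cladeA <- random_dna_chr(400, 0.5)
  cladeB <- paste(rev(strsplit(random_dna_chr(400, 0.5), "")[[1]]), collapse = "")
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), k)
    v[i] <- vapply(v[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  }
  seqs <- c(a1 = mut(cladeA, 4), a2 = mut(cladeA, 4), a3 = mut(cladeA, 4),
            b1 = mut(cladeB, 4), b2 = mut(cladeB, 4), b3 = mut(cladeB, 4))
  al <- progressive_align(seqs)
  tr <- bootstrap_support(al, n_reps = 50, seed = 5)
  key <- canon_split(c("a1", "a2", "a3"), names(seqs))
  expect_true(key %in% tree_bipartitions(tr, support_min = 99))
  tr2 <- bootstrap_support(al, n_reps = 50, seed = 5)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # single replicate: supports all 0 or 100
  tr1 <- bootstrap_support(al, n_reps = 1, seed = 6)
  sup <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("MLST concatenation recovers the planted clades", {
  study <- toy_study()
  ml <- mlst_run(study$strains, study$mlst_scheme, n_boot = 0)
  lac <- names(study$meta)[study$meta == "lactis"]
  blg <- names(study$meta)[study$meta == "bulgaricus"]
  expect_true(clade_monophyletic(ml$tree, lac))
  expect_true(clade_monophyletic(ml$tree, blg))
  expect_equal(ml$alignment$ncol,
               sum(vapply(ml$per_locus, function(a) a$ncol, integer(1))))
  # a strain missing one locus is excluded with a warning
  broken <- study$strains
  f <- broken[[1]]$features
  broken[[1]]$features <- f[!(f$gene_id == study$mlst_scheme[[1]] &
                                f$type == "CDS"), ]
  expect_warning(ml2 <- mlst_run(broken, study$mlst_scheme, n_boot = 0),
                 "excluded")
  expect_false(broken[[1]]$strain_id %in% ml2$strains_used)
})

test_that("diagnostic-site scan equals a brute-force per-column oracle", {
  # constructed alignment: 2 share-groups + query + differ-group,
  # 3 qualifying columns among decoys
  rows <- list(
    l1 = "AACGTACGTA", l2 = "AACGTACGTA",          # group L
    b1 = "AACGTACGAA", b2 = "AACGTACGAA",          # group B
    d1 = "GACTTACTAA", d2 = "GACTTTCTAA",          # group D (differ)
    q  = "AACGTACGTA")                             # query
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  groups <- list(L = c("l1", "l2"), B = c("b1", "b2"), D = c("d1", "d2"))
  got <- diagnostic_sites(m, groups, share_groups = c("L", "B"),
                          differ_group = "D", query = "q")
  # oracle: per-column scan
  share_rows <- c("l1", "l2", "b1", "b2", "q")
  exp_sites <- integer(0)
  for (j in seq_len(ncol(m))) {
    a <- m[share_rows, j]; b <- m[c("d1", "d2"), j]
    if (any(a == "-") || any(b == "-")) next
    if (length(unique(a)) == 1 && length(unique(b)) == 1 && a[1] != b[1]) {
      exp_sites <- c(exp_sites, j)
    }
  }
  expect_equal(got$site, exp_sites)
  expect_equal(got$site, c(1L, 4L, 8L))  # the three planted columns
  # all-identical alignment: no sites
  m0 <- m; m0[] <- "A"
  expect_equal(nrow(diagnostic_sites(m0, groups, "L", "D")), 0)
  expect_error(diagnostic_sites(m, c(groups, list(E = character(0))), "L", "E"),
               "empty group")
})
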