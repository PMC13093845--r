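test_that("Bray-Curtis matches the formula by hand and vegan", {
  M <- rbind(a = c(6, 4, 0), b = c(2, 0, 8))
  d <- brayCurtis(M, normalize = FALSE)
  expect_equal(d["a", "b"], (4 + 4 + 8) / (8 + 4 + 8)) # 0.8
  expect_equal(d["a", "a"], 0)
  # identical rows -> 0, disjoint supports -> 1
  M2 <- rbind(x = c(1, 2, 0, 0), y = c(1, 2, 0, 0), z = c(0, 0, 3, 7))
  d2 <- brayCurtis(M2, normalize = FALSE)
  expect_equal(d2["x", "y"], 0)
  expect_equal(d2["x", "z"], 1)
  set.seed(3)
  R <- matrix(rpois(8 * 40, 4), 8, dimnames = list(paste0("e", 1:8), NULL))
  R[, 1] <- R[, 1] + 1
  expect_equal(
    brayCurtis(R, normalize = FALSE),
    as.matrix(vegan::vegdist(R, "bray")),
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("an all-zero community is a hard error naming it", {
  M <- rbind(ok = c(1, 2), bad = c(0, 0))
  expect_error(brayCurtis(M), "bad")
})

test_that("PCoA embeds Euclidean distances exactly", {
  set.seed(4)
  P <- matrix(rnorm(9 * 4), 9, dimnames = list(paste0("p", 1:9), NULL))
  d <- as.matrix(dist(P))
  res <- pcoa(d)
  expect_lt(max(abs(as.matrix(dist(res$coordinates)) - d)), 1e-8)
  # cross-check eigenvalues against ape
  ref <- ape::pcoa(as.dist(d))
  k <- ncol(res$coordinates)
  expect_equal(res$eigenvalues[seq_len(k)], ref$values$Eigenvalues[seq_len(k)],
    tolerance = 1e-8
  )
})

test_that("PCoA of collinear points reproduces the line", {
  x <- c(0, 1, 3, 7)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  res <- pcoa(d)
  ax1 <- res$coordinates[, 1]
  expect_equal(as.matrix(dist(ax1)), d, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$prop_explained[1], 1, tolerance = 1e-10)
})

test_that("three equidistant entities give two equal positive eigenvalues", {
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  res <- pcoa(d)
  ev <- res$eigenvalues[res$eigenvalues > 1e-12]
  expect_length(ev, 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-12)
  expect_warning(pcoa(d, n_axes = 3), "truncating")
})

test_that("pseudo-F and R2 agree with vegan::adonis2", {
  set.seed(5)
  M <- matrix(rpois(12 * 30, 5), 12, dimnames = list(paste0("s", 1:12), NULL))
  d <- brayCurtis(M, normalize = FALSE)
  labs <- rep(c("A", "B", "C"), each = 4)
  res <- permanova(d, setNames(labs, rownames(d)), n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ labs, permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("pseudo-F on 1-D Euclidean data equals the classical ANOVA F", {
  set.seed(6)
  y <- rnorm(15)
  g <- rep(c("A", "B", "C"), each = 5)
  d <- as.matrix(dist(y))
  dimnames(d) <- list(paste0("s", 1:15), paste0("s", 1:15))
  res <- permanova(d, setNames(g, rownames(d)), n_perm = 9, seed = 1)
  expect_equal(res$pseudo_F, summary(aov(y ~ g))[[1]]$F[1],
    tolerance = 1e-8
  )
})

test_that("perfect separation attains the minimal permutation p", {
  # two clusters of near-clones; groups large enough that a random label
  # permutation essentially never reproduces the separating partition
  set.seed(12)
  A <- t(replicate(10, abs(c(50, 0, 0) + rnorm(3, 0, 0.5))))
  B <- t(replicate(10, abs(c(0, 30, 30) + rnorm(3, 0, 0.5))))
  M <- rbind(A, B)
  rownames(M) <- paste0("s", 1:20)
  d <- brayCurtis(M)
  labs <- setNames(rep(c("A", "B"), each = 10), rownames(M))
  res <- permanova(d, labs, n_perm = 199, seed = 2)
  expect_equal(res$p, 1 / (1 + 199))
})

test_that("permutation p agrees with exact enumeration at n = 3 + 3", {
  set.seed(7)
  M <- matrix(rpois(6 * 20, 4), 6, dimnames = list(paste0("s", 1:6), NULL))
  d <- brayCurtis(M, normalize = FALSE)
  labs <- setNames(rep(c("A", "B"), each = 3), rownames(M))
  res <- permanova(d, labs, exact = TRUE)
  expect_equal(res$n_perm, 20L)
  # brute-force oracle: every way to choose which 3 entities are "A"
  d2 <- d^2
  Fstat <- function(idxA) {
    f <- factor(ifelse(seq_len(6) %in% idxA, "A", "B"))
    n <- 6
    ss_tot <- sum(d2) / (2 * n)
    ss_w <- sum(d2[f == "A", f == "A"]) / 6 + sum(d2[f == "B", f == "B"]) / 6
    ((ss_tot - ss_w) / 1) / (ss_w / 4)
  }
  Fs <- combn(6, 3, Fstat)
  p_brute <- mean(Fs >= Fstat(1:3) - 1e-12)
  expect_equal(res$p, p_brute)
  # a long random permutation run approximates the exact value
  res2 <- permanova(d, labs, n_perm = 3999, seed = 3)
  expect_lt(abs(res2$p - p_brute), 0.03)
})

test_that("permanova rejects degenerate groupings", {
  d <- brayCurtis(matrix(rpois(9, 4) + 1, 3,
    dimnames = list(paste0("s", 1:3), NULL)
  ), normalize = FALSE)
  expect_error(permanova(d, setNames(c("A", "A", "B"), rownames(d))), "size 1")
  expect_error(permanova(d, setNames(rep("A", 3), rownames(d))), ">= 2 groups")
})

test_that("permanova p is invariant to renaming group labels", {
  set.seed(8)
  M <- matrix(rpois(10 * 25, 4), 10, dimnames = list(paste0("s", 1:10), NULL))
  d <- brayCurtis(M, normalize = FALSE)
  labs1 <- setNames(rep(c("A", "B"), each = 5), rownames(d))
  labs2 <- setNames(rep(c("zzz", "qqq"), each = 5), rownames(d))
  r1 <- permanova(d, labs1, n_perm = 99, seed = 4)
  r2 <- permanova(d, labs2, n_perm = 99, seed = 4)
  expect_equal(r1$pseudo_F, r2$pseudo_F)
  expect_equal(r1$p, r2$p)
})

test_that("pairwise PERMANOVA returns one result per group pair", {
  sim <- simulateCommunity(simConfig(
    group_sizes = c(A = 3, B = 3, C = 3, D = 3),
    replicates_per_species = 1, n_background_otus = 40,
    sequencing_depth = 2000, seed = 9
  ))
  d <- brayCurtis(sim$experiment, level = "sample")
  labs <- sampleLabels(sim$experiment)
  pw <- pairwisePermanova(d, labs, n_perm = 49, seed = 5)
  expect_equal(nrow(pw), 6L)
  expect_true(all(pw$p_adj >= pw$p))
  # sub-matrix consistency: the A-B row equals a manual subset run
  idx <- names(labs)[labs %in% c("A", "B")]
  manual <- permanova(d[idx, idx], labs[idx], n_perm = 49, seed = (5 + 1) %% 2147483647L)
  expect_equal(pw$pseudo_F[1], manual$pseudo_F)
  expect_equal(pw$p[1], manual$p)
})

test_that("planted turnover between two groups is localized by pairwise tests", {
  # groups A and C get disjoint dominant OTUs; B and D share the background
  set.seed(10)
  base <- rpois(30, 5) + 1
  mk <- function(boost) {
    t(replicate(4, {
      x <- base + rpois(30, 2)
      x[boost] <- x[boost] + 60
      x
    }))
  }
  M <- rbind(mk(1:5), mk(integer(0)), mk(6:10), mk(integer(0)))
  rownames(M) <- paste0("s", 1:16)
  labs <- setNames(rep(c("A", "B", "C", "D"), each = 4), rownames(M))
  pw <- pairwisePermanova(brayCurtis(M), labs, n_perm = 199, seed = 6)
  ac <- pw$p[pw$group_a == "A" & pw$group_b == "C"]
  bd <- pw$p[pw$group_a == "B" & pw$group_b == "D"]
  expect_lte(ac, min(pw$p))
  expect_gt(bd, 0.1)
})

test_that("species-level ordination separates groups under strong turnover", {
  sim <- simulateCommunity(simConfig(turnover_strength = 2, seed = 11))
  bc <- brayCurtis(sim$experiment, level = "species")
  res <- pcoa(bc, n_axes = 2)
  grp <- speciesGroups(sim$experiment)[rownames(res$coordinates)]
  # silhouette on axes 1-2 > 0: group centroids are separated
  co <- res$coordinates
  cent <- apply(co, 2, function(v) tapply(v, grp, mean))
  sil <- vapply(seq_len(nrow(co)), function(i) {
    dd <- sqrt(colSums((t(cent) - co[i, ])^2))
    own <- dd[grp[i]]
    other <- min(dd[setdiff(names(dd), grp[i])])
    (other - own) / max(own, other)
  }, 1)
  expect_gt(mean(sil), 0)
})
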