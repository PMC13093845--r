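# helper: synthetic pair design with controllable response
syntheticDesign <- function(seed, n_species = 24, groups = c("G1", "G2", "G3")) {
  set.seed(seed)
  sp <- sprintf("sp%02d", seq_len(n_species))
  tr <- makeTraits(sp, groups)
  tr$lma <- runif(n_species, 0.002, 0.01)
  tr$n_conc <- rnorm(n_species, 22, 4)
  tr$cn_ratio <- runif(n_species, 12, 25)
  tr$water_content <- runif(n_species, 55, 85)
  tr$abundance <- rpois(n_species, 80)
  tree <- ape::rcoal(n_species, tip.label = sample(sp))
  ph <- copheneticDistances(tree, sp)
  bc <- matrix(runif(n_species^2, 0.2, 0.9), n_species,
    dimnames = list(sp, sp)
  )
  bc <- (bc + t(bc)) / 2
  diag(bc) <- 0
  list(traits = tr, phylo = ph, bc = bc, tree = tree)
}

test_that("cophenetic distances equal path sums on a toy tree", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- copheneticDistances(tree)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_error(copheneticDistances(tree, species = c("A", "Z")), "Z")
})

test_that("ultrametric trees put all cross-root pairs at equal distance", {
  set.seed(14)
  tree <- ape::rcoal(10)
  d <- copheneticDistances(tree)
  root_children <- tree$edge[tree$edge[, 1] == 11, 2]
  left <- if (root_children[1] <= 10) {
    tree$tip.label[root_children[1]]
  } else {
    ape::extract.clade(tree, root_children[1])$tip.label
  }
  right <- setdiff(tree$tip.label, left)
  cross <- d[left, right]
  expect_lt(diff(range(cross)), 1e-10)
})

test_that("cophenetic distances match a graph shortest-path oracle", {
  set.seed(15)
  tree <- ape::rcoal(20)
  d <- copheneticDistances(tree)
  # independent oracle: shortest paths on the weighted tree graph
  g <- igraph::graph_from_edgelist(
    apply(tree$edge, 2, as.character),
    directed = FALSE
  )
  igraph::E(g)$weight <- tree$edge.length
  sp <- igraph::distances(g)
  tips <- as.character(seq_len(20))
  oracle <- sp[tips, tips]
  dimnames(oracle) <- list(tree$tip.label, tree$tip.label)
  expect_equal(d[rownames(oracle), colnames(oracle)], oracle,
    tolerance = 1e-10
  )
})

test_that("the cross-group pair design has the combinatorial row count", {
  fx <- syntheticDesign(1, n_species = 45, groups = "G1")
  # reassign groups to sizes 6 / 4 / 32 / 3
  fx$traits$group_id <- rep(c("G", "L", "DF", "MF"), c(6, 4, 32, 3))
  des <- buildPairDesign(fx$bc, fx$traits, fx$phylo)
  expect_equal(nrow(des), 470L) # 6*4 + 6*32 + 6*3 + 4*32 + 4*3 + 32*3
  expect_true(all(des$group_a != des$group_b))
  # identity: C(45, 2) - sum_g C(n_g, 2) = 990 - 520 = 470
  expect_equal(
    choose(45, 2) - sum(choose(c(6, 4, 32, 3), 2)),
    nrow(des)
  )
  # brute-force double loop oracle on random group assignments
  set.seed(16)
  fx$traits$group_id <- sample(c("a", "b", "c"), 45, replace = TRUE)
  des2 <- buildPairDesign(fx$bc, fx$traits, fx$phylo)
  cnt <- 0
  grp <- setNames(fx$traits$group_id, fx$traits$species_id)
  for (i in 1:44) {
    for (j in (i + 1):45) {
      if (grp[i] != grp[j]) cnt <- cnt + 1
    }
  }
  expect_equal(nrow(des2), cnt)
})

test_that("tiny bipartite designs and missing traits behave as specified", {
  fx <- syntheticDesign(2, n_species = 4, groups = c("G1", "G2"))
  des <- buildPairDesign(fx$bc, fx$traits, fx$phylo)
  expect_equal(nrow(des), 4L) # 2 x 2 complete bipartite
  expect_error(
    buildPairDesign(fx$bc, fx$traits[-1, ], fx$phylo),
    fx$traits$species_id[1]
  )
  # within-group pairs included on request
  des_all <- buildPairDesign(fx$bc, fx$traits, fx$phylo,
    includeWithinGroup = TRUE
  )
  expect_equal(nrow(des_all), choose(4, 2))
})

test_that("predictors are z-standardized with recorded constants", {
  fx <- syntheticDesign(3)
  des <- buildPairDesign(fx$bc, fx$traits, fx$phylo)
  expect_equal(unname(colMeans(as.matrix(des[, c("lma", "phylo")]))),
    c(0, 0),
    tolerance = 1e-12
  )
  expect_equal(unname(apply(as.matrix(des[, c("lma", "phylo")]), 2, sd)),
    c(1, 1),
    tolerance = 1e-12
  )
  sc <- attr(des, "scaling")
  raw <- buildPairDesign(fx$bc, fx$traits, fx$phylo, standardize = FALSE)
  expect_equal(
    des$lma,
    (raw$lma - sc$center[sc$predictor == "lma"]) /
      sc$scale[sc$predictor == "lma"]
  )
})

test_that("the REML solver agrees exactly with lme4 on a multimembership fit", {
  set.seed(17)
  S <- 15
  n <- 120
  a <- sample(S, n, TRUE)
  b <- sapply(a, function(ai) sample(setdiff(1:S, ai), 1))
  x1 <- rnorm(n)
  u <- rnorm(S, 0, 0.6)
  y <- 1 + 0.8 * x1 + u[a] + u[b] + rnorm(n, 0, 0.4)
  des <- data.frame(
    species_a = sprintf("s%02d", a), species_b = sprintf("s%02d", b),
    response = y, x1 = x1
  )
  fit <- fitDistanceLmm(des, predictors = "x1")
  # lme4 modular interface with the membership matrix as custom Zt
  df <- data.frame(
    y = y, x1 = x1,
    g = factor(sprintf("s%02d", a), levels = sprintf("s%02d", 1:S))
  )
  lf <- lme4::lFormula(y ~ x1 + (1 | g),
    data = df, REML = TRUE,
    control = lme4::lmerControl(
      check.nobs.vs.nlev = "ignore",
      check.nobs.vs.nRE = "ignore"
    )
  )
  M <- matrix(0, n, S)
  M[cbind(1:n, a)] <- 1
  M[cbind(1:n, b)] <- 1
  Zt <- methods::as(t(M), "CsparseMatrix")
  rownames(Zt) <- sprintf("s%02d", 1:S)
  lf$reTrms$Zt <- Zt
  lf$reTrms$Ztlist[[1]] <- Zt
  devfun <- do.call(lme4::mkLmerDevfun, lf)
  opt <- lme4::optimizeLmer(devfun)
  mm <- lme4::mkMerMod(environment(devfun), opt, lf$reTrms, fr = lf$fr)
  expect_equal(fit$coefficients$estimate, unname(lme4::fixef(mm)[2]),
    tolerance = 1e-6
  )
  vc <- as.data.frame(lme4::VarCorr(mm))
  expect_equal(unname(fit$varcomp), vc$vcov, tolerance = 1e-5)
  expect_equal(fit$coefficients$se, sqrt(as.matrix(vcov(mm))[2, 2]),
    tolerance = 1e-6
  )
})

test_that("with zero random-effect variance the fit reduces to OLS", {
  fx <- syntheticDesign(4)
  des <- buildPairDesign(fx$bc, fx$traits, fx$phylo)
  prep <- leafEndophytes:::.dlmmPrep(des)
  ev <- leafEndophytes:::.dlmmEval(prep, seq_len(ncol(prep$X)), 0)
  ols <- lm(response ~ abundance + n_conc + cn_ratio + water_content +
    lma + phylo, data = des)
  expect_equal(unname(ev$beta), unname(coef(ols)), tolerance = 1e-6)
})

test_that("a planted lma effect is recovered and row order is irrelevant", {
  fx <- syntheticDesign(5)
  des0 <- buildPairDesign(fx$bc, fx$traits, fx$phylo)
  set.seed(18)
  des0$response <- 2 * des0$lma + rnorm(nrow(des0), 0, 0.1)
  fit <- fitDistanceLmm(des0)
  co <- fit$coefficients
  lma_row <- co[co$predictor == "lma", ]
  expect_lt(abs(lma_row$estimate - 2), 3 * lma_row$se)
  expect_lt(lma_row$p, 1e-10)
  # permuting rows leaves all estimates identical
  des_p <- des0[sample(nrow(des0)), ]
  fit_p <- fitDistanceLmm(des_p)
  expect_equal(fit$coefficients$estimate, fit_p$coefficients$estimate,
    tolerance = 1e-9
  )
  expect_equal(fit$r2_marginal, fit_p$r2_marginal, tolerance = 1e-9)
})

test_that("rank-deficient designs raise an error naming aliased predictors", {
  fx <- syntheticDesign(6)
  des <- buildPairDesign(fx$bc, fx$traits, fx$phylo)
  des$cn_ratio <- des$lma
  expect_error(fitDistanceLmm(des), "aliased.*(cn_ratio|lma)")
})

test_that("per-predictor p-values are calibrated under a pure-noise response", {
  hits <- 0L
  tot <- 0L
  for (s in 1:60) {
    fx <- syntheticDesign(100 + s, n_species = 14, groups = c("G1", "G2"))
    des <- buildPairDesign(fx$bc, fx$traits, fx$phylo)
    set.seed(200 + s)
    des$response <- rnorm(nrow(des))
    fit <- fitDistanceLmm(des)
    hits <- hits + sum(fit$coefficients$p < 0.05)
    tot <- tot + nrow(fit$coefficients)
  }
  expect_gt(hits / tot, 0.01)
  expect_lt(hits / tot, 0.10)
})

test_that("hierarchical partitioning obeys its identities", {
  fx <- syntheticDesign(7)
  des <- buildPairDesign(fx$bc, fx$traits, fx$phylo)
  set.seed(19)
  des$response <- 1.5 * des$lma - 1 * des$phylo + rnorm(nrow(des), 0, 0.5)
  hp <- suppressMessages(hierarchicalPartition(des))
  fit <- fitDistanceLmm(des)
  # raw increments sum to the full model's marginal R2
  expect_equal(sum(hp$individual_r2_raw), attr(hp, "r2_full"),
    tolerance = 1e-6
  )
  expect_equal(attr(hp, "r2_full"), fit$r2_marginal, tolerance = 1e-6)
  # single-predictor partition equals that model's marginal R2
  hp1 <- hierarchicalPartition(des, predictors = "lma")
  fit1 <- fitDistanceLmm(des, predictors = "lma")
  expect_equal(hp1$individual_r2, fit1$r2_marginal, tolerance = 1e-9)
})

test_that("partitioning is invariant to predictor order and affine rescaling", {
  fx <- syntheticDesign(8)
  des <- buildPairDesign(fx$bc, fx$traits, fx$phylo)
  set.seed(20)
  des$response <- des$lma + 0.5 * des$n_conc + rnorm(nrow(des), 0, 0.4)
  hp_a <- suppressMessages(hierarchicalPartition(des))
  hp_b <- suppressMessages(
    hierarchicalPartition(des, predictors = rev(leafEndophytes:::.PAIR_PREDICTORS))
  )
  expect_equal(
    setNames(hp_a$individual_r2, hp_a$predictor)[hp_b$predictor],
    setNames(hp_b$individual_r2, hp_b$predictor),
    tolerance = 1e-7
  )
  des2 <- des
  des2$lma <- des2$lma * 7 + 3
  hp_c <- suppressMessages(hierarchicalPartition(des2))
  expect_equal(hp_a$individual_r2, hp_c$individual_r2, tolerance = 1e-7)
})

test_that("orthogonal equal effects receive equal individual importance", {
  set.seed(21)
  n <- 400
  S <- 30
  a <- sample(S, n, TRUE)
  b <- sapply(a, function(ai) sample(setdiff(1:S, ai), 1))
  x1 <- rnorm(n)
  x2 <- rnorm(n) # independent predictors
  des <- data.frame(
    species_a = sprintf("s%02d", a), species_b = sprintf("s%02d", b),
    response = x1 + x2 + rnorm(n, 0, 0.5),
    x1 = x1, x2 = x2
  )
  hp <- hierarchicalPartition(des, predictors = c("x1", "x2"))
  r <- setNames(hp$individual_r2, hp$predictor)
  expect_gt(r[["x1"]] / r[["x2"]], 0.7)
  expect_lt(r[["x1"]] / r[["x2"]], 1.4)
})

test_that("lma-driven turnover makes lma the top-ranked predictor end-to-end", {
  tops <- vapply(1:5, function(s) {
    cfg <- simConfig(turnover_driver = "lma", turnover_strength = 2, seed = s)
    sim <- simulateCommunity(cfg)
    ee <- sim$experiment
    bc <- brayCurtis(ee, level = "species")
    ph <- copheneticDistances(hostTree(ee), species = rownames(bc))
    des <- buildPairDesign(bc, speciesTraits(ee), ph)
    hp <- suppressMessages(hierarchicalPartition(des))
    hp$predictor[which.max(hp$individual_r2)]
  }, "")
  expect_gte(sum(tops == "lma"), 4)
})
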