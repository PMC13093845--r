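#' Configuration for the synthetic endophyte community generator
#'
#' Builds and validates the parameter set for [simulateCommunity()]. The
#' defaults emulate the sampling design the package targets: four plant
#' functional groups of 6 (grasses), 4 (legumes), 32 (dicot forbs) and 3
#' (monocot forbs) host species with 3 replicate samples per species, a
#' shared background OTU pool whose composition turns over along a
#' trait-driven gradient, and group-specific marker OTUs planted with
#' controllable specificity and occupancy.
#'
#' @param group_sizes named integer vector: host species per functional
#'   group.
#' @param replicates_per_species replicate samples per host species.
#' @param n_background_otus size of the shared background OTU pool.
#' @param n_marker_otus_per_group marker OTUs planted per group.
#' @param marker_specificity_target expected specificity of planted
#'   markers, in (0, 1].
#' @param marker_occupancy_target expected within-group presence frequency
#'   of planted markers, in (0, 1].
#' @param marker_mean_abundance expected group-mean relative abundance of
#'   one planted marker within its group.
#' @param marker_leakage_abundance relative abundance of a marker in
#'   samples of other groups; `NULL` (default) derives the value from the
#'   specificity target. Supplying a value incompatible with the target is
#'   an error.
#' @param trait_means,trait_sds numeric matrices (groups x traits, traits
#'   = `lma`, `n_conc`, `cn_ratio`, `water_content`, `abundance`) giving
#'   group means and within-group standard deviations; `NULL` uses
#'   built-in values typical of alpine meadow vegetation.
#' @param turnover_driver one of the five trait names; community
#'   composition turns over along this trait.
#' @param turnover_strength non-negative scalar: gradient displacement per
#'   standard deviation of the driver trait. 0 disables trait-driven
#'   turnover.
#' @param niche_breadth Gaussian niche breadth of background OTUs on the
#'   latent gradient (gradient units).
#' @param species_niche_jitter standard deviation of species-specific
#'   gradient noise, giving species individuality even at
#'   `turnover_strength = 0`.
#' @param sequencing_depth reads per sample.
#' @param dispersion Dirichlet-multinomial overdispersion; counts are
#'   multinomial draws from a Dirichlet deviate with concentration
#'   `composition / dispersion`. 0 means a pure multinomial.
#' @param group_structured_tree if `TRUE`, the host tree is built from
#'   per-group coalescent subtrees so phylogeny is collinear with groups;
#'   otherwise a single random coalescent tree is used.
#' @param seed integer seed; every draw in [simulateCommunity()] derives
#'   from it.
#' @return a validated `sim_config` list.
#' @export
simConfig <- function(group_sizes = c(
                        grass = 6, legume = 4,
                        dicot_forb = 32, monocot_forb = 3
                      ),
                      replicates_per_species = 3,
                      n_background_otus = 150,
                      n_marker_otus_per_group = 5,
                      marker_specificity_target = 0.9,
                      marker_occupancy_target = 0.9,
                      marker_mean_abundance = 0.02,
                      marker_leakage_abundance = NULL,
                      trait_means = NULL,
                      trait_sds = NULL,
                      turnover_driver = "lma",
                      turnover_strength = 1,
                      niche_breadth = 1,
                      species_niche_jitter = 0.25,
                      sequencing_depth = 10000,
                      dispersion = 0,
                      group_structured_tree = FALSE,
                      seed = 1) {
  if (is.null(names(group_sizes)) || anyDuplicated(names(group_sizes))) {
    stop("group_sizes must have unique names")
  }
  stopifnot(
    all(group_sizes >= 1), replicates_per_species >= 1,
    n_background_otus >= 1, n_marker_otus_per_group >= 0,
    sequencing_depth >= 1, dispersion >= 0, turnover_strength >= 0,
    niche_breadth > 0, species_niche_jitter >= 0,
    marker_mean_abundance > 0
  )
  if (marker_specificity_target <= 0 || marker_specificity_target > 1) {
    stop("marker_specificity_target must lie in (0, 1]")
  }
  if (marker_occupancy_target <= 0 || marker_occupancy_target > 1) {
    stop("marker_occupancy_target must lie in (0, 1]")
  }
  traits <- c("lma", "n_conc", "cn_ratio", "water_content", "abundance")
  if (!(turnover_driver %in% traits)) {
    stop(
      "turnover_driver must be one of: ",
      paste(traits, collapse = ", ")
    )
  }
  G <- length(group_sizes)
  tm <- if (is.null(trait_means)) .defaultTraitMeans(G) else as.matrix(trait_means)
  ts <- if (is.null(trait_sds)) .defaultTraitSds(G) else as.matrix(trait_sds)
  rownames(tm) <- rownames(ts) <- names(group_sizes)
  if (!identical(colnames(tm), traits) || !identical(colnames(ts), traits)) {
    stop("trait_means/trait_sds need columns: ", paste(traits, collapse = ", "))
  }
  # marker feasibility: derive (or check) the out-of-group leakage needed
  # to hit the specificity target spec = m / (m + (G-1) * leak)
  t0 <- marker_specificity_target
  if (is.null(marker_leakage_abundance)) {
    leak <- if (G > 1) {
      marker_mean_abundance * (1 - t0) / ((G - 1) * t0)
    } else {
      0
    }
  } else {
    leak <- marker_leakage_abundance
    if (t0 >= 1 && leak > 0) {
      stop(
        "specificity target 1 is unattainable with nonzero leakage ",
        "(leak = ", leak, "): markers would never be fully exclusive"
      )
    }
    achieved <- marker_mean_abundance /
      (marker_mean_abundance + (G - 1) * leak)
    if (achieved < t0) {
      stop(
        "specificity target ", t0, " is unattainable: leakage ", leak,
        " caps expected specificity at ", signif(achieved, 4)
      )
    }
  }
  p_in <- marker_mean_abundance / marker_occupancy_target
  mass <- n_marker_otus_per_group *
    (p_in + (G - 1) * leak)
  if (mass >= 0.95) {
    stop(
      "marker settings claim ", signif(mass, 3), " of each sample; ",
      "reduce n_marker_otus_per_group or marker_mean_abundance"
    )
  }
  cfg <- list(
    group_sizes = group_sizes,
    replicates_per_species = as.integer(replicates_per_species),
    n_background_otus = as.integer(n_background_otus),
    n_marker_otus_per_group = as.integer(n_marker_otus_per_group),
    marker_specificity_target = t0,
    marker_occupancy_target = marker_occupancy_target,
    marker_mean_abundance = marker_mean_abundance,
    marker_leakage = leak,
    trait_means = tm,
    trait_sds = ts,
    turnover_driver = turnover_driver,
    turnover_strength = turnover_strength,
    niche_breadth = niche_breadth,
    species_niche_jitter = species_niche_jitter,
    sequencing_depth = as.integer(sequencing_depth),
    dispersion = dispersion,
    group_structured_tree = isTRUE(group_structured_tree),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# group-mean trait values typical of alpine meadow functional groups
# (order: grass, legume, dicot forb, monocot forb; recycled if G != 4)
.defaultTraitMeans <- function(G) {
  base <- rbind(
    lma = c(0.0062, 0.0040, 0.0036, 0.0044), # g/cm^2
    n_conc = c(18, 32, 24, 22), # mg/g
    cn_ratio = c(24, 14, 18, 19),
    water_content = c(62, 70, 72, 78), # percent
    abundance = c(220, 60, 140, 30) # plot occurrences
  )
  t(base[, rep_len(seq_len(4), G), drop = FALSE])
}

.defaultTraitSds <- function(G) {
  base <- rbind(
    lma = rep(0.0006, 4),
    n_conc = rep(2.5, 4),
    cn_ratio = rep(2, 4),
    water_content = rep(3, 4),
    abundance = c(55, 15, 35, 8)
  )
  t(base[, rep_len(seq_len(4), G), drop = FALSE])
}

#' Simulate a grouped endophyte community with planted markers
#'
#' Generates an OTU table, species traits, guild annotations, a host tree
#' and the generating truth, under the model described in the package
#' vignette: species sit on a latent gradient proportional to their
#' standardized `turnover_driver` trait (plus idiosyncratic jitter);
#' background OTUs respond to the gradient through Gaussian niches;
#' group-specific marker OTUs are planted so their expected specificity
#' and within-group occupancy meet the configured targets; per-sample
#' counts are multinomial (or Dirichlet-multinomial) draws of
#' `sequencing_depth` reads.
#'
#' @param cfg a [simConfig()] object.
#' @param seed integer seed; defaults to `cfg$seed`. Identical `cfg` and
#'   seed give bit-identical output.
#' @return list with elements
#'   \describe{
#'     \item{experiment}{an [EndophyteExperiment-class] with traits, tree
#'       and guilds attached.}
#'     \item{truth}{list: `markers` (planted marker OTU ids per group),
#'       `latent` (species x background-OTU latent compositions),
#'       `gradient` (species gradient positions), `driver`, `strength`.}
#'   }
#' @export
simulateCommunity <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  groups <- names(cfg$group_sizes)
  G <- length(groups)
  sp_group <- rep(groups, cfg$group_sizes)
  n_sp <- length(sp_group)
  species <- unlist(lapply(groups, function(g) {
    sprintf("%s_sp%02d", g, seq_len(cfg$group_sizes[[g]]))
  }))
  reps <- cfg$replicates_per_species

  # species traits: group means + Gaussian noise, clamped to invariants
  tnames <- colnames(cfg$trait_means)
  tr <- sapply(tnames, function(v) {
    x <- stats::rnorm(n_sp, cfg$trait_means[sp_group, v], cfg$trait_sds[sp_group, v])
    switch(v,
      lma = pmax(x, 1e-4),
      cn_ratio = pmax(x, 1),
      water_content = pmin(pmax(x, 1), 99),
      abundance = pmax(x, 0),
      x
    )
  })
  traits <- data.frame(
    species_id = species, group_id = sp_group,
    as.data.frame(tr), stringsAsFactors = FALSE
  )

  # latent gradient: standardized driver trait scaled by turnover strength
  drv <- traits[[cfg$turnover_driver]]
  z <- if (stats::sd(drv) > 0) (drv - mean(drv)) / stats::sd(drv) else rep(0, n_sp)
  grad <- cfg$turnover_strength * z +
    stats::rnorm(n_sp, 0, cfg$species_niche_jitter)

  # background pool: Gaussian niches along the gradient
  K <- cfg$n_background_otus
  bg_ids <- sprintf("OTU%04d", seq_len(K))
  mu <- stats::runif(K, min(grad) - cfg$niche_breadth, max(grad) + cfg$niche_breadth)
  logb <- stats::rnorm(K, 0, 1)
  W <- exp(outer(grad, mu, function(g, m) -(g - m)^2 / (2 * cfg$niche_breadth^2)) +
    rep(logb, each = n_sp))
  latent <- W / rowSums(W)
  dimnames(latent) <- list(species, bg_ids)

  # samples
  sample_species <- rep(species, each = reps)
  sample_group <- rep(sp_group, each = reps)
  sample_ids <- paste0(sample_species, "_r", rep(seq_len(reps), n_sp))
  n_samp <- length(sample_ids)

  # planted markers: occupancy via a fixed random subset of group samples,
  # specificity via calibrated out-of-group leakage
  n_mk <- cfg$n_marker_otus_per_group
  marker_ids <- list()
  mk_mat <- NULL
  if (n_mk > 0) {
    all_mk <- unlist(lapply(groups, function(g) {
      sprintf("M_%s_%02d", g, seq_len(n_mk))
    }))
    mk_mat <- matrix(cfg$marker_leakage, n_samp, length(all_mk),
      dimnames = list(sample_ids, all_mk)
    )
    for (g in groups) {
      g_samples <- which(sample_group == g)
      n_occ <- ceiling(cfg$marker_occupancy_target * length(g_samples))
      p_in <- cfg$marker_mean_abundance * length(g_samples) / n_occ
      ids <- sprintf("M_%s_%02d", g, seq_len(n_mk))
      marker_ids[[g]] <- ids
      for (m in ids) {
        occ_set <- sample(g_samples, n_occ)
        mk_mat[g_samples, m] <- 0
        mk_mat[occ_set, m] <- p_in
      }
    }
  } else {
    marker_ids <- stats::setNames(
      rep(list(character(0)), G), groups
    )
  }

  # per-sample composition and counts
  otu_ids <- c(bg_ids, if (!is.null(mk_mat)) colnames(mk_mat))
  counts <- matrix(0L, length(otu_ids), n_samp,
    dimnames = list(otu_ids, sample_ids)
  )
  for (j in seq_len(n_samp)) {
    mk <- if (is.null(mk_mat)) numeric(0) else mk_mat[j, ]
    mass <- sum(mk)
    comp <- c(latent[sample_species[j], ] * (1 - mass), mk)
    if (cfg$dispersion > 0) {
      a <- comp / cfg$dispersion
      gdraw <- stats::rgamma(length(a), shape = a)
      if (sum(gdraw) == 0) gdraw <- comp
      comp <- gdraw / sum(gdraw)
    }
    counts[, j] <- stats::rmultinom(1, cfg$sequencing_depth, comp)
  }
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]

  meta <- data.frame(
    sample_id = sample_ids,
    species_id = sample_species,
    group_id = sample_group,
    replicate_index = rep(seq_len(reps), n_sp),
    stringsAsFactors = FALSE
  )

  guilds <- .simGuilds(rownames(counts), marker_ids)
  tree <- .simTree(species, sp_group, cfg$group_structured_tree)

  ee <- EndophyteExperiment(counts, meta,
    traits = traits, tree = tree,
    guilds = guilds, proportions = FALSE, dropEmpty = FALSE
  )
  truth <- list(
    markers = marker_ids,
    latent = latent,
    gradient = stats::setNames(grad, species),
    driver = cfg$turnover_driver,
    strength = cfg$turnover_strength
  )
  list(experiment = ee, truth = truth)
}

# trophic modes: background drawn from a broad mixture; planted markers
# biased to a group-specific dominant mode (legume-like groups lean
# symbiotrophic, forb-like groups pathotrophic) so guild-level contrasts
# exist to detect
.simGuilds <- function(otu_ids, marker_ids) {
  modes <- .TROPHIC_MODES
  bg_prob <- c(0.18, 0.30, 0.10, 0.12, 0.04, 0.06, 0.05, 0.15)
  g <- sample(modes, length(otu_ids), replace = TRUE, prob = bg_prob)
  names(g) <- otu_ids
  dominant <- c(
    "Pathotroph-Saprotroph-Symbiotroph", "Symbiotroph",
    "Pathotroph", "Unclassified"
  )
  for (i in seq_along(marker_ids)) {
    ids <- intersect(marker_ids[[i]], otu_ids)
    dom <- dominant[(i - 1L) %% length(dominant) + 1L]
    pick <- stats::runif(length(ids)) < 0.8
    g[ids[pick]] <- dom
    g[ids[!pick]] <- sample(modes, sum(!pick), replace = TRUE, prob = bg_prob)
  }
  data.frame(otu_id = otu_ids, trophic_mode = unname(g[otu_ids]))
}

.simTree <- function(species, sp_group, group_structured) {
  if (!group_structured) {
    return(ape::rcoal(length(species), tip.label = sample(species)))
  }
  parts <- vapply(unique(sp_group), function(g) {
    tips <- species[sp_group == g]
    if (length(tips) == 1) {
      paste0(tips, ":1")
    } else {
      sub <- ape::rcoal(length(tips), tip.label = sample(tips))
      paste0(sub("; *$", "", ape::write.tree(sub)), ":1")
    }
  }, character(1))
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

#' Exchangeable null community
#'
#' Runs [simulateCommunity()] and then shuffles the per-sample group
#' labels uniformly at random, detaching group identity from community
#' composition while preserving every per-sample count vector. The result
#' is an exchangeable null for PERMANOVA type-I error studies.
#'
#' @inheritParams simulateCommunity
#' @return an [EndophyteExperiment-class] (traits/tree/guilds attached;
#'   note species-to-group nesting is intentionally broken by the
#'   shuffle).
#' @export
nullCommunity <- function(cfg, seed = cfg$seed) {
  sim <- simulateCommunity(cfg, seed = seed)
  ee <- sim$experiment
  grp <- colData(ee)$group_id
  colData(ee)$group_id <- grp[sample(length(grp))]
  ee
}
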