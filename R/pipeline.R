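#' Pipeline configuration
#'
#' Validates the configuration driving [runPipeline()]. Exactly one data
#' source must be given: `simulate` (arguments for [simConfig()]) or
#' `inputs` (paths to the OTU, metadata, trait, guild and tree files). A
#' seed is mandatory whenever any stochastic stage runs (simulation or
#' permutation tests).
#'
#' @param outdir output directory (created if absent).
#' @param seed integer master seed; every stochastic stage derives its
#'   own seed from it.
#' @param n_perm permutations for the PERMANOVA stages (default 999).
#' @param marker_threshold dual SPEC-OCCU threshold, in (0.5, 1].
#' @param proportions whether input abundance tables hold proportions.
#' @param aggregation species-level community profile: `"mean"` of
#'   replicate proportion vectors (default) or `"pool"`ed counts.
#' @param simulate `NULL`, or a list of [simConfig()] arguments (or a
#'   ready `sim_config`).
#' @param inputs `NULL`, or a named list of paths: `otu`, `metadata`,
#'   `traits`, and optionally `guilds`, `tree`.
#' @return validated `pipeline_config` list.
#' @export
pipelineConfig <- function(outdir, seed = NULL, n_perm = 999,
                           marker_threshold = 0.7, proportions = FALSE,
                           aggregation = c("mean", "pool"),
                           simulate = NULL, inputs = NULL) {
  aggregation <- match.arg(aggregation)
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of 'simulate' or 'inputs' must be given")
  }
  if (marker_threshold <= 0.5 || marker_threshold > 1) {
    stop("marker_threshold must lie in (0.5, 1]")
  }
  stochastic <- !is.null(simulate) || n_perm > 0
  if (stochastic && is.null(seed)) {
    stop("seed is required when any stochastic stage runs")
  }
  if (!is.null(inputs)) {
    miss <- setdiff(c("otu", "metadata", "traits"), names(inputs))
    if (length(miss)) {
      stop("inputs lack: ", paste(miss, collapse = ", "))
    }
  }
  cfg <- list(
    outdir = outdir, seed = if (is.null(seed)) NULL else as.integer(seed),
    n_perm = as.integer(n_perm), marker_threshold = marker_threshold,
    proportions = isTRUE(proportions), aggregation = aggregation,
    simulate = simulate, inputs = inputs
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipelineConfig()].
#' @return validated `pipeline_config`.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null"
  )
  path
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, alpha diversity, beta diversity, marker-OTU
#' and distance-LMM stages on one configuration, writing every result
#' table (TSV) and statistic (JSON) plus a manifest of md5 content
#' hashes to `outdir`. Identical configuration and seed give
#' bit-identical manifests. Any stage error aborts with the stage name.
#' The run log records the analysis choices actually taken (abundance
#' normalization, species aggregation, denominator-df method) so a run
#' is self-describing.
#'
#' @param config a `pipeline_config` from [pipelineConfig()], a YAML
#'   path, or a plain list of [pipelineConfig()] arguments.
#' @param ... overrides applied over `config` (e.g. `seed = 7`);
#'   precedence: arguments > config file > defaults.
#' @return invisibly, the manifest list (`files`: relative path -> md5).
#' @export
runPipeline <- function(config, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipelineConfig, utils::modifyList(
      as.list(config),
      list(...)
    ))
  } else if (length(list(...))) {
    config <- do.call(pipelineConfig, utils::modifyList(
      unclass(config)[!vapply(unclass(config), is.null, TRUE)],
      list(...)
    ))
  }
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log_lines <- c(
    paste0("seed: ", config$seed),
    paste0("n_perm: ", config$n_perm),
    paste0("marker_threshold: ", config$marker_threshold),
    paste0(
      "abundance_normalization: ",
      "per-sample proportions for distances and SPEC-OCCU"
    ),
    paste0("species_aggregation: ", config$aggregation),
    "denominator_df: satterthwaite"
  )

  # ---- load / simulate --------------------------------------------------
  ee <- .stage("input", {
    if (!is.null(config$simulate)) {
      sim_cfg <- if (inherits(config$simulate, "sim_config")) {
        config$simulate
      } else {
        do.call(simConfig, config$simulate)
      }
      sim <- simulateCommunity(sim_cfg, seed = config$seed)
      writeOtuTable(
        sim$experiment, file.path(out, "otu_table.tsv"),
        file.path(out, "sample_metadata.tsv")
      )
      writeSpeciesTraits(
        speciesTraits(sim$experiment),
        file.path(out, "species_traits.tsv")
      )
      writeGuildTable(
        data.frame(
          otu_id = rownames(sim$experiment),
          trophic_mode = unname(guildAssignments(sim$experiment))
        ),
        file.path(out, "guilds.tsv")
      )
      writeHostTree(
        hostTree(sim$experiment),
        file.path(out, "host_tree.nwk")
      )
      .writeJson(
        list(
          markers = sim$truth$markers,
          driver = sim$truth$driver,
          strength = sim$truth$strength
        ),
        file.path(out, "sim_truth.json")
      )
      files <- c(
        files, "otu_table.tsv", "sample_metadata.tsv",
        "species_traits.tsv", "guilds.tsv", "host_tree.nwk",
        "sim_truth.json"
      )
      sim$experiment
    } else {
      x <- readOtuTable(config$inputs$otu, config$inputs$metadata,
        proportions = config$proportions
      )
      speciesTraits(x) <- readSpeciesTraits(config$inputs$traits)
      if (!is.null(config$inputs$guilds)) {
        guildAssignments(x) <- readGuildTable(config$inputs$guilds)
      }
      if (!is.null(config$inputs$tree)) {
        hostTree(x) <- readHostTree(config$inputs$tree,
          species = unique(sampleInfo(x)$species_id)
        )
      }
      x
    }
  })

  # ---- alpha ------------------------------------------------------------
  .stage("alpha", {
    al <- alphaDiversity(ee)
    fm <- alphaFactorModels(al, speciesTraits(ee))
    files <- c(
      files,
      {
        .writeTsv(al@samples, file.path(out, "alpha_samples.tsv"))
        "alpha_samples.tsv"
      },
      {
        .writeTsv(al@species, file.path(out, "alpha_species.tsv"))
        "alpha_species.tsv"
      },
      {
        .writeTsv(al@groups, file.path(out, "alpha_groups.tsv"))
        "alpha_groups.tsv"
      },
      {
        .writeTsv(fm, file.path(out, "alpha_factor_models.tsv"))
        "alpha_factor_models.tsv"
      }
    )
  })

  # ---- beta -------------------------------------------------------------
  .stage("beta", {
    bc <- brayCurtis(ee,
      level = "species",
      normalize = TRUE
    )
    ord <- pcoa(bc)
    labs <- speciesGroups(ee)
    pw <- pairwisePermanova(bc, labs,
      n_perm = config$n_perm,
      seed = (config$seed + 101L) %% 2147483647L
    )
    files <- c(
      files,
      {
        .writeTsv(
          data.frame(species_id = rownames(bc), bc,
            check.names = FALSE
          ),
          file.path(out, "bray_curtis_species.tsv")
        )
        "bray_curtis_species.tsv"
      },
      {
        .writeTsv(
          data.frame(
            species_id = rownames(ord$coordinates),
            ord$coordinates[, seq_len(min(4, ncol(ord$coordinates))),
              drop = FALSE
            ]
          ),
          file.path(out, "pcoa_coordinates.tsv")
        )
        "pcoa_coordinates.tsv"
      },
      {
        .writeJson(
          list(
            pairwise = pw,
            prop_explained = ord$prop_explained[
              seq_len(min(4, length(ord$prop_explained)))
            ]
          ),
          file.path(out, "permanova.json")
        )
        "permanova.json"
      }
    )
  })

  # ---- markers ----------------------------------------------------------
  .stage("markers", {
    so <- specOccu(ee, threshold = config$marker_threshold)
    mk <- filterMarkers(so, threshold = config$marker_threshold)
    files <- c(
      files,
      {
        .writeTsv(so, file.path(out, "spec_occu.tsv"))
        "spec_occu.tsv"
      },
      {
        .writeTsv(mk, file.path(out, "markers.tsv"))
        "markers.tsv"
      }
    )
    if (nrow(mk)) {
      gp <- markerGuildProfile(mk, ee)
      mfo <- markerFunctionOrdination(mk, ee,
        n_perm = config$n_perm,
        seed = (config$seed + 202L) %% 2147483647L
      )
      files <- c(
        files,
        {
          .writeTsv(gp$profile, file.path(out, "marker_guilds.tsv"))
          "marker_guilds.tsv"
        },
        {
          .writeJson(
            list(
              marker_share = as.list(gp$marker_share),
              function_permanova = mfo$permanova
            ),
            file.path(out, "marker_function.json")
          )
          "marker_function.json"
        }
      )
    } else {
      log_lines <- c(log_lines, "markers: none found; guild stage skipped")
    }
  })

  # ---- distance LMM -----------------------------------------------------
  .stage("dlmm", {
    if (is.null(hostTree(ee))) {
      log_lines <- c(log_lines, "dlmm: skipped (no host tree)")
    } else {
      bc <- brayCurtis(ee, level = "species")
      ph <- copheneticDistances(hostTree(ee),
        species = rownames(bc)
      )
      des <- buildPairDesign(bc, speciesTraits(ee), ph)
      fit <- fitDistanceLmm(des)
      hp <- hierarchicalPartition(des)
      tab <- merge(fit$coefficients,
        hp[, c("predictor", "individual_r2")],
        by = "predictor", sort = FALSE
      )
      files <- c(
        files,
        {
          .writeTsv(as.data.frame(des), file.path(out, "pair_design.tsv"))
          "pair_design.tsv"
        },
        {
          .writeJson(
            list(
              n = fit$n,
              table = data.frame(
                X = tab$predictor, F = tab$F, p = tab$p,
                individual_importance_R2 = tab$individual_r2
              ),
              r2_marginal = fit$r2_marginal,
              r2_conditional = fit$r2_conditional,
              varcomp = as.list(fit$varcomp)
            ),
            file.path(out, "dlmm_results.json")
          )
          "dlmm_results.json"
        }
      )
    }
  })

  # ---- manifest ---------------------------------------------------------
  writeLines(log_lines, file.path(out, "pipeline_log.txt"))
  files <- c(files, "pipeline_log.txt")
  hashes <- as.list(tools::md5sum(file.path(out, files)))
  names(hashes) <- files
  manifest <- list(
    seed = config$seed, n_perm = config$n_perm,
    marker_threshold = config$marker_threshold,
    aggregation = config$aggregation,
    files = hashes
  )
  .writeJson(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}
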