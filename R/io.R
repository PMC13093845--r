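#' Read an OTU abundance table with sample metadata
#'
#' Reads a tab-separated OTU abundance table plus its sample metadata and
#' returns a validated [EndophyteExperiment-class]. The native dialect has
#' samples as rows (first header cell `sample_id`); the transposed dialect
#' with OTUs as rows is auto-detected via the header sentinel `otu_id` and
#' normalized on load. OTU columns that are zero everywhere are dropped
#' with a warning. Every sample must have a metadata row; a sample without
#' one is a hard error naming the sample.
#'
#' @param path TSV abundance table. Samples-as-rows dialect: first column
#'   `sample_id`, remaining columns one per OTU. OTUs-as-rows dialect:
#'   first column `otu_id`, remaining columns one per sample.
#' @param metadata_path TSV with columns `sample_id`, `species_id`,
#'   `group_id`, `replicate_index`.
#' @param proportions logical; set `TRUE` when the table stores per-sample
#'   relative abundances rather than counts.
#' @return an [EndophyteExperiment-class] (no traits/tree/guilds attached).
#' @export
readOtuTable <- function(path, metadata_path, proportions = FALSE) {
  raw <- utils::read.delim(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    colClasses = "character"
  )
  if (ncol(raw) < 2) stop("OTU table needs an id column plus data columns")
  sentinel <- colnames(raw)[1]
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated ids in OTU table: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  num <- as.matrix(raw[, -1, drop = FALSE])
  parsed <- suppressWarnings(array(as.numeric(num), dim = dim(num)))
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed), arr.ind = TRUE)[1, ]
    stop(
      "non-numeric abundance at row ", bad[1], " (id '", ids[bad[1]],
      "'), column '", colnames(num)[bad[2]], "'",
      call. = FALSE
    )
  }
  dimnames(parsed) <- list(ids, colnames(num))
  counts <- switch(sentinel,
    sample_id = t(parsed), # native: samples x OTUs on disk
    otu_id = parsed, # transposed dialect: already OTUs x samples
    stop(
      "first header cell must be 'sample_id' or 'otu_id', got '",
      sentinel, "'",
      call. = FALSE
    )
  )
  if (any(counts < 0)) stop("negative abundances in OTU table")
  if (all(counts == round(counts)) &&
    max(counts) <= .Machine$integer.max) {
    storage.mode(counts) <- "integer"
  }
  meta <- utils::read.delim(metadata_path,
    header = TRUE, sep = "\t",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  need <- c("sample_id", "species_id", "group_id", "replicate_index")
  miss <- setdiff(need, colnames(meta))
  if (length(miss)) {
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata")
  }
  EndophyteExperiment(counts, meta,
    proportions = proportions,
    dropEmpty = TRUE
  )
}

#' Write an OTU table and its metadata to TSV
#'
#' Inverse of [readOtuTable()] (samples-as-rows dialect). Integer counts
#' are written as integers so that a write/read cycle is lossless.
#'
#' @param x an [EndophyteExperiment-class].
#' @param path,metadata_path output TSV paths.
#' @return `x`, invisibly.
#' @export
writeOtuTable <- function(x, path, metadata_path) {
  m <- t(otuCounts(x)) # samples x OTUs on disk
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  utils::write.table(sampleInfo(x), metadata_path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(x)
}

#' Read a species-level trait table
#'
#' One row per host species with the leaf functional traits and the plot
#' abundance used as predictors throughout: `lma` (leaf mass per area,
#' g/cm^2), `n_conc` (leaf nitrogen, mg/g), `cn_ratio`, `water_content`
#' (percent of fresh weight) and `abundance` (plot occurrence count).
#' Trait invariants (`lma > 0`, `cn_ratio > 0`,
#' `0 <= water_content <= 100`, `abundance >= 0`) and species uniqueness
#' are enforced as hard errors.
#'
#' @param path TSV with columns `species_id`, `group_id`, `lma`, `n_conc`,
#'   `cn_ratio`, `water_content`, `abundance`.
#' @return data.frame, one row per species.
#' @export
readSpeciesTraits <- function(path) {
  tr <- utils::read.delim(path,
    header = TRUE, sep = "\t",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  validateTraits(tr)
}

#' Validate a species trait table
#'
#' @param tr data.frame as described in [readSpeciesTraits()].
#' @return the validated data.frame (invisibly the same object).
#' @export
validateTraits <- function(tr) {
  need <- c(
    "species_id", "group_id", "lma", "n_conc", "cn_ratio",
    "water_content", "abundance"
  )
  miss <- setdiff(need, colnames(tr))
  if (length(miss)) {
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "))
  }
  dup <- unique(tr$species_id[duplicated(tr$species_id)])
  if (length(dup)) {
    stop("duplicated species_id: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  num <- c("lma", "n_conc", "cn_ratio", "water_content", "abundance")
  for (v in num) {
    if (!is.numeric(tr[[v]]) || anyNA(tr[[v]])) {
      stop("trait column '", v, "' must be numeric without NA")
    }
  }
  if (any(tr$lma <= 0)) stop("lma must be > 0", call. = FALSE)
  if (any(tr$cn_ratio <= 0)) stop("cn_ratio must be > 0", call. = FALSE)
  if (any(tr$water_content < 0 | tr$water_content > 100)) {
    stop("water_content must lie in [0, 100]", call. = FALSE)
  }
  if (any(tr$abundance < 0)) stop("abundance must be >= 0", call. = FALSE)
  tr
}

#' Write a species trait table to TSV
#' @param tr trait data.frame (see [readSpeciesTraits()]).
#' @param path output TSV path.
#' @return `tr`, invisibly.
#' @export
writeSpeciesTraits <- function(tr, path) {
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tr)
}

#' Read a FUNGuild-style guild annotation table
#'
#' Maps OTU ids to a trophic mode drawn from a closed vocabulary
#' (Pathotroph / Saprotroph / Symbiotroph, their hyphenated combinations,
#' or Unclassified). OTUs present in an experiment but absent from the
#' table are treated as `Unclassified` when the annotations are attached
#' via [guildAssignments<-].
#'
#' @param path TSV with columns `otu_id`, `trophic_mode`.
#' @return data.frame with columns `otu_id`, `trophic_mode`.
#' @export
readGuildTable <- function(path) {
  g <- utils::read.delim(path,
    header = TRUE, sep = "\t",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  miss <- setdiff(c("otu_id", "trophic_mode"), colnames(g))
  if (length(miss)) {
    stop("guild table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(g$otu_id)) stop("duplicated otu_id in guild table")
  bad <- setdiff(unique(g$trophic_mode), .TROPHIC_MODES)
  if (length(bad)) {
    stop("unknown trophic mode(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  g[, c("otu_id", "trophic_mode")]
}

#' Write a guild annotation table to TSV
#' @param g data.frame with columns `otu_id`, `trophic_mode`.
#' @param path output TSV path.
#' @return `g`, invisibly.
#' @export
writeGuildTable <- function(g, path) {
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(g)
}

#' Read a host phylogeny from Newick
#'
#' @param path Newick file; leaf labels are species ids; branch lengths
#'   must be non-negative.
#' @param species optional character vector of species ids that the tree
#'   must cover; missing species are a hard error listing the ids.
#' @return an [ape::phylo] tree.
#' @export
readHostTree <- function(path, species = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree from ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated leaf labels in host tree")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths in host tree")
  }
  if (!is.null(species)) {
    miss <- setdiff(species, tree$tip.label)
    if (length(miss)) {
      stop("host tree is missing species: ", paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
  }
  tree
}

#' Write a host phylogeny to Newick
#' @param tree an [ape::phylo].
#' @param path output path.
#' @return `tree`, invisibly.
#' @export
writeHostTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(tree)
}
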