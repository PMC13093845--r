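#' Accessors for EndophyteExperiment
#'
#' Small accessor layer over the slots of
#' [EndophyteExperiment-class]: the abundance matrix, host metadata,
#' species traits, guild annotations and the host tree.
#'
#' @param x an `EndophyteExperiment`.
#' @param value replacement value (see individual setters).
#' @name endophyte-accessors
NULL

#' @describeIn endophyte-accessors abundance matrix (OTUs x samples).
#' @export
otuCounts <- function(x) {
  stopifnot(is(x, "EndophyteExperiment"))
  assay(x, "counts")
}

#' @describeIn endophyte-accessors per-sample host metadata as a data.frame
#'   with columns `sample_id`, `species_id`, `group_id`, `replicate_index`.
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "EndophyteExperiment"))
  cd <- as.data.frame(colData(x))
  data.frame(
    sample_id = colnames(x),
    species_id = as.character(cd$species_id),
    group_id = as.character(cd$group_id),
    replicate_index = cd$replicate_index,
    stringsAsFactors = FALSE
  )
}

#' @describeIn endophyte-accessors species-level trait table (data.frame).
#' @export
speciesTraits <- function(x) {
  stopifnot(is(x, "EndophyteExperiment"))
  as.data.frame(x@traits)
}

#' @describeIn endophyte-accessors set the species trait table.
#' @export
`speciesTraits<-` <- function(x, value) {
  x@traits <- S4Vectors::DataFrame(as.data.frame(value))
  validObject(x)
  x
}

#' @describeIn endophyte-accessors host phylogeny ([ape::phylo] or `NULL`).
#' @export
hostTree <- function(x) {
  stopifnot(is(x, "EndophyteExperiment"))
  x@tree
}

#' @describeIn endophyte-accessors set the host phylogeny.
#' @export
`hostTree<-` <- function(x, value) {
  x@tree <- value
  validObject(x)
  x
}

#' @describeIn endophyte-accessors per-OTU trophic modes (named character).
#' @export
guildAssignments <- function(x) {
  stopifnot(is(x, "EndophyteExperiment"))
  g <- rowData(x)$trophic_mode
  names(g) <- rownames(x)
  g
}

#' @describeIn endophyte-accessors set per-OTU trophic modes (named
#'   character vector or `otu_id`/`trophic_mode` data.frame; unannotated
#'   OTUs become `"Unclassified"`).
#' @export
`guildAssignments<-` <- function(x, value) {
  rowData(x)$trophic_mode <- .normalizeGuilds(value, rownames(x))
  x
}

#' @describeIn endophyte-accessors `TRUE` when the counts assay holds
#'   per-sample relative abundances.
#' @export
isProportions <- function(x) {
  stopifnot(is(x, "EndophyteExperiment"))
  x@proportions
}

#' Per-sample relative abundances
#'
#' Returns the experiment with its `counts` assay normalized so each
#' sample (column) sums to one. A no-op when the table already holds
#' proportions.
#'
#' @param x an [EndophyteExperiment-class].
#' @return an `EndophyteExperiment` with `isProportions(x)` `TRUE`.
#' @export
asProportions <- function(x) {
  stopifnot(is(x, "EndophyteExperiment"))
  if (x@proportions) {
    return(x)
  }
  m <- assay(x, "counts")
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop(
      "sample(s) with zero total abundance: ",
      paste(colnames(m)[cs == 0], collapse = ", "),
      call. = FALSE
    )
  }
  SummarizedExperiment::assay(x, "counts") <- sweep(m, 2, cs, "/")
  x@proportions <- TRUE
  x
}

#' Species-level community profiles
#'
#' Aggregates replicate samples to one community profile per host species:
#' each sample is converted to relative abundances and the replicate
#' proportion vectors of a species are averaged (alternatively, replicate
#' counts are pooled and then normalized).
#'
#' @param x an [EndophyteExperiment-class].
#' @param method `"mean"` (default) averages replicate proportion vectors;
#'   `"pool"` sums replicate counts before normalizing.
#' @return numeric matrix, species x OTUs, rows summing to 1.
#' @export
speciesProfiles <- function(x, method = c("mean", "pool")) {
  method <- match.arg(method)
  info <- sampleInfo(x)
  if (method == "pool" && x@proportions) {
    stop("method = 'pool' needs raw counts, table holds proportions")
  }
  if (method == "mean") {
    m <- otuCounts(asProportions(x))
  } else {
    m <- otuCounts(x)
  }
  sp <- unique(info$species_id)
  out <- matrix(0, length(sp), nrow(m), dimnames = list(sp, rownames(m)))
  for (s in sp) {
    cols <- info$sample_id[info$species_id == s]
    out[s, ] <- rowMeans(m[, cols, drop = FALSE])
  }
  if (method == "pool") out <- out / rowSums(out)
  out
}

#' @describeIn endophyte-accessors map species id -> functional group id.
#' @export
speciesGroups <- function(x) {
  info <- sampleInfo(x)
  g <- info$group_id[!duplicated(info$species_id)]
  names(g) <- info$species_id[!duplicated(info$species_id)]
  g
}
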