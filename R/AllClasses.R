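#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DFrame
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData colData<- rowData rowData<-
NULL

# Trophic-mode vocabulary (FUNGuild-style): single modes, hyphenated
# combinations in canonical order, or Unclassified.
.TROPHIC_MODES <- c(
  "Pathotroph", "Saprotroph", "Symbiotroph",
  "Pathotroph-Saprotroph", "Pathotroph-Symbiotroph",
  "Saprotroph-Symbiotroph", "Pathotroph-Saprotroph-Symbiotroph",
  "Unclassified"
)

#' Container for a leaf fungal endophyte survey
#'
#' `EndophyteExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' with the pieces a functional-group endophyte analysis needs: a `counts`
#' assay (OTUs as rows, samples as columns), per-sample host metadata
#' (`species_id`, `group_id`, `replicate_index` in `colData`), optional
#' per-OTU trophic guild annotations (`trophic_mode` in `rowData`), a
#' species-level trait table and a host phylogeny.
#'
#' @slot tree a rooted [ape::phylo] host tree whose tips cover the host
#'   species, or `NULL`.
#' @slot traits a [S4Vectors::DataFrame] of species-level traits
#'   (possibly zero rows): `species_id`, `group_id`, `lma` (g/cm^2),
#'   `n_conc` (mg/g), `cn_ratio`, `water_content` (percent of fresh
#'   weight), `abundance` (plot occurrence count).
#' @slot proportions logical flag: `TRUE` when the `counts` assay already
#'   holds per-sample relative abundances rather than read counts.
#'
#' @seealso [EndophyteExperiment()] for construction,
#'   [readOtuTable()] for import from TSV.
#' @exportClass EndophyteExperiment
setClass("EndophyteExperiment",
  contains = "SummarizedExperiment",
  slots = c(tree = "ANY", traits = "DFrame", proportions = "logical"),
  prototype = prototype(
    tree = NULL,
    traits = S4Vectors::DataFrame(),
    proportions = FALSE
  )
)

.validEndophyteExperiment <- function(object) {
  msg <- character(0)
  if (!("counts" %in% assayNames(object))) {
    return("assay 'counts' is required")
  }
  m <- assay(object, "counts")
  if (any(!is.finite(m)) || any(m < 0)) {
    msg <- c(msg, "counts must be finite and non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "OTU ids (rownames) must be present and unique")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  }
  cd <- colData(object)
  need <- c("species_id", "group_id", "replicate_index")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  } else {
    if (anyNA(cd$species_id) || anyNA(cd$group_id)) {
      msg <- c(msg, "species_id / group_id must not contain NA")
    }
  }
  if (!is.null(object@tree)) {
    if (!inherits(object@tree, "phylo")) {
      msg <- c(msg, "tree must be an ape 'phylo' object or NULL")
    } else if (!length(miss)) {
      sp <- unique(as.character(cd$species_id))
      lost <- setdiff(sp, object@tree$tip.label)
      if (length(lost)) {
        msg <- c(msg, paste0(
          "host tree is missing species: ",
          paste(lost, collapse = ", ")
        ))
      }
      if (anyDuplicated(object@tree$tip.label)) {
        msg <- c(msg, "host tree has duplicated tip labels")
      }
    }
  }
  tr <- object@traits
  if (nrow(tr) > 0) {
    tneed <- c(
      "species_id", "group_id", "lma", "n_conc", "cn_ratio",
      "water_content", "abundance"
    )
    tmiss <- setdiff(tneed, colnames(tr))
    if (length(tmiss)) {
      msg <- c(msg, paste0("traits lack: ", paste(tmiss, collapse = ", ")))
    } else {
      if (anyDuplicated(tr$species_id)) {
        msg <- c(msg, "duplicated species_id in traits")
      }
      if (any(tr$lma <= 0)) msg <- c(msg, "traits: lma must be > 0")
      if (any(tr$cn_ratio <= 0)) msg <- c(msg, "traits: cn_ratio must be > 0")
      if (any(tr$water_content < 0 | tr$water_content > 100)) {
        msg <- c(msg, "traits: water_content must lie in [0, 100]")
      }
      if (any(tr$abundance < 0)) msg <- c(msg, "traits: abundance must be >= 0")
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("EndophyteExperiment", .validEndophyteExperiment)

#' Construct an EndophyteExperiment
#'
#' @param counts numeric matrix of abundances, OTUs as rows and samples as
#'   columns, with unique dimnames.
#' @param sampleData data.frame (or DataFrame) with one row per sample and
#'   columns `sample_id` (or rownames), `species_id`, `group_id`,
#'   `replicate_index`.
#' @param traits optional species-level trait table (see
#'   [readSpeciesTraits()] for the column contract).
#' @param tree optional [ape::phylo] host tree covering all host species.
#' @param guilds optional per-OTU trophic annotation: either a named
#'   character vector (names = OTU ids) or a data.frame with columns
#'   `otu_id`, `trophic_mode`. OTUs without an annotation are recorded as
#'   `"Unclassified"`.
#' @param proportions logical; `TRUE` when `counts` holds per-sample
#'   relative abundances.
#' @param dropEmpty drop OTUs with zero total abundance (with a warning
#'   reporting how many were removed). Default `TRUE`.
#'
#' @return a validated [EndophyteExperiment-class] object.
#' @examples
#' m <- matrix(c(5, 1, 0, 2, 0, 3), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' sd <- data.frame(sample_id = c("s1", "s2"),
#'                  species_id = c("spA", "spA"),
#'                  group_id = c("grass", "grass"),
#'                  replicate_index = 1:2)
#' EndophyteExperiment(m, sd)
#' @export
EndophyteExperiment <- function(counts, sampleData, traits = NULL,
                                tree = NULL, guilds = NULL,
                                proportions = FALSE, dropEmpty = TRUE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  sampleData <- as.data.frame(sampleData)
  if ("sample_id" %in% colnames(sampleData)) {
    rownames(sampleData) <- as.character(sampleData$sample_id)
    sampleData$sample_id <- NULL
  }
  if (is.null(colnames(counts))) {
    stop("counts must carry sample ids as column names")
  }
  miss <- setdiff(colnames(counts), rownames(sampleData))
  if (length(miss)) {
    stop(
      "no metadata for sample(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  sampleData <- sampleData[colnames(counts), , drop = FALSE]
  if (dropEmpty) {
    empty <- rowSums(counts) == 0
    if (any(empty)) {
      warning(
        sum(empty), " OTU(s) with zero total abundance dropped",
        call. = FALSE
      )
      counts <- counts[!empty, , drop = FALSE]
    }
  }
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  rd$trophic_mode <- .normalizeGuilds(guilds, rownames(counts))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sampleData),
    rowData = rd
  )
  traits <- if (is.null(traits)) {
    S4Vectors::DataFrame()
  } else {
    S4Vectors::DataFrame(as.data.frame(traits))
  }
  new("EndophyteExperiment",
    se,
    tree = tree, traits = traits,
    proportions = isTRUE(proportions)
  )
}

# guilds -> character vector aligned to otu_ids; NULL allowed (all NA)
.normalizeGuilds <- function(guilds, otu_ids) {
  if (is.null(guilds)) {
    return(rep(NA_character_, length(otu_ids)))
  }
  if (is.data.frame(guilds)) {
    v <- as.character(guilds$trophic_mode)
    names(v) <- as.character(guilds$otu_id)
    guilds <- v
  }
  bad <- setdiff(unique(guilds), .TROPHIC_MODES)
  if (length(bad)) {
    stop(
      "unknown trophic mode(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  out <- unname(guilds[otu_ids])
  out[is.na(out)] <- "Unclassified"
  out
}

setMethod("show", "EndophyteExperiment", function(object) {
  cd <- colData(object)
  cat(
    "EndophyteExperiment:", nrow(object), "OTUs x", ncol(object),
    "samples\n"
  )
  cat(
    " ", length(unique(cd$species_id)), "host species in",
    length(unique(cd$group_id)), "functional group(s):",
    paste(sort(unique(as.character(cd$group_id))), collapse = ", "), "\n"
  )
  cat(
    "  abundances:",
    if (object@proportions) "proportions" else "counts", "\n"
  )
  cat(
    "  traits:", nrow(object@traits), "species;  tree:",
    if (is.null(object@tree)) "absent" else "present", ";  guilds:",
    if (all(is.na(rowData(object)$trophic_mode))) {
      "absent"
    } else {
      "annotated"
    }, "\n"
  )
  invisible(NULL)
})
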