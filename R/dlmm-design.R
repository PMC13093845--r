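#' Cophenetic (patristic) distances between host species
#'
#' Sum of branch lengths along the tree path between every pair of
#' leaves.
#'
#' @param tree an [ape::phylo] host tree with branch lengths.
#' @param species optional species ids to extract (in this order); every
#'   id must be a tip of the tree.
#' @return symmetric matrix of patristic distances with species ids as
#'   dimnames.
#' @export
copheneticDistances <- function(tree, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(species)) {
    miss <- setdiff(species, rownames(d))
    if (length(miss)) {
      stop("tree is missing species: ", paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    d <- d[species, species, drop = FALSE]
  }
  d
}

.PAIR_PREDICTORS <- c(
  "abundance", "n_conc", "cn_ratio", "water_content",
  "lma", "phylo"
)

#' Cross-group species-pair design for the distance mixed model
#'
#' Builds one row per unordered pair of host species from *different*
#' functional groups. The response is the Bray-Curtis dissimilarity of
#' the two species' endophyte profiles; the predictors are the absolute
#' (Euclidean, for scalars) trait differences |d abundance|, |d n_conc|,
#' |d cn_ratio|, |d water_content|, |d lma| and the cophenetic
#' phylogenetic distance. Predictors are z-standardized; the centering
#' and scaling constants are recorded in the `"scaling"` attribute.
#' With group sizes \eqn{n_1..n_G} the design has
#' \eqn{\sum_{g<h} n_g n_h} rows.
#'
#' @param bc species-level Bray-Curtis matrix (e.g.
#'   `brayCurtis(x, level = "species")`).
#' @param traits species trait table covering every species in `bc`.
#' @param phylo cophenetic distance matrix from [copheneticDistances()].
#' @param includeWithinGroup also keep within-group pairs (sensitivity
#'   analysis; default `FALSE`, the cross-group design).
#' @param standardize z-score the predictors (default `TRUE`).
#' @return data.frame of class `pair_design` with columns `species_a`,
#'   `species_b`, `group_a`, `group_b`, `response` and the six predictor
#'   columns; attribute `scaling` holds the per-predictor center/scale.
#' @export
buildPairDesign <- function(bc, traits, phylo, includeWithinGroup = FALSE,
                            standardize = TRUE) {
  traits <- validateTraits(traits)
  sp <- traits$species_id
  for (nm in c("bc", "phylo")) {
    d <- get(nm)
    miss <- setdiff(sp, rownames(d))
    if (length(miss)) {
      stop(nm, " matrix is missing species: ",
        paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
  }
  untraited <- setdiff(rownames(bc), sp)
  if (length(untraited)) {
    stop("species without trait records: ",
      paste(untraited, collapse = ", "),
      call. = FALSE
    )
  }
  rownames(traits) <- sp
  pairs <- utils::combn(sp, 2, simplify = FALSE)
  grp <- stats::setNames(as.character(traits$group_id), sp)
  rows <- lapply(pairs, function(pr) {
    a <- pr[1]
    b <- pr[2]
    if (!includeWithinGroup && grp[a] == grp[b]) {
      return(NULL)
    }
    data.frame(
      species_a = a, species_b = b,
      group_a = grp[a], group_b = grp[b],
      response = bc[a, b],
      abundance = abs(traits[a, "abundance"] - traits[b, "abundance"]),
      n_conc = abs(traits[a, "n_conc"] - traits[b, "n_conc"]),
      cn_ratio = abs(traits[a, "cn_ratio"] - traits[b, "cn_ratio"]),
      water_content = abs(traits[a, "water_content"] -
        traits[b, "water_content"]),
      lma = abs(traits[a, "lma"] - traits[b, "lma"]),
      phylo = phylo[a, b],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  scaling <- NULL
  if (standardize) {
    scaling <- data.frame(
      predictor = .PAIR_PREDICTORS,
      center = vapply(.PAIR_PREDICTORS, function(v) mean(out[[v]]), 1),
      scale = vapply(.PAIR_PREDICTORS, function(v) stats::sd(out[[v]]), 1),
      stringsAsFactors = FALSE
    )
    for (v in .PAIR_PREDICTORS) {
      s <- scaling$scale[scaling$predictor == v]
      if (s > 0) {
        out[[v]] <- (out[[v]] - scaling$center[scaling$predictor == v]) / s
      }
    }
  }
  attr(out, "scaling") <- scaling
  class(out) <- c("pair_design", "data.frame")
  out
}
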