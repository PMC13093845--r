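#' Specificity and occupancy of every OTU in every functional group
#'
#' For OTU \eqn{S} and functional group \eqn{H}:
#' specificity \eqn{= N_{individuals,S,H} / N_{individuals,S}}, where
#' \eqn{N_{individuals,S,H}} is the mean abundance of \eqn{S} across the
#' samples of group \eqn{H} and \eqn{N_{individuals,S}} the sum of those
#' group means over all groups; occupancy
#' \eqn{= N_{sites,S,H} / N_{sites,H}}, the fraction of group-\eqn{H}
#' samples in which \eqn{S} is present (abundance strictly > 0). For
#' every OTU with nonzero total abundance the specificities sum to one
#' across groups, so at a threshold above 0.5 an OTU can mark at most one
#' group.
#'
#' @param x an [EndophyteExperiment-class] with at least two groups.
#' @param useProportions compute abundances on per-sample relative
#'   abundances (default, removing library-size bias); `FALSE` uses the
#'   table's raw values.
#' @param threshold dual threshold defining `is_marker`
#'   (specificity >= threshold AND occupancy >= threshold); default 0.7.
#' @return data.frame with one row per (OTU, group): `otu_id`,
#'   `group_id`, `specificity`, `occupancy`, `is_marker`. OTUs with zero
#'   total abundance are excluded with a message.
#' @export
specOccu <- function(x, useProportions = TRUE, threshold = 0.7) {
  info <- sampleInfo(x)
  if (length(unique(info$group_id)) < 2) stop("need >= 2 functional groups")
  m <- otuCounts(if (useProportions) asProportions(x) else x)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    message(sum(zero), " OTU(s) absent everywhere excluded from SPEC-OCCU")
    m <- m[!zero, , drop = FALSE]
  }
  groups <- sort(unique(info$group_id))
  group_means <- sapply(groups, function(g) {
    rowMeans(m[, info$group_id == g, drop = FALSE])
  })
  occ <- sapply(groups, function(g) {
    sub <- m[, info$group_id == g, drop = FALSE] > 0
    rowSums(sub) / ncol(sub)
  })
  spec <- group_means / rowSums(group_means)
  out <- data.frame(
    otu_id = rep(rownames(m), times = length(groups)),
    group_id = rep(groups, each = nrow(m)),
    specificity = as.vector(spec),
    occupancy = as.vector(occ),
    stringsAsFactors = FALSE
  )
  out$is_marker <- out$specificity >= threshold & out$occupancy >= threshold
  out
}

#' Filter marker OTUs by the dual specificity/occupancy threshold
#'
#' Keeps the (OTU, group) records whose specificity AND occupancy are
#' both greater than or equal to `threshold` (inclusive). Because
#' specificity sums to one over groups, a threshold above 0.5 guarantees
#' each OTU marks at most one group; this is asserted.
#'
#' @param records data.frame from [specOccu()].
#' @param threshold dual threshold, in (0.5, 1]; default 0.7.
#' @return the marker subset of `records`, with `is_marker` recomputed at
#'   `threshold`.
#' @export
filterMarkers <- function(records, threshold = 0.7) {
  stopifnot(all(c("otu_id", "group_id", "specificity", "occupancy")
  %in% colnames(records)))
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must lie in (0.5, 1]")
  }
  keep <- records$specificity >= threshold & records$occupancy >= threshold
  out <- records[keep, , drop = FALSE]
  out$is_marker <- TRUE
  if (anyDuplicated(out$otu_id)) {
    stop("internal error: an OTU marks more than one group")
  }
  rownames(out) <- NULL
  out
}

#' Trophic guild composition of each group's marker OTUs
#'
#' For every functional group with at least one marker OTU: the relative
#' abundance of each trophic mode among that group's markers (guild
#' shares weighted by the markers' mean relative abundance in the group's
#' samples, or by marker counts), plus the markers' share of the group's
#' total sequences.
#'
#' @param markers marker records from [filterMarkers()].
#' @param x the [EndophyteExperiment-class] the markers came from; OTUs
#'   without a guild annotation count as `Unclassified`.
#' @param weightByAbundance weight guild shares by marker abundance
#'   (default) rather than by the number of marker OTUs.
#' @return list with `profile` (data.frame: `group_id`, `trophic_mode`,
#'   `proportion`) and `marker_share` (named numeric: per-group share of
#'   total sequences attributable to that group's markers). Groups
#'   without markers get an empty profile and are reported via a message.
#' @export
markerGuildProfile <- function(markers, x, weightByAbundance = TRUE) {
  info <- sampleInfo(x)
  guild <- guildAssignments(x)
  guild[is.na(guild)] <- "Unclassified"
  m <- otuCounts(x)
  groups <- sort(unique(info$group_id))
  profs <- list()
  share <- stats::setNames(numeric(length(groups)), groups)
  for (g in groups) {
    ids <- markers$otu_id[markers$group_id == g]
    cols <- info$group_id == g
    if (!length(ids)) {
      message("group '", g, "' has no marker OTUs; empty profile")
      share[g] <- 0
      next
    }
    w <- if (weightByAbundance) {
      rowMeans(m[ids, cols, drop = FALSE] /
        rep(colSums(m[, cols, drop = FALSE]), each = length(ids)))
    } else {
      stats::setNames(rep(1, length(ids)), ids)
    }
    tot <- tapply(w, guild[ids], sum)
    profs[[g]] <- data.frame(
      group_id = g,
      trophic_mode = names(tot),
      proportion = as.numeric(tot) / sum(tot),
      stringsAsFactors = FALSE
    )
    share[g] <- sum(m[ids, cols, drop = FALSE]) / sum(m[, cols, drop = FALSE])
  }
  list(
    profile = if (length(profs)) {
      do.call(rbind, c(profs, list(make.row.names = FALSE)))
    } else {
      data.frame(
        group_id = character(0), trophic_mode = character(0),
        proportion = numeric(0)
      )
    },
    marker_share = share
  )
}

#' Ordination of marker-OTU functional composition
#'
#' Collapses each sample's marker-OTU abundances to a trophic-guild
#' profile (relative abundance of each trophic mode summed over all
#' marker OTUs), then reuses the beta-diversity machinery: Bray-Curtis
#' distances between the guild profiles, PCoA, and pairwise PERMANOVA
#' among the functional groups. Samples containing no marker sequences at
#' all are dropped with a message (a Bray-Curtis distance is undefined
#' for an empty profile).
#'
#' @param markers marker records from [filterMarkers()].
#' @param x the source [EndophyteExperiment-class].
#' @param n_perm,seed passed to [pairwisePermanova()].
#' @return list: `guild_profiles` (samples x trophic modes matrix),
#'   `distance`, `pcoa` ([pcoa()] result), `permanova`
#'   ([pairwisePermanova()] table).
#' @export
markerFunctionOrdination <- function(markers, x, n_perm = 999, seed = NULL) {
  if (!nrow(markers)) stop("no marker OTUs supplied")
  info <- sampleInfo(x)
  guild <- guildAssignments(x)
  guild[is.na(guild)] <- "Unclassified"
  p <- otuCounts(asProportions(x))
  ids <- unique(markers$otu_id)
  sub <- p[ids, , drop = FALSE]
  modes <- sort(unique(guild[ids]))
  prof <- t(rowsum(sub, group = guild[ids])) # samples x modes
  prof <- prof[, modes, drop = FALSE]
  empty <- rowSums(prof) == 0
  if (any(empty)) {
    message(
      sum(empty), " sample(s) without marker sequences dropped: ",
      paste(rownames(prof)[empty], collapse = ", ")
    )
    prof <- prof[!empty, , drop = FALSE]
  }
  d <- brayCurtis(prof, normalize = TRUE)
  labs <- stats::setNames(info$group_id, info$sample_id)[rownames(prof)]
  list(
    guild_profiles = prof,
    distance = d,
    pcoa = pcoa(d),
    permanova = pairwisePermanova(d, labs, n_perm = n_perm, seed = seed)
  )
}
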