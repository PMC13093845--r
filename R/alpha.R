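#' Shannon diversity of one community
#'
#' Shannon entropy \eqn{-\sum_i p_i \ln p_i} over the positive relative
#' abundances of a single community vector, in nats (natural log, the
#' vegan convention). Invariant to rescaling of the abundances.
#'
#' @param x non-negative numeric vector with at least one positive entry.
#' @return Shannon diversity in nats.
#' @examples
#' shannonIndex(c(1, 1, 1, 1)) # log(4)
#' @export
shannonIndex <- function(x) {
  if (any(x < 0) || anyNA(x)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s == 0) stop("all-zero abundance vector")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' OTU richness of one community
#'
#' @param x non-negative numeric vector.
#' @return number of entries greater than zero.
#' @export
otuRichness <- function(x) {
  if (any(x < 0) || anyNA(x)) stop("abundances must be non-negative")
  sum(x > 0)
}

#' Alpha diversity result
#'
#' @slot samples data.frame of per-sample richness and Shannon diversity.
#' @slot species data.frame of per-species means over replicate samples.
#' @slot groups data.frame of per-group means and standard errors (over
#'   species) with significance letters.
#' @slot tests list with one entry per response (`richness`,
#'   `diversity`): overall one-way ANOVA p-value, the Tukey HSD pairwise
#'   table, the significance letters, and the groups excluded for having
#'   fewer than two species.
#' @exportClass AlphaDiversity
setClass("AlphaDiversity",
  slots = c(
    samples = "data.frame", species = "data.frame",
    groups = "data.frame", tests = "list"
  )
)

setMethod("show", "AlphaDiversity", function(object) {
  cat(
    "AlphaDiversity:", nrow(object@samples), "samples,",
    nrow(object@species), "species,", nrow(object@groups), "groups\n"
  )
  print(object@groups, row.names = FALSE)
  invisible(NULL)
})

#' Alpha diversity by sample, species and functional group
#'
#' Computes per-sample OTU richness and Shannon diversity, averages them
#' over replicate samples to species level, and summarizes and tests
#' group differences: per-group mean and standard error over species,
#' one-way ANOVA across groups, Tukey HSD pairwise comparisons, and
#' compact significance letters at `alpha`. Groups with fewer than two
#' species are excluded from the tests (with a message) but still
#' summarized.
#'
#' @param x an [EndophyteExperiment-class] with at least two groups.
#' @param alpha significance level for the letter display (default 0.05).
#' @return an [AlphaDiversity-class] object.
#' @export
alphaDiversity <- function(x, alpha = 0.05) {
  info <- sampleInfo(x)
  if (length(unique(info$group_id)) < 2) stop("need >= 2 functional groups")
  m <- otuCounts(x)
  samples <- data.frame(
    info,
    richness = apply(m, 2, otuRichness),
    diversity = apply(m, 2, shannonIndex),
    stringsAsFactors = FALSE
  )
  species <- stats::aggregate(
    cbind(richness, diversity) ~ species_id + group_id,
    data = samples, FUN = mean
  )
  tests <- list()
  grows <- list()
  for (resp in c("richness", "diversity")) {
    tests[[resp]] <- .groupTest(species, resp, alpha)
  }
  agg <- function(f) {
    stats::aggregate(cbind(richness, diversity) ~ group_id,
      data = species, FUN = f
    )
  }
  mu <- agg(mean)
  se <- agg(function(v) stats::sd(v) / sqrt(length(v)))
  n <- agg(length)
  groups <- data.frame(
    group_id = mu$group_id,
    n_species = n$richness,
    richness_mean = mu$richness,
    richness_se = se$richness,
    richness_letters = tests$richness$letters[mu$group_id],
    diversity_mean = mu$diversity,
    diversity_se = se$diversity,
    diversity_letters = tests$diversity$letters[mu$group_id],
    stringsAsFactors = FALSE
  )
  new("AlphaDiversity",
    samples = samples, species = species,
    groups = groups, tests = tests
  )
}

.groupTest <- function(species, resp, alpha) {
  cnt <- table(species$group_id)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    message(
      "group(s) with < 2 species excluded from ", resp, " tests: ",
      paste(small, collapse = ", ")
    )
  }
  dat <- species[!(species$group_id %in% small), ]
  letters_all <- stats::setNames(
    rep(NA_character_, length(cnt)), names(cnt)
  )
  if (length(unique(dat$group_id)) < 2) {
    return(list(
      anova_p = NA_real_, tukey = NULL,
      letters = letters_all, excluded = small
    ))
  }
  dat$group_id <- factor(dat$group_id)
  fit <- stats::aov(stats::reformulate("group_id", resp), data = dat)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group_id
  g <- levels(dat$group_id)
  diff <- matrix(FALSE, length(g), length(g), dimnames = list(g, g))
  for (r in rownames(tk)) {
    pr <- strsplit(r, "-", fixed = TRUE)[[1]]
    sig <- tk[r, "p adj"] < alpha
    diff[pr[1], pr[2]] <- diff[pr[2], pr[1]] <- sig
  }
  letters_all[g] <- .compactLetters(diff)
  list(
    anova_p = p, tukey = as.data.frame(tk),
    letters = letters_all, excluded = small
  )
}

# compact letter display (insert-and-absorb) from a logical matrix of
# significant pairwise differences; adequate for the handful of groups
# this design carries
.compactLetters <- function(diff) {
  g <- rownames(diff)
  cols <- list(g)
  for (i in seq_along(g)) {
    for (j in seq_len(i - 1L)) {
      if (!diff[i, j]) next
      nxt <- list()
      for (col in cols) {
        if (all(c(g[i], g[j]) %in% col)) {
          nxt <- c(nxt, list(setdiff(col, g[i])), list(setdiff(col, g[j])))
        } else {
          nxt <- c(nxt, list(col))
        }
      }
      nxt <- unique(nxt)
      keep <- rep(TRUE, length(nxt))
      for (a in seq_along(nxt)) {
        for (b in seq_along(nxt)) {
          if (a != b && keep[b] &&
            all(nxt[[a]] %in% nxt[[b]]) &&
            length(nxt[[a]]) < length(nxt[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- nxt[keep]
    }
  }
  ord <- order(vapply(cols, function(col) min(match(col, g)), 1))
  cols <- cols[ord]
  out <- vapply(g, function(gr) {
    paste0(letters[which(vapply(cols, function(col) gr %in% col, TRUE))],
      collapse = ""
    )
  }, character(1))
  out
}

#' Univariate trait models for alpha diversity
#'
#' Fits one Gaussian linear model per trait predictor and response, at
#' species level: `richness ~ trait` and `diversity ~ trait` for each of
#' plot abundance, leaf nitrogen, C:N ratio, water content and LMA. The
#' models are deliberately univariate (the trait predictors are
#' collinear across functional groups); predictors with zero variance are
#' skipped with a message.
#'
#' @param alpha an [AlphaDiversity-class] from [alphaDiversity()].
#' @param traits species trait table (see [readSpeciesTraits()]); every
#'   species in `alpha` must have a trait row.
#' @return data.frame with columns `response`, `predictor`, `estimate`
#'   (slope), `p`, `n`.
#' @export
alphaFactorModels <- function(alpha, traits) {
  stopifnot(is(alpha, "AlphaDiversity"))
  traits <- validateTraits(traits)
  sp <- alpha@species
  miss <- setdiff(sp$species_id, traits$species_id)
  if (length(miss)) {
    stop(
      "species without trait records: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  dat <- merge(sp, traits, by = "species_id")
  preds <- c("abundance", "n_conc", "cn_ratio", "water_content", "lma")
  out <- list()
  for (resp in c("richness", "diversity")) {
    for (px in preds) {
      if (stats::sd(dat[[px]]) == 0) {
        message("predictor '", px, "' has zero variance; model skipped")
        next
      }
      fit <- stats::lm(stats::reformulate(px, resp), data = dat)
      cf <- summary(fit)$coefficients
      out[[length(out) + 1L]] <- data.frame(
        response = resp, predictor = px,
        estimate = cf[2, "Estimate"], p = cf[2, "Pr(>|t|)"],
        n = nrow(dat), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
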