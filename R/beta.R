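#' Bray-Curtis dissimilarity matrix
#'
#' Computes the Bray-Curtis dissimilarity
#' \eqn{d_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})}
#' between all pairs of communities. For an
#' [EndophyteExperiment-class], `level = "sample"` compares samples and
#' `level = "species"` first aggregates replicate samples to one profile
#' per host species via [speciesProfiles()].
#'
#' @param x an [EndophyteExperiment-class], or a plain non-negative
#'   numeric matrix with entities as rows and taxa as columns.
#' @param level `"sample"` or `"species"` (ignored for matrix input).
#' @param normalize convert each entity's abundances to proportions
#'   before computing distances (default `TRUE`; species-level profiles
#'   are proportions by construction). Set `FALSE` to use raw values, in
#'   which case library size contributes to the dissimilarity.
#' @return symmetric matrix with zero diagonal and entries in \[0, 1\],
#'   dimnames = entity ids. An entity with all-zero abundances is a hard
#'   error naming it.
#' @export
brayCurtis <- function(x, level = c("sample", "species"), normalize = TRUE) {
  level <- match.arg(level)
  if (is(x, "EndophyteExperiment")) {
    M <- switch(level,
      sample = t(otuCounts(x)),
      species = speciesProfiles(x)
    )
  } else {
    M <- as.matrix(x)
  }
  if (any(M < 0)) stop("abundances must be non-negative")
  rs <- rowSums(M)
  if (any(rs == 0)) {
    stop("entity with all-zero abundances: ",
      paste(rownames(M)[rs == 0], collapse = ", "),
      call. = FALSE
    )
  }
  if (normalize) {
    M <- M / rs
    rs <- rowSums(M)
  }
  num <- as.matrix(stats::dist(M, method = "manhattan"))
  den <- outer(rs, rs, "+")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(M), rownames(M))
  d
}

# internal: distance-matrix sanity used by pcoa/permanova
.checkDistanceMatrix <- function(d, tol = 1e-12) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > tol) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > tol)) stop("distance matrix diagonal must be 0")
  if (any(d < -tol)) stop("distances must be non-negative")
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the double-centered
#' matrix \eqn{-\frac{1}{2} J D^2 J}. Coordinates are eigenvectors scaled
#' by the square root of their (positive) eigenvalues; negative
#' eigenvalues are retained in the report but excluded from coordinates
#' (no Cailliez/Lingoes correction is applied by default).
#'
#' @param d symmetric distance matrix with zero diagonal (ids as
#'   dimnames).
#' @param n_axes number of coordinate axes to return; defaults to all
#'   axes with positive eigenvalues and is truncated (with a warning) when
#'   it exceeds that count.
#' @return list of class `pcoa_result`: `coordinates` (entities x axes),
#'   `eigenvalues` (all, descending), `prop_explained` (per returned
#'   axis, relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- .checkDistanceMatrix(d)
  n <- nrow(d)
  D2 <- d^2
  rm <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(D2))
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (is.null(n_axes)) {
    n_axes <- length(pos)
  } else if (n_axes > length(pos)) {
    warning(
      "requested ", n_axes, " axes but only ", length(pos),
      " positive eigenvalues; truncating"
    )
    n_axes <- length(pos)
  }
  keep <- pos[seq_len(n_axes)]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), n_axes)
  dimnames(coords) <- list(rownames(d), paste0("Axis", seq_len(n_axes)))
  out <- list(
    coordinates = coords,
    eigenvalues = e$values,
    prop_explained = e$values[keep] / sum(e$values[pos])
  )
  class(out) <- "pcoa_result"
  out
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(
    "PCoA:", nrow(x$coordinates), "entities,", ncol(x$coordinates),
    "axes;  first axes explain",
    paste(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 3)),
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}

# Anderson's pseudo-F from a squared-distance matrix and a grouping factor
.pseudoF <- function(d2, f) {
  n <- nrow(d2)
  g <- nlevels(f)
  ss_tot <- sum(d2) / (2 * n)
  ss_w <- 0
  for (lev in levels(f)) {
    idx <- which(f == lev)
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_b <- ss_tot - ss_w
  c(
    F = (ss_b / (g - 1)) / (ss_w / (n - g)),
    R2 = ss_b / ss_tot
  )
}

# all distinct assignments of labels (a factor) to positions; used by
# permanova(exact = TRUE)
.enumerateLabelings <- function(f, limit = 2e5) {
  counts <- table(f)
  total <- exp(lgamma(length(f) + 1) - sum(lgamma(counts + 1)))
  if (total > limit) {
    stop(
      "exact enumeration needs ", round(total),
      " labelings; use random permutations instead"
    )
  }
  levs <- names(counts)
  rec <- function(idx, k) {
    if (k == length(levs)) {
      return(list(stats::setNames(list(idx), levs[k])))
    }
    out <- list()
    for (s in utils::combn(idx, counts[[k]], simplify = FALSE)) {
      for (r in rec(setdiff(idx, s), k + 1L)) {
        out[[length(out) + 1L]] <- c(stats::setNames(list(s), levs[k]), r)
      }
    }
    out
  }
  lapply(rec(seq_along(f), 1L), function(asg) {
    v <- character(length(f))
    for (lev in levs) v[asg[[lev]]] <- lev
    factor(v, levels = levels(f))
  })
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' PERMANOVA on a distance matrix: the pseudo-F statistic is computed
#' from Anderson's sums-of-squares partition
#' (\eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n}, within-group sums from
#' within-group pairs, \eqn{F = (SS_b/(g-1)) / (SS_w/(n-g))}) and its
#' significance by permuting group labels:
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}.
#' With `exact = TRUE` all distinct labelings are enumerated instead and
#' `p` is the exact proportion of labelings (including the observed one)
#' with \eqn{F \ge F_{obs}}.
#'
#' @param d symmetric distance matrix (ids as dimnames).
#' @param labels group label per entity, in row order of `d` (or named by
#'   entity id). At least two groups, each with at least two entities.
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutations; required for
#'   reproducibility.
#' @param exact enumerate all distinct labelings instead of sampling.
#' @return list of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `n_perm` (or number of enumerated labelings), `seed`, `exact`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL, exact = FALSE) {
  d <- .checkDistanceMatrix(d)
  n <- nrow(d)
  if (!is.null(names(labels)) && !is.null(rownames(d))) {
    labels <- labels[rownames(d)]
  }
  if (length(labels) != n) stop("one label per entity required")
  f <- droplevels(factor(labels))
  if (nlevels(f) < 2) stop("need >= 2 groups")
  if (any(table(f) < 2)) {
    stop(
      "group(s) of size 1: ",
      paste(names(which(table(f) < 2)), collapse = ", "),
      call. = FALSE
    )
  }
  d2 <- d^2
  obs <- .pseudoF(d2, f)
  tol <- 1e-12
  if (exact) {
    labelings <- .enumerateLabelings(f)
    Fs <- vapply(labelings, function(ff) .pseudoF(d2, ff)[["F"]], 1)
    p <- mean(Fs >= obs[["F"]] - tol)
    n_used <- length(labelings)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      fp <- f[sample.int(n)]
      if (.pseudoF(d2, fp)[["F"]] >= obs[["F"]] - tol) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  out <- list(
    pseudo_F = obs[["F"]], R2 = obs[["R2"]], p = p,
    n_perm = n_used, seed = seed, exact = exact
  )
  class(out) <- "permanova_result"
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%s, %d %s)\n",
    x$pseudo_F, x$R2, x$p,
    if (x$exact) "exact" else "permutation",
    x$n_perm, if (x$exact) "labelings" else "permutations"
  ))
  invisible(x)
}

#' Pairwise PERMANOVA between all group pairs
#'
#' Runs [permanova()] on the sub-matrix of every unordered pair of
#' groups. Raw p-values are reported together with Holm-adjusted values;
#' each pair uses a seed derived deterministically from `seed`.
#'
#' @inheritParams permanova
#' @return data.frame with columns `group_a`, `group_b`, `n`, `pseudo_F`,
#'   `R2`, `p`, `p_adj` (Holm), `n_perm`.
#' @export
pairwisePermanova <- function(d, labels, n_perm = 999, seed = NULL) {
  d <- .checkDistanceMatrix(d)
  if (!is.null(names(labels)) && !is.null(rownames(d))) {
    labels <- labels[rownames(d)]
  }
  f <- droplevels(factor(labels))
  if (nlevels(f) < 2) stop("need >= 2 groups")
  levs <- levels(f)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    idx <- which(f %in% pr)
    sub_seed <- if (is.null(seed)) NULL else (as.integer(seed) + k) %% 2147483647L
    res <- permanova(d[idx, idx, drop = FALSE], f[idx],
      n_perm = n_perm, seed = sub_seed
    )
    data.frame(
      group_a = pr[1], group_b = pr[2], n = length(idx),
      pseudo_F = res$pseudo_F, R2 = res$R2, p = res$p,
      n_perm = n_perm, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out[, c(
    "group_a", "group_b", "n", "pseudo_F", "R2", "p", "p_adj",
    "n_perm"
  )]
}
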