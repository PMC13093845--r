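#' @name distance-lmm
#' @title Distance linear mixed model with multi-membership species effects
#'
#' @description
#' The cross-group pair design regresses the Bray-Curtis dissimilarity of
#' two species' endophyte communities on six pairwise distance
#' predictors. Each row involves two species, so "species identity as a
#' random factor" is a multi-membership random effect: one latent
#' intercept per species, entering every row that species is a member
#' of, with a single shared variance. Writing the membership matrix
#' \eqn{M} (rows = pairs, columns = species, two 1s per row), the model is
#' \deqn{y = X\beta + M u + e,\quad u \sim N(0, \sigma_u^2 I),\quad
#'   e \sim N(0, \sigma_e^2 I).}
#' The marginal covariance \eqn{V = \sigma_e^2 I + \sigma_u^2 M M^\top}
#' is handled exactly through the Woodbury identity and a one-off
#' eigendecomposition of \eqn{M^\top M}, so restricted maximum likelihood
#' reduces to a one-dimensional profile optimization over
#' \eqn{\lambda = \sigma_u^2 / \sigma_e^2}. Per-coefficient F statistics
#' are squared t statistics with a Satterthwaite-style denominator df
#' (delta method on the REML information); the same machinery refits
#' every predictor subset for hierarchical partitioning of the marginal
#' R-squared.
NULL

# ---- internal linear algebra -------------------------------------------

# one-off quantities shared by all subset fits on a design
.dlmmPrep <- function(design, predictors = .PAIR_PREDICTORS) {
  stopifnot(all(predictors %in% colnames(design)))
  y <- design$response
  n <- length(y)
  X <- cbind("(Intercept)" = 1, as.matrix(design[predictors]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed design; aliased: ",
      paste(aliased, collapse = ", "),
      call. = FALSE
    )
  }
  species <- sort(unique(c(design$species_a, design$species_b)))
  M <- matrix(0, n, length(species), dimnames = list(NULL, species))
  M[cbind(seq_len(n), match(design$species_a, species))] <- 1
  M[cbind(seq_len(n), match(design$species_b, species))] <- 1
  C <- crossprod(M)
  eC <- eigen(C, symmetric = TRUE)
  UA <- crossprod(eC$vectors, crossprod(M, X)) # S x (p+1)
  Ua <- drop(crossprod(eC$vectors, crossprod(M, y))) # S
  list(
    y = y, X = X, M = M, n = n, species = species,
    dC = eC$values, UA = UA, Ua = Ua,
    XtX = crossprod(X), Xty = drop(crossprod(X, y)),
    yty = sum(y^2),
    z2 = mean(rowSums(M^2)) # random variance multiplier per row (= 2)
  )
}

# GLS pieces at a given lambda for a column subset (always incl. intercept)
.dlmmEval <- function(prep, cols, lambda) {
  UA <- prep$UA[, cols, drop = FALSE]
  # diag of (1/lambda I + C)^-1 in the eigenbasis of C = M'M:
  # 1/(1/lambda + d) = lambda / (1 + lambda d), safe at lambda = 0 or d = 0
  w <- lambda / (1 + lambda * prep$dC)
  XtVX <- prep$XtX[cols, cols, drop = FALSE] - crossprod(UA, w * UA)
  XtVy <- prep$Xty[cols] - drop(crossprod(UA, w * prep$Ua))
  yVy <- prep$yty - sum(w * prep$Ua^2)
  beta <- solve(XtVX, XtVy)
  rss <- yVy - sum(beta * XtVy)
  list(
    beta = beta, XtVX = XtVX, rss = rss,
    logdetV0 = sum(log1p(lambda * prep$dC)),
    logdetXtVX = as.numeric(determinant(XtVX)$modulus)
  )
}

# profiled REML criterion in log-lambda
.dlmmCrit <- function(prep, cols, loglambda) {
  ev <- .dlmmEval(prep, cols, exp(loglambda))
  (prep$n - length(cols)) * log(ev$rss) + ev$logdetV0 + ev$logdetXtVX
}

# REML fit for a column subset; returns variance components, beta, vcov
.dlmmFit <- function(prep, cols) {
  opt <- stats::optimize(function(ll) .dlmmCrit(prep, cols, ll),
    interval = c(-16, 16), tol = 1e-9
  )
  if (!is.finite(opt$objective)) {
    stop("REML optimization failed (non-finite criterion)")
  }
  lambda <- exp(opt$minimum)
  # boundary check: sigma_u^2 = 0
  crit0 <- .dlmmCrit(prep, cols, -Inf)
  if (is.finite(crit0) && crit0 <= opt$objective + 1e-8) lambda <- 0
  ev <- .dlmmEval(prep, cols, lambda)
  p <- length(cols)
  sige2 <- ev$rss / (prep$n - p)
  sigu2 <- lambda * sige2
  fitted_fixed <- drop(prep$X[, cols, drop = FALSE] %*% ev$beta)
  var_fixed <- stats::var(fitted_fixed)
  denom <- var_fixed + prep$z2 * sigu2 + sige2
  list(
    lambda = lambda, sige2 = sige2, sigu2 = sigu2,
    beta = ev$beta, vcov = sige2 * solve(ev$XtVX),
    var_fixed = var_fixed,
    r2_marginal = var_fixed / denom,
    r2_conditional = (var_fixed + prep$z2 * sigu2) / denom,
    cols = cols
  )
}

# full (non-profiled) REML criterion in (sigu2, sige2); for the
# Satterthwaite information matrix
.dlmmCrit2 <- function(prep, cols, sigu2, sige2) {
  if (sige2 <= 0 || sigu2 < 0) {
    return(Inf)
  }
  ev <- .dlmmEval(prep, cols, sigu2 / sige2)
  (prep$n - length(cols)) * log(sige2) + ev$logdetV0 + ev$logdetXtVX +
    ev$rss / sige2
}

# Satterthwaite-style denominator df for each coefficient
.dlmmSatterthwaite <- function(prep, fit) {
  cols <- fit$cols
  p <- length(cols)
  resid_df <- prep$n - p
  if (fit$sigu2 <= 1e-10) {
    return(rep(resid_df, p))
  }
  theta <- c(fit$sigu2, fit$sige2)
  h <- pmax(abs(theta) * 1e-4, 1e-10)
  cr <- function(th) .dlmmCrit2(prep, cols, th[1], th[2])
  H <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) {
      ei <- ej <- c(0, 0)
      ei[i] <- h[i]
      ej[j] <- h[j]
      H[i, j] <- (cr(theta + ei + ej) - cr(theta + ei - ej) -
        cr(theta - ei + ej) + cr(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  Vtheta <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(Vtheta) || any(!is.finite(Vtheta)) || any(diag(Vtheta) < 0)) {
    return(rep(resid_df, p))
  }
  fvar <- function(th) {
    ev <- .dlmmEval(prep, cols, th[1] / th[2])
    th[2] * diag(solve(ev$XtVX))
  }
  g1 <- (fvar(theta + c(h[1], 0)) - fvar(theta - c(h[1], 0))) / (2 * h[1])
  g2 <- (fvar(theta + c(0, h[2])) - fvar(theta - c(0, h[2]))) / (2 * h[2])
  f0 <- fvar(theta)
  df <- vapply(seq_len(p), function(k) {
    g <- c(g1[k], g2[k])
    den <- drop(t(g) %*% Vtheta %*% g)
    if (den <= 0) {
      return(resid_df)
    }
    2 * f0[k]^2 / den
  }, 1)
  pmin(pmax(df, 1), resid_df)
}

# ---- exported fitting interface ----------------------------------------

#' Fit the distance linear mixed model
#'
#' Fits the multi-membership mixed model described in
#' [distance-lmm] on a cross-group pair design by restricted
#' maximum likelihood. Per predictor it reports the coefficient, its
#' standard error, an F statistic (squared t, 1 numerator df) and a
#' p-value on a Satterthwaite-style denominator df; at the model level it
#' reports the species and residual variance components and the marginal
#' and conditional R-squared (fixed-effect variance over total variance,
#' with the multi-membership random term contributing
#' \eqn{2\sigma_u^2} per row).
#'
#' @param design a `pair_design` from [buildPairDesign()] (at least 20
#'   rows).
#' @param predictors predictor columns to include (default all six).
#' @param ddf denominator-df method: `"satterthwaite"` (default) or
#'   `"residual"` (n - p).
#' @return list of class `distance_lmm`: `coefficients` (data.frame with
#'   `predictor`, `estimate`, `se`, `F`, `df`, `p`), `varcomp`
#'   (`sigma2_species`, `sigma2_residual`), `r2_marginal`,
#'   `r2_conditional`, `lambda`, `n`.
#' @export
fitDistanceLmm <- function(design, predictors = .PAIR_PREDICTORS,
                           ddf = c("satterthwaite", "residual")) {
  ddf <- match.arg(ddf)
  if (nrow(design) < 20) stop("need >= 20 pair rows")
  prep <- .dlmmPrep(design, predictors)
  cols <- seq_len(ncol(prep$X))
  fit <- .dlmmFit(prep, cols)
  df <- if (ddf == "satterthwaite") {
    .dlmmSatterthwaite(prep, fit)
  } else {
    rep(prep$n - length(cols), length(cols))
  }
  se <- sqrt(diag(fit$vcov))
  tval <- fit$beta / se
  keep <- -1 # drop intercept row from the report
  coefs <- data.frame(
    predictor = colnames(prep$X)[-1],
    estimate = fit$beta[keep],
    se = se[keep],
    F = tval[keep]^2,
    df = df[keep],
    p = 2 * stats::pt(-abs(tval[keep]), df[keep]),
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  out <- list(
    coefficients = coefs,
    varcomp = c(
      sigma2_species = fit$sigu2,
      sigma2_residual = fit$sige2
    ),
    r2_marginal = fit$r2_marginal,
    r2_conditional = fit$r2_conditional,
    lambda = fit$lambda,
    n = prep$n
  )
  class(out) <- "distance_lmm"
  out
}

#' @export
print.distance_lmm <- function(x, ...) {
  cat(sprintf(
    "Distance LMM (n = %d): marginal R2 = %.4f, conditional R2 = %.4f\n",
    x$n, x$r2_marginal, x$r2_conditional
  ))
  cat(sprintf(
    "  variance components: species %.3g, residual %.3g\n",
    x$varcomp[["sigma2_species"]], x$varcomp[["sigma2_residual"]]
  ))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Hierarchical partitioning of the marginal R-squared
#'
#' Refits the distance mixed model on every subset of the predictors
#' (keeping the multi-membership random structure) and attributes to each
#' predictor its individual importance: the average, over hierarchy
#' levels, of the mean increase in marginal R-squared when the predictor
#' joins each subset not containing it (Chevan-Sutherland averaging).
#' The individual contributions sum exactly to the full model's marginal
#' R-squared; negative averages (possible with correlated predictors)
#' are clipped to zero in the `individual_r2` column with the raw value
#' kept alongside.
#'
#' @param design a `pair_design` from [buildPairDesign()].
#' @param predictors predictor columns to partition (at most 12).
#' @return data.frame with columns `predictor`, `individual_r2`
#'   (clipped at 0), `individual_r2_raw`; attributes `r2_full` (full
#'   marginal R-squared) and `failed_subsets` (count of subset fits that
#'   failed and were excluded).
#' @export
hierarchicalPartition <- function(design, predictors = .PAIR_PREDICTORS) {
  k <- length(predictors)
  if (k > 12) stop("at most 12 predictors (2^k subset fits)")
  prep <- .dlmmPrep(design, predictors)
  nmask <- bitwShiftL(1L, k)
  r2 <- rep(NA_real_, nmask)
  failed <- 0L
  for (mask in seq_len(nmask) - 1L) {
    cols <- c(1L, 1L + which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0))
    r2[mask + 1L] <- tryCatch(
      .dlmmFit(prep, cols)$r2_marginal,
      error = function(e) {
        failed <<- failed + 1L
        NA_real_
      }
    )
  }
  if (failed) message(failed, " subset fit(s) failed and were excluded")
  size <- vapply(seq_len(nmask) - 1L, function(m) {
    sum(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0)
  }, 1L)
  indep <- vapply(seq_len(k), function(j) {
    bit <- bitwShiftL(1L, j - 1L)
    inc_by_level <- vapply(0:(k - 1L), function(h) {
      ms <- which(size == h & bitwAnd(seq_len(nmask) - 1L, bit) == 0L)
      inc <- r2[ms - 1L + bit + 1L] - r2[ms]
      mean(inc, na.rm = TRUE)
    }, 1)
    mean(inc_by_level, na.rm = TRUE)
  }, 1)
  out <- data.frame(
    predictor = predictors,
    individual_r2 = pmax(indep, 0),
    individual_r2_raw = indep,
    stringsAsFactors = FALSE
  )
  if (any(indep < 0)) {
    message(
      sum(indep < 0),
      " negative individual contribution(s) clipped to 0"
    )
  }
  attr(out, "r2_full") <- r2[nmask]
  attr(out, "failed_subsets") <- failed
  out
}
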