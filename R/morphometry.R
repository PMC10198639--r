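## Cross-species sulcal morphometry: normalized anteroposterior distances,
## landmark assignment, occurrence frequencies, and the species-effect
## mixed logistic test with post hoc pairwise contrasts.

#' Normalized anteroposterior distance
#'
#' \code{(yFeature - yLandmark) / apExtent}: the Y difference between a
#' sulcal characteristic and a landmark, divided by the species'
#' anteroposterior brain extent so distances are comparable across species.
#' Missing feature Y (absent sulcus) propagates as NA.
#'
#' @param yFeature,yLandmark Y coordinates in mm (vectorized).
#' @param apExtent anteroposterior extent in mm (> 0).
#' @return dimensionless distance(s).
#' @export
normalizedDistance <- function(yFeature, yLandmark, apExtent) {
  if (any(apExtent <= 0)) stop("apExtent must be > 0")
  (yFeature - yLandmark) / apExtent
}

## Lower median: for even counts, the lower of the two central order
## statistics (deterministic).
.lowerMedian <- function(x) {
  x <- sort(x[!is.na(x)])
  if (!length(x)) return(NA_real_)
  x[ceiling(length(x) / 2)]
}

#' Assign the landmark nearest a sulcal characteristic
#'
#' For each candidate landmark, computes the lower median across records of
#' the normalized distance between the feature's Y and that landmark's
#' per-species Y level; the landmark whose |median| is closest to 0 is
#' assigned. Records are pooled across hemispheres (and across the species
#' present in \code{records}).
#'
#' @param records data.frame with columns \code{species} and the Y column
#'   named by \code{yColumn}; absent records (NA) are ignored.
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param candidates character vector of candidate landmark names; default
#'   all landmarks available for the species involved.
#' @param yColumn name of the Y column, default \code{"caudal_y"}.
#' @return list: \code{landmark} (assigned name), \code{tie} (logical; an
#'   exact |median| tie, reported with the most caudal landmark),
#'   \code{medians} data.frame(landmark, median, n).
#' @export
assignLandmark <- function(records, landmarks,
                           candidates = NULL, yColumn = "caudal_y") {
  y <- records[[yColumn]]
  ok <- !is.na(y)
  if (!any(ok)) stop("all records are missing the feature Y coordinate")
  records <- records[ok, , drop = FALSE]
  y <- y[ok]
  tb <- landmarkTable(landmarks)
  if (is.null(candidates))
    candidates <- unique(tb$landmark[tb$species %in% records$species])
  if (!length(candidates)) stop("no candidate landmarks")
  ext <- apExtent(landmarks)
  med <- n <- numeric(length(candidates))
  caudality <- numeric(length(candidates))  # mean normalized landmark Y
  for (ci in seq_along(candidates)) {
    lmY <- vapply(records$species, function(sp)
      landmarkY(landmarks, sp, candidates[ci]), numeric(1))
    d <- normalizedDistance(y, lmY, ext[records$species])
    med[ci] <- .lowerMedian(d)
    n[ci] <- sum(!is.na(d))
    caudality[ci] <- mean(lmY / ext[records$species])
  }
  best <- abs(med) == min(abs(med))
  tie <- sum(best) > 1L
  pick <- which(best)[order(caudality[best])][1]  # tie: most caudal
  list(landmark = candidates[pick], tie = tie,
       medians = data.frame(landmark = candidates, median = med, n = n))
}

#' Occurrence frequency of sulcal features
#'
#' Sample proportion of present records per (species, feature) cell,
#' reported as a percentage with the underlying counts. Cells with no
#' records are absent from the table (missing, not 0).
#'
#' @param records data.frame with columns \code{species}, \code{feature},
#'   \code{present}.
#' @return data.frame(species, feature, nPresent, n, percent).
#' @export
occurrenceFrequency <- function(records) {
  if (!nrow(records))
    return(data.frame(species = character(), feature = character(),
                      nPresent = integer(), n = integer(),
                      percent = numeric()))
  agg <- aggregate(present ~ species + feature, data = records,
                   FUN = function(p) c(sum(p), length(p)))
  out <- data.frame(species = agg$species, feature = agg$feature,
                    nPresent = agg$present[, 1], n = agg$present[, 2])
  out$percent <- 100 * out$nPresent / out$n
  out[order(out$feature, out$species), ]
}

## ---- Firth bias-reduced logistic regression -----------------------------

## Jeffreys-prior penalized logistic regression (Firth). Returns
## coefficients, covariance (inverse penalized information) and the
## penalized log-likelihood; finite estimates exist under complete
## separation, where ordinary ML diverges.
.firthLogit <- function(X, y, maxIter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    infoInv <- solve(info)
    h <- rowSums((X %*% infoInv) * XW)  # hat diagonal
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(infoInv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  info <- crossprod(X, X * (mu * (1 - mu)))
  logLik <- sum(y * log(mu) + (1 - y) * log(1 - mu)) +
    0.5 * determinant(info, logarithm = TRUE)$modulus
  list(coef = beta, vcov = solve(info), penLogLik = as.numeric(logLik))
}

## Shared fitting route for the species test and the post hoc contrasts.
## Returns coef/vcov on the logit scale (treatment coding, first species as
## reference), the species levels, the LRT against the intercept-only
## model, and a method tag.
.fitSpeciesModel <- function(records) {
  records$present <- as.integer(records$present)
  records$species <- factor(records$species)
  records$subject <- factor(records$subject)
  nSpecies <- nlevels(records$species)
  if (nSpecies < 2L) stop("need at least 2 species")
  if (length(unique(records$present)) < 2L)
    stop("both outcomes (present/absent) must be represented")
  cellP <- tapply(records$present, records$species, mean)

  if (any(cellP == 0 | cellP == 1)) {
    ## a species observed at 0% or 100%: the ML species effect diverges
    ## (complete/quasi-complete separation)
    warning("separation detected (a species at 0% or 100% presence); ",
            "using bias-reduced (Firth) logistic regression")
    X <- stats::model.matrix(~ species, records)
    full <- .firthLogit(X, records$present)
    null <- .firthLogit(X[, 1, drop = FALSE], records$present)
    chisq <- 2 * (full$penLogLik - null$penLogLik)
    return(list(coef = full$coef, vcov = full$vcov,
                levels = levels(records$species),
                statistic = chisq, df = nSpecies - 1L,
                p = stats::pchisq(chisq, nSpecies - 1L, lower.tail = FALSE),
                method = "penalized LRT (Firth; separation detected)"))
  }

  fullG <- suppressWarnings(suppressMessages(
    lme4::glmer(present ~ species + (1 | subject), data = records,
                family = stats::binomial())))
  reVar <- as.numeric(lme4::VarCorr(fullG)$subject[1])
  if (reVar > 1e-6) {
    nullG <- suppressWarnings(suppressMessages(
      lme4::glmer(present ~ 1 + (1 | subject), data = records,
                  family = stats::binomial())))
    an <- suppressMessages(stats::anova(nullG, fullG))
    chisq <- an$Chisq[2]
    df <- an$Df[2]
    return(list(coef = lme4::fixef(fullG),
                vcov = as.matrix(stats::vcov(fullG)),
                levels = levels(records$species),
                statistic = chisq, df = as.integer(df),
                p = stats::pchisq(chisq, df, lower.tail = FALSE),
                method = "LRT (binomial GLMM, subject random intercept)"))
  }
  ## random-effect variance estimated at 0: the mixed model degenerates to
  ## ordinary logistic regression
  message("subject random-effect variance estimated at 0; ",
          "falling back to plain logistic regression")
  full <- stats::glm(present ~ species, data = records,
                     family = stats::binomial())
  null <- stats::glm(present ~ 1, data = records,
                     family = stats::binomial())
  chisq <- as.numeric(null$deviance - full$deviance)
  list(coef = stats::coef(full), vcov = stats::vcov(full),
       levels = levels(records$species),
       statistic = chisq, df = nSpecies - 1L,
       p = stats::pchisq(chisq, nSpecies - 1L, lower.tail = FALSE),
       method = "LRT (logistic regression; random-effect variance 0)")
}

#' Species effect on sulcus presence
#'
#' Fits a binomial-logit mixed model \code{presence ~ species + (1 |
#' subject)} and tests the species fixed effect by likelihood ratio against
#' the intercept-only model (numerator df = number of species - 1). When
#' the subject random-effect variance is estimated at 0 the test degenerates
#' to an ordinary logistic-regression LRT (noted); when a species is
#' observed at 0% or 100% presence (separation, where ML diverges) a
#' bias-reduced Firth fit with a penalized LRT is used (warning).
#' Denominator df approximations for binomial mixed models are
#' software-specific and reported as \code{"n/a"}.
#'
#' @param records data.frame for one sulcal feature with columns
#'   \code{species}, \code{subject}, \code{present}.
#' @return a \linkS4class{SpeciesTestResult}.
#' @export
speciesEffectTest <- function(records) {
  fit <- .fitSpeciesModel(records)
  new("SpeciesTestResult", statistic = fit$statistic,
      numDf = as.integer(fit$df), denDf = "n/a", pValue = fit$p,
      method = fit$method)
}

#' Pairwise species contrasts on sulcus presence
#'
#' All pairwise species differences on the logit scale from the same model
#' route as \code{\link{speciesEffectTest}}, with Wald z tests and
#' Holm-adjusted p-values (multiplicity-adjusted p is never below the raw
#' p). Species pairs without data yield missing rows.
#'
#' @inheritParams speciesEffectTest
#' @param species optional character vector fixing the full species set;
#'   pairs involving a species absent from \code{records} are reported as
#'   missing rows.
#' @return data.frame(species1, species2, estimate, se, z, p, pAdjusted).
#' @export
pairwisePosthoc <- function(records, species = NULL) {
  fit <- .fitSpeciesModel(records)
  lev <- fit$levels
  allLev <- if (is.null(species)) lev else species
  pairs <- t(combn(allLev, 2))
  out <- data.frame(species1 = pairs[, 1], species2 = pairs[, 2],
                    estimate = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, pAdjusted = NA_real_)
  ## treatment coding: coef 1 = intercept (reference level), coef j>1 =
  ## logit difference of level j vs reference
  contrastVec <- function(sp) {
    v <- rep(0, length(lev))
    j <- match(sp, lev)
    if (j > 1) v[j] <- 1
    v
  }
  for (r in seq_len(nrow(out))) {
    if (!(out$species1[r] %in% lev) || !(out$species2[r] %in% lev)) next
    cv <- contrastVec(out$species1[r]) - contrastVec(out$species2[r])
    out$estimate[r] <- sum(cv * fit$coef)
    out$se[r] <- sqrt(drop(t(cv) %*% fit$vcov %*% cv))
    out$z[r] <- out$estimate[r] / out$se[r]
    out$p[r] <- 2 * stats::pnorm(-abs(out$z[r]))
  }
  est <- !is.na(out$p)
  out$pAdjusted[est] <- stats::p.adjust(out$p[est], method = "holm")
  attr(out, "method") <- paste0(fit$method, " + Holm-adjusted Wald contrasts")
  out
}
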