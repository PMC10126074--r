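# User-facing IRT interface: Rasch / 2PL fitting, model comparison, ability
# estimation, reliability, information, item fit, empirical ICCs, DIF.

#' Item characteristic curve (Rasch / 2PL)
#'
#' Probability of a correct response given ability `theta`, difficulty `b`
#' and discrimination `a`:
#' \eqn{P = \exp(a(\theta-b)) / (1 + \exp(a(\theta-b)))}. With `a = 1` this
#' is the Rasch model; a person whose ability equals the item difficulty
#' has probability 0.5 of solving the item.
#'
#' @param theta ability (vectorized).
#' @param b item difficulty.
#' @param a item discrimination (default 1 = Rasch).
#' @return probability (or vector of probabilities).
#' @examples
#' raschICC(0, 0)      # 0.5
#' raschICC(1, 0)      # logistic(1)
#' @export
raschICC <- function(theta, b, a = 1) {
  stopifnot(all(is.finite(theta)), all(is.finite(b)), all(is.finite(a)))
  plogis(a * (theta - b))
}

asCorrectness <- function(responses) {
  if (is(responses, "ResponseMatrix")) correctness(responses) else {
    x <- as.matrix(responses)
    storage.mode(x) <- "integer"
    x
  }
}

#' Fit a Rasch model by marginal maximum likelihood
#'
#' EM estimation over a fixed quadrature grid. For identification the
#' common discrimination is fixed at 1 and the latent ability prior is
#' N(0, sigma^2) with sigma estimated, so the free-parameter count is
#' (number of items) + 1. Missing responses (omissions) are excluded from
#' the likelihood cell-wise, never scored incorrect. Items answered all
#' correctly or all incorrectly by the scored respondents are flagged
#' inestimable (with a warning) and excluded from estimation. Estimation is
#' deterministic: no random initialization.
#'
#' @param responses a [ResponseMatrix-class] or persons x items matrix in
#'   {0, 1, NA}.
#' @param nQuad number of quadrature nodes (default 61, equally spaced).
#' @param quadRange quadrature range on the ability scale (default
#'   c(-6, 6)).
#' @param tol EM convergence tolerance on the maximum absolute parameter
#'   change (default 1e-5).
#' @param maxit maximum EM iterations (default 500); non-convergence is
#'   reported in the convergence record, not raised.
#' @param se compute observed-information standard errors (numerical
#'   differentiation of the analytic marginal score); default TRUE.
#' @return an [IRTFit-class].
#' @export
fitRasch <- function(responses, nQuad = 61L, quadRange = c(-6, 6),
                     tol = 1e-5, maxit = 500L, se = TRUE) {
  mmlFit(asCorrectness(responses), model = "rasch",
         quad = makeQuad(nQuad, quadRange), tol = tol, maxit = maxit, se = se)
}

#' Fit a two-parameter logistic (2PL) model by marginal maximum likelihood
#'
#' As [fitRasch()], but with a free discrimination per item; for
#' identification the latent prior is fixed to standard normal. Free
#' parameters: 2 per item. Discriminations are constrained to a positive
#' interval to prevent divergence.
#'
#' @inheritParams fitRasch
#' @param aBounds allowed discrimination interval (default c(0.05, 5)).
#' @return an [IRTFit-class].
#' @export
fit2PL <- function(responses, nQuad = 61L, quadRange = c(-6, 6),
                   tol = 1e-5, maxit = 500L, aBounds = c(0.05, 5), se = TRUE) {
  mmlFit(asCorrectness(responses), model = "2pl",
         quad = makeQuad(nQuad, quadRange), tol = tol, maxit = maxit,
         aBounds = aBounds, se = se)
}

#' Likelihood-ratio test between nested IRT fits
#'
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{nested})} with degrees of freedom
#' equal to the difference in free-parameter counts. With the package's
#' identification conventions, Rasch (J + 1 parameters) is nested in 2PL
#' (2J parameters), giving df = J - 1.
#'
#' @param fitNested,fitFull [IRTFit-class] objects on the same data.
#' @param tolerance slack allowed before a lower full-model likelihood is
#'   treated as an inconsistency error (default 1e-6).
#' @return list with `chisq`, `df`, `p`.
#' @export
lrTest <- function(fitNested, fitFull, tolerance = 1e-6) {
  if (fitNested@nPersons != fitFull@nPersons)
    stop("fits must be on the same data (person counts differ)")
  if (fitNested@npar >= fitFull@npar)
    stop("nested model must have fewer free parameters than the full model")
  delta <- fitFull@loglik - fitNested@loglik
  if (delta < -tolerance)
    stop("full model has lower log-likelihood than the nested model; fits are inconsistent")
  chisq <- max(0, 2 * delta)
  df <- fitFull@npar - fitNested@npar
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
}

#' Expected a posteriori (EAP) ability estimates
#'
#' Posterior mean and SD of the latent ability per person, computed by
#' quadrature against the fit's latent prior. Persons without any scored
#' response get the prior mean and prior SD.
#'
#' @param fit an [IRTFit-class].
#' @param responses the response data (only estimable items are used).
#' @return data.frame with `person`, `theta`, `se` (posterior SD).
#' @export
eapAbilities <- function(fit, responses) {
  X <- asCorrectness(responses)
  it <- fit@items[fit@items$estimable, ]
  use <- intersect(colnames(X), it$item)
  if (!length(use)) stop("no estimable items present in the responses")
  it <- it[match(use, it$item), ]
  X <- X[, use, drop = FALSE]
  quad <- makeQuad(fit@quad$n, fit@quad$range)
  qn <- quadNodes(quad, fit@prior$mean, fit@prior$sd)
  nodes <- qn$nodes; logw <- qn$logw
  Mm <- !is.na(X) + 0
  X0 <- ifelse(is.na(X), 0, X)
  P <- gridProbs(nodes, it$a, it$b)
  es <- eStep(X0, Mm, t(log(P)), t(log1p(-P)), logw)
  m <- as.vector(es$post %*% nodes)
  v <- as.vector(es$post %*% nodes^2) - m^2
  data.frame(person = rownames(X), theta = m, se = sqrt(pmax(v, 0)),
             n_scored = rowSums(Mm), stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical marginal reliability
#'
#' The proportion of true-score variance in total variance, estimated from
#' EAP abilities: the true-score variance is the variance of the ability
#' estimates and the error variance is the mean squared posterior SD, so
#' \eqn{rel = var(\hat\theta) / (var(\hat\theta) + mean(SE^2))}.
#'
#' @param abilities data.frame from [eapAbilities()] (columns `theta`,
#'   `se`).
#' @return reliability coefficient in \[0, 1).
#' @export
empiricalReliability <- function(abilities) {
  if (nrow(abilities) < 2L) stop("need at least 2 persons")
  v <- var(abilities$theta)
  e <- mean(abilities$se^2)
  if (v + e <= 0) stop("total variance is zero; reliability undefined")
  v / (v + e)
}

#' Test information and ability standard-error curves
#'
#' \eqn{I(\theta) = \sum_j a_j^2 P_j(\theta)(1 - P_j(\theta))} over the
#' estimable items, and \eqn{SE(\theta) = 1/\sqrt{I(\theta)}}.
#'
#' @param fit an [IRTFit-class].
#' @param theta ability grid (default `seq(-4, 4, by = 0.1)`).
#' @return data.frame with `theta`, `information`, `se`.
#' @export
testInformation <- function(fit, theta = seq(-4, 4, by = 0.1)) {
  it <- fit@items[fit@items$estimable, ]
  P <- gridProbs(theta, it$a, it$b)
  info <- as.vector((P * (1 - P)) %*% it$a^2)
  data.frame(theta = theta, information = info, se = 1 / sqrt(info))
}

# Quantile-bin persons by EAP ability, merging bins below a minimum count.
abilityBins <- function(theta, nBins, minBin) {
  qs <- quantile(theta, probs = seq(0, 1, length.out = nBins + 1), type = 7)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  bin <- cut(theta, unique(qs), labels = FALSE, include.lowest = TRUE)
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < minBin]
    if (!length(small) || length(tab) == 1L) break
    s <- as.integer(small[1])
    lv <- sort(unique(bin))
    target <- if (s == min(lv)) lv[which(lv == s) + 1L] else lv[which(lv == s) - 1L]
    bin[bin == s] <- target
  }
  match(bin, sort(unique(bin)))
}

#' Per-item fit statistics (infit / outfit and binned chi-square)
#'
#' Residual-based fit measures against EAP abilities. For scored response
#' \eqn{x_{ij}} with model probability \eqn{P_{ij}}: outfit is the mean
#' squared standardized residual, infit the information-weighted mean
#' square. A binned observed-vs-expected chi-square over ability bins is
#' reported alongside. Items with infit or outfit outside `bounds` are
#' flagged.
#'
#' @param fit an [IRTFit-class].
#' @param responses the response data.
#' @param nBins number of ability bins for the chi-square (default 8); bins
#'   with fewer than `minBin` persons are merged with a neighbor.
#' @param minBin minimum persons per bin (default 5).
#' @param bounds flagging interval for infit/outfit (default c(0.7, 1.3)).
#' @return data.frame with `item`, `infit`, `outfit`, `chisq`, `df_chisq`,
#'   `p_chisq`, `flagged`.
#' @export
itemFit <- function(fit, responses, nBins = 8L, minBin = 5L,
                    bounds = c(0.7, 1.3)) {
  X <- asCorrectness(responses)
  ab <- eapAbilities(fit, responses)
  it <- fit@items[fit@items$estimable, ]
  X <- X[, it$item, drop = FALSE]
  P <- gridProbs(ab$theta, it$a, it$b)      # n x J, at the EAP point
  W <- P * (1 - P)
  R2 <- (X - P)^2
  scored <- !is.na(X)
  outfit <- colSums(ifelse(scored, R2 / W, 0)) / colSums(scored)
  infit <- colSums(ifelse(scored, R2, 0)) / colSums(ifelse(scored, W, 0))
  # Binned observed-vs-expected chi-square. Both the binning ability and
  # the expected probability for item j condition on the responses to the
  # OTHER items only (leave-one-out posterior): binning on an ability that
  # contains item j's own response selects persons into bins by that very
  # response and inflates the statistic even under a true model.
  quad <- makeQuad(fit@quad$n, fit@quad$range)
  qn <- quadNodes(quad, fit@prior$mean, fit@prior$sd)
  logw <- qn$logw
  Mm0 <- scored + 0
  X00 <- ifelse(scored, X, 0L)
  Pq <- gridProbs(qn$nodes, it$a, it$b)   # Q x J
  logLfull <- X00 %*% t(log(Pq)) + (Mm0 - X00) %*% t(log1p(-Pq))  # n x Q
  chisq <- df <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    contrib <- outer(X00[, j], log(Pq[, j])) +
               outer(Mm0[, j] - X00[, j], log1p(-Pq[, j]))
    lw <- sweep(logLfull - contrib, 2L, logw, "+")
    m <- apply(lw, 1L, max)
    pw <- exp(lw - m); pw <- pw / rowSums(pw)
    thetaLoo <- as.vector(pw %*% qn$nodes)
    eP <- as.vector(pw %*% Pq[, j])         # expected P_j given other items
    bin <- abilityBins(thetaLoo, nBins, minBin)
    cs <- 0; dfj <- 0
    for (bq in seq_len(max(bin))) {
      sel <- bin == bq & scored[, j]
      nbj <- sum(sel)
      if (nbj == 0) next
      o <- mean(X[sel, j]); e <- mean(eP[sel])
      if (e <= 0 || e >= 1) next
      cs <- cs + nbj * (o - e)^2 / (e * (1 - e))
      dfj <- dfj + 1
    }
    chisq[j] <- cs; df[j] <- dfj
  }
  data.frame(item = it$item, infit = infit, outfit = outfit,
             chisq = chisq, df_chisq = df,
             p_chisq = pchisq(chisq, pmax(df, 1), lower.tail = FALSE),
             flagged = infit < bounds[1] | infit > bounds[2] |
                       outfit < bounds[1] | outfit > bounds[2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical item characteristic curves
#'
#' Observed proportion correct per ability bin for every item, with counts,
#' alongside the model-implied probability when a fit is supplied — the
#' ingredients for graphical item-fit inspection.
#'
#' @param responses the response data.
#' @param abilities data.frame from [eapAbilities()].
#' @param nBins number of ability bins (default 8); empty/small bins are
#'   merged with a neighbor, conserving counts.
#' @param minBin minimum persons per bin (default 5).
#' @param fit optional [IRTFit-class] for the model-implied curve.
#' @return long data.frame: `item`, `bin`, `theta_mean`, `n`, `observed`,
#'   `expected` (NA without a fit).
#' @export
empiricalICC <- function(responses, abilities, nBins = 8L, minBin = 5L,
                         fit = NULL) {
  X <- asCorrectness(responses)
  stopifnot(nrow(X) == nrow(abilities))
  bin <- abilityBins(abilities$theta, nBins, minBin)
  items <- colnames(X)
  rows <- list()
  for (j in seq_along(items)) {
    for (bq in sort(unique(bin))) {
      sel <- bin == bq & !is.na(X[, j])
      n <- sum(sel)
      ex <- NA_real_
      if (!is.null(fit)) {
        itj <- fit@items[fit@items$item == items[j] & fit@items$estimable, ]
        if (nrow(itj) == 1L && n > 0)
          ex <- mean(raschICC(abilities$theta[sel], itj$b, itj$a))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        item = items[j], bin = bq,
        theta_mean = if (n) mean(abilities$theta[sel]) else NA_real_,
        n = n, observed = if (n) mean(X[sel, j]) else NA_real_,
        expected = ex, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Differential item functioning between two groups (Rasch)
#'
#' Omnibus likelihood-ratio test of group-equal item difficulties against
#' group-specific difficulties, with the two latent distributions linked
#' through the constrained model (group-specific latent means and SDs; the
#' first group's mean anchors the scale). The alternative is two fully
#' separate Rasch fits, so the omnibus df equals J - 1. Per-item Wald tests
#' of the difficulty differences use all-other-items-as-anchor alignment:
#' item j's group shift is estimated relative to the mean shift of the
#' remaining items.
#'
#' @param responses a [ResponseMatrix-class] (or matrix) with responses from
#'   both groups.
#' @param group grouping variable: a vector with one value per person, or
#'   the name of a column of `personGroups(responses)`. Exactly 2 levels.
#' @param minGroup minimum persons per group (default 20).
#' @param alpha per-item flagging level for the unadjusted Wald tests
#'   (default 0.05).
#' @param ... passed to the underlying fits (`nQuad`, `tol`, ...).
#' @return list with `grouping`, `chisq`, `df`, `p` (omnibus), and `items`:
#'   data.frame `item`, `delta` (difficulty difference group2 - group1
#'   after anchoring), `se`, `z`, `p`, `flagged`.
#' @export
difTest <- function(responses, group, minGroup = 20L, alpha = 0.05, ...) {
  X <- asCorrectness(responses)
  gname <- "group"
  if (length(group) == 1L && is.character(group)) {
    gr <- personGroups(responses)
    if (is.null(gr) || !group %in% names(gr))
      stop(sprintf("grouping column '%s' not found in the responses", group))
    gname <- group
    group <- gr[[group]]
  }
  group <- as.factor(group)
  if (nlevels(group) != 2L)
    stop("DIF testing requires exactly 2 groups (got ",
         nlevels(group), ")")
  ng <- table(group)
  if (any(ng < minGroup))
    stop(sprintf("each group needs at least %d persons (got %s)",
                 minGroup, paste(ng, collapse = "/")))
  gi <- as.integer(group)
  dots <- list(...)
  quad <- makeQuad(dots$nQuad %||% 61L, dots$quadRange %||% c(-6, 6))
  tol <- dots$tol %||% 1e-5

  # items must be estimable within both groups for a group-specific fit
  estBoth <- rep(TRUE, ncol(X))
  for (g in 1:2) {
    Xg <- X[gi == g, , drop = FALSE]
    sc <- colSums(!is.na(Xg)); co <- colSums(Xg, na.rm = TRUE)
    estBoth <- estBoth & co >= 1 & (sc - co) >= 1 & sc >= 2
  }
  if (!all(estBoth))
    warning("items not estimable in both groups excluded from DIF testing: ",
            paste(colnames(X)[!estBoth], collapse = ", "))
  X <- X[, estBoth, drop = FALSE]
  J <- ncol(X)
  if (J < 2L) stop("fewer than 2 items estimable in both groups")

  null <- mmlFitMultigroup(X, gi, quad = quad, tol = tol)
  f1 <- mmlFit(X[gi == 1L, , drop = FALSE], "rasch", quad = quad, tol = tol, se = TRUE)
  f2 <- mmlFit(X[gi == 2L, , drop = FALSE], "rasch", quad = quad, tol = tol, se = TRUE)
  llAlt <- f1@loglik + f2@loglik
  nparAlt <- f1@npar + f2@npar
  chisq <- max(0, 2 * (llAlt - null$loglik))
  df <- nparAlt - null$npar
  b1 <- f1@items$b; se1 <- f1@items$se_b
  b2 <- f2@items$b; se2 <- f2@items$se_b
  raw <- b2 - b1
  delta <- se <- numeric(J)
  for (j in seq_len(J)) {
    anchorShift <- mean(raw[-j])
    delta[j] <- raw[j] - anchorShift
    se[j] <- sqrt(se1[j]^2 + se2[j]^2 +
                  sum(se1[-j]^2 + se2[-j]^2) / (J - 1)^2)
  }
  z <- delta / se
  p <- 2 * pnorm(-abs(z))
  list(grouping = gname,
       chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE),
       items = data.frame(item = colnames(X), delta = delta, se = se,
                          z = z, p = p, flagged = p < alpha,
                          stringsAsFactors = FALSE, row.names = NULL),
       groupFits = list(null = null, group1 = f1, group2 = f2))
}
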