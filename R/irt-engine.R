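# Internal marginal-maximum-likelihood machinery shared by fitRasch(),
# fit2PL() and the multigroup DIF fit. The latent ability is integrated out
# over a fixed quadrature grid (default 61 equally spaced nodes on [-6, 6]
# with midpoint weights h * dnorm; for Gaussian-decaying integrands this
# rule is accurate far beyond the EM tolerance). Estimation is EM:
# posteriors over nodes in the E-step, per-item logistic Newton updates and
# latent-moment updates in the M-step. No random initialization anywhere.

makeQuad <- function(n = 61L, range = c(-6, 6)) {
  nodes <- seq(range[1], range[2], length.out = n)
  list(nodes = nodes, h = nodes[2] - nodes[1], n = n, range = range)
}

# Ability nodes and log prior masses for an N(mean, sd) latent prior. The
# grid lives in prior-SD units (theta = mean + sd * z, z equally spaced on
# the quadrature range), so the integration always spans the same number
# of prior SDs regardless of the estimated latent scale.
quadNodes <- function(quad, mean = 0, sd = 1) {
  list(nodes = mean + sd * quad$nodes,
       logw = dnorm(quad$nodes, log = TRUE) + log(quad$h))
}

# item response probabilities on the grid: Q x J
gridProbs <- function(nodes, a, b) {
  plogis(outer(nodes, b, "-") * rep(a, each = length(nodes)))
}

# E-step for one person block. X0: n x J with NA -> 0; Mm: scored indicator.
# logPt/log1Pt: J x Q. Returns posterior (n x Q) and total loglik.
eStep <- function(X0, Mm, logPt, log1Pt, logw) {
  logL <- X0 %*% logPt + (Mm - X0) %*% log1Pt
  lw <- sweep(logL, 2L, logw, "+")
  m <- apply(lw, 1L, max)
  p <- exp(lw - m)
  s <- rowSums(p)
  list(post = p / s, ll = sum(log(s) + m))
}

# Newton solve for Rasch difficulties given expected counts (vectorized over
# items). nqj/rqj: Q x J expected scored / correct counts at each node.
raschItemUpdate <- function(b, nodes, nqj, rqj, maxit = 50L, tol = 1e-11) {
  rj <- colSums(rqj)
  for (i in seq_len(maxit)) {
    P <- gridProbs(nodes, rep(1, length(b)), b)
    g <- colSums(nqj * P) - rj
    hss <- colSums(nqj * P * (1 - P))
    step <- g / pmax(hss, 1e-12)
    step <- pmin(pmax(step, -1), 1)  # damp huge first steps
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  b
}

# Newton solve for 2PL (slope a, difficulty b) per item, in slope-intercept
# space logit = a*t + d with d = -a*b; a clipped to bounds.
twoplItemUpdate <- function(a, b, nodes, nqj, rqj, aBounds, maxit = 50L, tol = 1e-11) {
  d <- -a * b
  J <- length(a)
  for (i in seq_len(maxit)) {
    eta <- outer(nodes, a) + rep(d, each = length(nodes))
    P <- plogis(eta)
    R <- rqj - nqj * P           # Q x J score contributions
    W <- nqj * P * (1 - P)
    ga <- colSums(R * nodes)
    gd <- colSums(R)
    haa <- colSums(W * nodes^2)
    had <- colSums(W * nodes)
    hdd <- colSums(W)
    det <- pmax(haa * hdd - had^2, 1e-12)
    sa <- (hdd * ga - had * gd) / det
    sd_ <- (haa * gd - had * ga) / det
    sa <- pmin(pmax(sa, -0.5), 0.5)
    sd_ <- pmin(pmax(sd_, -1), 1)
    a <- pmin(pmax(a + sa, aBounds[1]), aBounds[2])
    d <- d + sd_
    if (max(abs(sa), abs(sd_)) < tol) break
  }
  list(a = a, b = -d / a)
}

# Analytic gradient of the marginal loglik at given parameters (Fisher's
# identity: expected complete-data score under the posterior). Used for
# observed-information standard errors via numerical differentiation.
mmlGradient <- function(par, model, X0, Mm, quad) {
  J <- ncol(X0)
  zq <- quad$nodes
  if (model == "rasch") {
    b <- par[seq_len(J)]; sig <- par[J + 1L]
    a <- rep(1, J)
  } else {
    a <- par[seq_len(J)]; b <- par[J + seq_len(J)]
    sig <- 1
  }
  qn <- quadNodes(quad, 0, sig)
  nodes <- qn$nodes; logw <- qn$logw
  P <- gridProbs(nodes, a, b)
  es <- eStep(X0, Mm, t(log(P)), t(log1p(-P)), logw)
  nqj <- crossprod(es$post, Mm)
  rqj <- crossprod(es$post, X0)
  R <- rqj - nqj * P
  gb <- -a * colSums(R)
  if (model == "rasch") {
    # theta = sig * z, so the scale gradient flows through the nodes
    gs <- sum(zq * rowSums(R))
    c(gb, gs)
  } else {
    ga <- colSums(R * (nodes - rep(b, each = length(nodes))))
    c(ga, gb)
  }
}

# Observed information by central differences of the analytic gradient.
mmlStandardErrors <- function(par, model, X0, Mm, quad) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- 1e-4 * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    H[, j] <- (mmlGradient(up, model, X0, Mm, quad) -
               mmlGradient(dn, model, X0, Mm, quad)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  info <- -H
  se <- rep(NA_real_, k)
  ok <- tryCatch({
    V <- solve(info)
    dg <- diag(V)
    se[dg > 0] <- sqrt(dg[dg > 0])
    TRUE
  }, error = function(e) FALSE)
  if (!ok) warning("observed information matrix is singular; standard errors unavailable")
  se
}

# Core single-group fit. X: persons x items matrix in {0,1,NA} with dimnames.
mmlFit <- function(X, model = c("rasch", "2pl"), quad = makeQuad(),
                   tol = 1e-5, maxit = 500L, aBounds = c(0.05, 5),
                   se = TRUE) {
  model <- match.arg(model)
  if (is.null(rownames(X))) rownames(X) <- paste0("p", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("i", seq_len(ncol(X)))
  Mm <- !is.na(X) + 0
  X0 <- ifelse(is.na(X), 0, X)
  nCorrect <- colSums(X0)
  nScored <- colSums(Mm)
  estimable <- nCorrect >= 1 & (nScored - nCorrect) >= 1 & nScored >= 2
  if (any(!estimable)) {
    warning("items without both correct and incorrect scored responses are inestimable and excluded: ",
            paste(colnames(X)[!estimable], collapse = ", "))
  }
  J <- sum(estimable)
  if (J < 1L) stop("no estimable items")
  if (model == "2pl" && J < 2L)
    stop("the 2PL model is not identified with a single estimable item")
  Xe <- X0[, estimable, drop = FALSE]
  Me <- Mm[, estimable, drop = FALSE]
  keepPerson <- rowSums(Me) > 0
  XeF <- Xe[keepPerson, , drop = FALSE]
  MeF <- Me[keepPerson, , drop = FALSE]
  n <- nrow(XeF)
  nodes <- quad$nodes

  p0 <- (colSums(XeF) + 0.5) / (colSums(MeF) + 1)
  b <- -qlogis(p0)
  a <- rep(1, J)
  sig <- 1
  trace <- numeric(0)
  conv <- FALSE; iter <- 0L; maxChange <- NA_real_
  repeat {
    iter <- iter + 1L
    qn <- quadNodes(quad, 0, sig)
    P <- gridProbs(qn$nodes, a, b)
    es <- eStep(XeF, MeF, t(log(P)), t(log1p(-P)), qn$logw)
    trace <- c(trace, es$ll)
    nqj <- crossprod(es$post, MeF)
    rqj <- crossprod(es$post, XeF)
    if (model == "rasch") {
      bNew <- raschItemUpdate(b, qn$nodes, nqj, rqj)
      sigNew <- sqrt(sum(colSums(es$post) * qn$nodes^2) / n)
      maxChange <- max(abs(bNew - b), abs(sigNew - sig))
      b <- bNew; sig <- sigNew
    } else {
      up <- twoplItemUpdate(a, b, qn$nodes, nqj, rqj, aBounds)
      maxChange <- max(abs(up$a - a), abs(up$b - b))
      a <- up$a; b <- up$b
    }
    if (maxChange < tol) { conv <- TRUE; break }
    if (iter >= maxit) break
  }
  # loglik at the final parameters
  qn <- quadNodes(quad, 0, sig)
  P <- gridProbs(qn$nodes, a, b)
  es <- eStep(XeF, MeF, t(log(P)), t(log1p(-P)), qn$logw)
  trace <- c(trace, es$ll)
  if (any(diff(trace) < -1e-6 * (1 + abs(es$ll))))
    warning("marginal log-likelihood decreased during EM; results may be unreliable")

  npar <- if (model == "rasch") J + 1L else 2L * J
  seA <- rep(NA_real_, J); seB <- rep(NA_real_, J); seSig <- NA_real_
  if (se) {
    par <- if (model == "rasch") c(b, sig) else c(a, b)
    ses <- mmlStandardErrors(par, model, XeF, MeF, quad)
    if (model == "rasch") {
      seB <- ses[seq_len(J)]; seSig <- ses[J + 1L]
    } else {
      seA <- ses[seq_len(J)]; seB <- ses[J + seq_len(J)]
    }
  }
  items <- data.frame(
    item = colnames(X), a = NA_real_, b = NA_real_,
    se_a = NA_real_, se_b = NA_real_, estimable = estimable,
    stringsAsFactors = FALSE, row.names = NULL)
  items$a[estimable] <- a
  items$b[estimable] <- b
  items$se_a[estimable] <- seA
  items$se_b[estimable] <- seB
  new("IRTFit",
      model = model, items = items,
      prior = list(mean = 0, sd = if (model == "rasch") sig else 1,
                   sd_se = seSig),
      loglik = es$ll, npar = npar,
      AIC = -2 * es$ll + 2 * npar,
      BIC = -2 * es$ll + npar * log(n),
      nPersons = as.integer(n), nItems = as.integer(ncol(X)),
      convergence = list(converged = conv, iterations = iter,
                         maxChange = maxChange, loglikTrace = trace),
      quad = list(n = quad$n, range = quad$range))
}

# Multigroup Rasch with shared difficulties, group-specific latent means
# (group 1 anchored at 0) and SDs. Used as the null model of the DIF
# omnibus test. groups: integer vector in {1, 2} per person.
mmlFitMultigroup <- function(X, groups, quad = makeQuad(), tol = 1e-5,
                             maxit = 500L) {
  Mm <- !is.na(X) + 0
  X0 <- ifelse(is.na(X), 0, X)
  nCorrect <- colSums(X0); nScored <- colSums(Mm)
  estimable <- nCorrect >= 1 & (nScored - nCorrect) >= 1 & nScored >= 2
  Xe <- X0[, estimable, drop = FALSE]; Me <- Mm[, estimable, drop = FALSE]
  keep <- rowSums(Me) > 0
  Xe <- Xe[keep, , drop = FALSE]; Me <- Me[keep, , drop = FALSE]
  groups <- groups[keep]
  J <- ncol(Xe); n <- nrow(Xe)
  g1 <- groups == 1L; g2 <- !g1
  p0 <- (colSums(Xe) + 0.5) / (colSums(Me) + 1)
  b <- -qlogis(p0); mu2 <- 0; sig <- c(1, 1)
  # each group integrates over its own prior-scaled grid; the shared-item
  # M-step stacks the two grids' expected counts
  groupE <- function(b, mu2, sig) {
    q1 <- quadNodes(quad, 0, sig[1])
    q2 <- quadNodes(quad, mu2, sig[2])
    P1 <- gridProbs(q1$nodes, rep(1, J), b)
    P2 <- gridProbs(q2$nodes, rep(1, J), b)
    e1 <- eStep(Xe[g1, , drop = FALSE], Me[g1, , drop = FALSE],
                t(log(P1)), t(log1p(-P1)), q1$logw)
    e2 <- eStep(Xe[g2, , drop = FALSE], Me[g2, , drop = FALSE],
                t(log(P2)), t(log1p(-P2)), q2$logw)
    list(e1 = e1, e2 = e2, nodes1 = q1$nodes, nodes2 = q2$nodes)
  }
  trace <- numeric(0); conv <- FALSE; iter <- 0L; maxChange <- NA_real_
  repeat {
    iter <- iter + 1L
    ge <- groupE(b, mu2, sig)
    trace <- c(trace, ge$e1$ll + ge$e2$ll)
    nqj <- rbind(crossprod(ge$e1$post, Me[g1, , drop = FALSE]),
                 crossprod(ge$e2$post, Me[g2, , drop = FALSE]))
    rqj <- rbind(crossprod(ge$e1$post, Xe[g1, , drop = FALSE]),
                 crossprod(ge$e2$post, Xe[g2, , drop = FALSE]))
    bNew <- raschItemUpdate(b, c(ge$nodes1, ge$nodes2), nqj, rqj)
    s1 <- sqrt(sum(colSums(ge$e1$post) * ge$nodes1^2) / sum(g1))
    m2 <- sum(colSums(ge$e2$post) * ge$nodes2) / sum(g2)
    s2 <- sqrt(sum(colSums(ge$e2$post) * (ge$nodes2 - m2)^2) / sum(g2))
    maxChange <- max(abs(bNew - b), abs(s1 - sig[1]), abs(s2 - sig[2]), abs(m2 - mu2))
    b <- bNew; sig <- c(s1, s2); mu2 <- m2
    if (maxChange < tol) { conv <- TRUE; break }
    if (iter >= maxit) break
  }
  ge <- groupE(b, mu2, sig)
  list(b = setNames(b, colnames(Xe)), mu2 = mu2, sigma = sig,
       loglik = ge$e1$ll + ge$e2$ll, npar = J + 3L, converged = conv,
       iterations = iter, estimable = estimable, nPersons = n)
}
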