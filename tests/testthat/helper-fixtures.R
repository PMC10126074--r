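# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; no data files.

# A tiny feature table with hand-picked values.
toyFeatures <- function(n = 6, gender = "female", seed = 1) {
  withr::with_seed(seed, {
    f1 <- runif(n, 400, 600)
    fd <- runif(n, 850, 1150)
    data.frame(
      speaker_id = sprintf("%s%02d", substr(gender, 1, 1), seq_len(n)),
      gender = gender,
      f0_hz = runif(n, 180, 240),
      f1_hz = f1, f2_hz = f1 + fd * 0.9, f3_hz = f1 + fd * 2,
      f4_hz = f1 + fd * 3,
      hnr_db = runif(n, 10, 20),
      stringsAsFactors = FALSE)
  })
}

# A VoiceSpace built directly from given 3D coordinates (standardized on
# construction so validity holds).
spaceFromCoords <- function(xyz, ids = NULL, stratum = "female") {
  xyz <- as.matrix(xyz)
  ids <- ids %||% sprintf("v%02d", seq_len(nrow(xyz)))
  z <- scale(xyz)
  ctr <- attr(z, "scaled:center"); scl <- attr(z, "scaled:scale")
  z <- matrix(as.numeric(z), nrow(xyz), ncol(xyz),
              dimnames = list(ids, c("f0", "fd", "hnr")))
  new("VoiceSpace", stratum = stratum, speakerIds = ids, coords = z,
      standardization = list(center = ctr, scale = scl,
                             transform = "identity"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force marginal log-likelihood by dense grid
# integration over the latent ability (the oracle for the EM's internal
# value).
denseGridLoglik <- function(X, b, a = rep(1, length(b)), sigma = 1,
                            lo = -9, hi = 9, nGrid = 20001) {
  xs <- seq(lo, hi, length.out = nGrid)
  h <- xs[2] - xs[1]
  w <- dnorm(xs, 0, sigma) * h
  w[c(1, nGrid)] <- w[c(1, nGrid)] / 2
  P <- plogis(outer(xs, b, "-") * rep(a, each = nGrid))
  X0 <- ifelse(is.na(X), 0, X)
  Mm <- !is.na(X) + 0
  logL <- X0 %*% t(log(P)) + (Mm - X0) %*% t(log1p(-P))
  m <- apply(logL, 1, max)
  sum(log(rowSums(exp(sweep(logL, 1, m)) * rep(w, each = nrow(X)))) + m)
}

# As denseGridLoglik but with the latent mean shifted: translation
# identification means shifting all difficulties and the latent mean by
# the same constant leaves the marginal likelihood unchanged.
denseGridLoglikShift <- function(X, b, sigma = 1, shift = 0,
                                 lo = -9, hi = 9, nGrid = 20001) {
  xs <- seq(lo + shift, hi + shift, length.out = nGrid)
  h <- xs[2] - xs[1]
  w <- dnorm(xs, shift, sigma) * h
  w[c(1, nGrid)] <- w[c(1, nGrid)] / 2
  P <- plogis(outer(xs, b, "-"))
  X0 <- ifelse(is.na(X), 0, X)
  Mm <- !is.na(X) + 0
  logL <- X0 %*% t(log(P)) + (Mm - X0) %*% t(log1p(-P))
  m <- apply(logL, 1, max)
  sum(log(rowSums(exp(sweep(logL, 1, m)) * rep(w, each = nrow(X)))) + m)
}

# Independent dense-grid EAP (posterior mean and SD).
denseGridEAP <- function(X, b, a = rep(1, length(b)), sigma = 1,
                         lo = -9, hi = 9, nGrid = 20001) {
  xs <- seq(lo, hi, length.out = nGrid)
  h <- xs[2] - xs[1]
  w <- dnorm(xs, 0, sigma) * h
  P <- plogis(outer(xs, b, "-") * rep(a, each = nGrid))
  X0 <- ifelse(is.na(X), 0, X)
  Mm <- !is.na(X) + 0
  logL <- X0 %*% t(log(P)) + (Mm - X0) %*% t(log1p(-P))
  m <- apply(logL, 1, max)
  pw <- exp(sweep(logL, 1, m)) * rep(w, each = nrow(X))
  pw <- pw / rowSums(pw)
  mu <- as.vector(pw %*% xs)
  v <- as.vector(pw %*% xs^2) - mu^2
  cbind(theta = mu, se = sqrt(v))
}

# Small deterministic Rasch data for oracle comparisons.
toyResponses <- function(n = 60, b = c(-1, 0, 1), seed = 7, missing = 0) {
  withr::with_seed(seed, {
    th <- rnorm(n)
    P <- plogis(outer(th, b, "-"))
    X <- matrix(rbinom(n * length(b), 1, P), n, length(b),
                dimnames = list(sprintf("p%03d", 1:n),
                                sprintf("i%02d", seq_along(b))))
    if (missing > 0) X[withr::with_seed(seed + 1, sample(length(X), missing))] <- NA
    X
  })
}

# brute-force oracle: scan all C(n,3) triples recomputing distances
# elementwise, independent of the package's distance code
bruteTriplets <- function(space, tolerance) {
  ids <- sort(speakerIds(space))
  co <- coords(space)[ids, , drop = FALSE]
  out <- list()
  n <- length(ids)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    d12 <- sqrt(sum((co[i, ] - co[j, ])^2))
    d13 <- sqrt(sum((co[i, ] - co[k, ])^2))
    d23 <- sqrt(sum((co[j, ] - co[k, ])^2))
    s <- c(d12, d13, d23)
    dev <- (max(s) - min(s)) / mean(s)
    if (min(s) > 0 && dev <= tolerance)
      out[[length(out) + 1L]] <- data.frame(id1 = ids[i], id2 = ids[j], id3 = ids[k],
                                            stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(id1 = character(), id2 = character(), id3 = character())
}

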