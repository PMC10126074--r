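# The IRT engine: response function, MML estimation, model comparison,
# EAP abilities, reliability, information, item fit, DIF.

test_that("the item characteristic curve has its analytic anchor points", {
  # ability equal to difficulty: probability exactly 0.5
  for (bb in c(-2, 0, 1.7)) expect_equal(raschICC(bb, bb), 0.5)
  expect_equal(raschICC(1, 0), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_gte(raschICC(20, 0), 1 - 1e-8)
  expect_lte(raschICC(-20, 0), 1e-8)
  # 2PL slope steepens around b
  expect_gt(raschICC(0.5, 0, a = 2), raschICC(0.5, 0, a = 1))
})

test_that("EM marginal loglik matches dense-grid integration on a toy", {
  X <- toyResponses(60, c(-1, 0, 1), seed = 7, missing = 10)
  fit <- fitRasch(X)
  ip <- itemParams(fit)
  oracle <- denseGridLoglik(X, ip$b, sigma = priorParams(fit)$sd)
  expect_equal(fit@loglik, oracle, tolerance = 1e-4)
  # and the EM trace is monotone non-decreasing
  expect_true(all(diff(fit@convergence$loglikTrace) >
                  -1e-8 * (1 + abs(fit@loglik))))
})

test_that("2PL loglik also matches the dense-grid oracle", {
  X <- toyResponses(80, c(-1, 0.2, 1), seed = 12)
  fit <- fit2PL(X)
  ip <- itemParams(fit)
  oracle <- denseGridLoglik(X, ip$b, a = ip$a, sigma = 1)
  expect_equal(fit@loglik, oracle, tolerance = 1e-4)
})

test_that("Rasch difficulties are recovered from simulated data", {
  b <- c(-1, 0, 1)
  rm0 <- simulateResponses(setNames(b, c("e", "m", "h")), 500, seed = 5)
  fit <- fitRasch(rm0, se = FALSE)
  bh <- itemParams(fit)$b
  # centered after identification alignment
  rmse <- sqrt(mean(((bh - mean(bh)) - (b - mean(b)))^2))
  expect_lt(rmse, 0.15)
  expect_equal(order(bh), order(b))
})

test_that("translation of difficulties and latent mean leaves loglik unchanged", {
  X <- toyResponses(60, c(-0.5, 0.5, 1), seed = 3)
  fit <- fitRasch(X)
  ip <- itemParams(fit)
  s <- priorParams(fit)$sd
  base <- denseGridLoglikShift(X, ip$b, s, shift = 0)
  for (sh in c(-0.7, 0.4)) {
    expect_equal(denseGridLoglikShift(X, ip$b + sh, s, shift = sh), base,
                 tolerance = 1e-8)
  }
})

test_that("degenerate items are flagged, single-item 2PL errors", {
  X <- toyResponses(40, c(-1, 0, 1), seed = 9)
  X[, 2] <- 1L  # answered correctly by everyone
  expect_warning(fit <- fitRasch(X), "inestimable")
  ip <- itemParams(fit)
  expect_false(ip$estimable[2])
  expect_true(is.na(ip$b[2]))
  expect_true(all(ip$estimable[c(1, 3)]))
  X1 <- toyResponses(40, c(0, 0.2), seed = 2)
  X1[, 2] <- 1L
  expect_error(suppressWarnings(fit2PL(X1)), "identified")
})

test_that("2PL recovers the ordering of discriminations", {
  it <- data.frame(item = sprintf("i%d", 1:6),
                   b = c(-1, 0, 1, -1, 0, 1),
                   a = c(0.5, 0.5, 0.5, 2, 2, 2))
  rm0 <- simulateResponses(it, 800, seed = 31)
  fit <- fit2PL(rm0, se = FALSE)
  ah <- itemParams(fit)$a
  expect_true(all(ah[4:6] > ah[1:3]))
})

test_that("likelihood-ratio test computes chi-square, df, p correctly", {
  mk <- function(ll, npar, n = 100L) new("IRTFit",
    model = "rasch", items = data.frame(item = "i", a = 1, b = 0, se_a = NA_real_,
                                        se_b = NA_real_, estimable = TRUE),
    prior = list(mean = 0, sd = 1), loglik = ll, npar = as.integer(npar),
    AIC = -2 * ll + 2 * npar, BIC = -2 * ll + npar * log(n),
    nPersons = n, nItems = 1L,
    convergence = list(converged = TRUE, iterations = 1L, maxChange = 0,
                       loglikTrace = ll),
    quad = list(n = 61L, range = c(-6, 6)))
  # identical fits: chi-square 0, p 1
  out <- lrTest(mk(-100, 4), mk(-100, 9))
  expect_equal(out$chisq, 0)
  expect_equal(out$p, 1)
  # logliks -100 and -97.5 with df 5: chi-square 5, p from the chi-square
  # upper tail (frozen from an independent evaluation of the chi-square
  # survival function at 5 with 5 df)
  out <- lrTest(mk(-100, 4), mk(-97.5, 9))
  expect_equal(out$chisq, 5)
  expect_equal(out$df, 5)
  expect_equal(out$p, 0.4158801869, tolerance = 1e-8)
  expect_error(lrTest(mk(-97, 4), mk(-100, 9)), "lower log-likelihood")
  expect_error(lrTest(mk(-100, 9), mk(-99, 4)), "fewer free parameters")
})

test_that("EAP abilities match dense-grid posterior integration", {
  X <- toyResponses(30, c(-1.5, -0.5, 0.5, 1.5), seed = 17, missing = 8)
  fit <- fitRasch(X)
  ip <- itemParams(fit)
  ab <- eapAbilities(fit, X)
  oracle <- denseGridEAP(X, ip$b, sigma = priorParams(fit)$sd)
  expect_equal(ab$theta, unname(oracle[, "theta"]), tolerance = 1e-6)
  expect_equal(ab$se, unname(oracle[, "se"]), tolerance = 1e-6)
})

test_that("the sum score is sufficient for Rasch EAP", {
  X <- toyResponses(50, c(-1, -0.3, 0.4, 1.2), seed = 23)
  fit <- fitRasch(X)
  ab <- eapAbilities(fit, X)
  ss <- rowSums(X)
  for (s in unique(ss)) {
    th <- ab$theta[ss == s]
    expect_lt(diff(range(th)), 1e-8)
  }
})

test_that("persons without scored responses fall back to the prior", {
  X <- toyResponses(30, c(-1, 0, 1), seed = 29)
  X[1, ] <- NA
  fit <- suppressWarnings(fitRasch(X))
  ab <- eapAbilities(fit, X)
  expect_equal(ab$theta[1], 0, tolerance = 1e-8)
  expect_equal(ab$se[1], priorParams(fit)$sd, tolerance = 1e-6)
})

test_that("empirical reliability is the EAP variance ratio", {
  ab <- data.frame(person = c("a", "b", "c"),
                   theta = c(-0.6, 0, 0.6), se = sqrt(0.15))
  # var(theta) = 0.36; with mean SE^2 = 0.15: 0.36/0.51
  expect_equal(empiricalReliability(ab), 0.36 / 0.51)
  abHand <- data.frame(theta = c(-1, 1), se = 0)
  abHand$theta <- abHand$theta * sqrt(0.3 / var(abHand$theta))
  abHand$se <- sqrt(0.15)
  expect_equal(empiricalReliability(abHand), 0.3 / 0.45, tolerance = 1e-12)
  # zero error variance: limit 1
  expect_equal(empiricalReliability(data.frame(theta = c(-1, 1), se = 0)), 1)
  expect_error(empiricalReliability(data.frame(theta = c(0.2, 0.2), se = 0)),
               "undefined")
  expect_error(empiricalReliability(data.frame(theta = 1, se = 1)), "at least 2")
})

test_that("test information follows the analytic form", {
  fit <- fitRasch(toyResponses(80, c(-1, 0, 1), seed = 37))
  ip <- itemParams(fit)
  # single-item information at theta = b is a^2 * 0.25
  info <- testInformation(fit, theta = ip$b[2])
  expect_equal(info$information,
               sum(ip$a^2 * raschICC(ip$b[2], ip$b, ip$a) *
                   (1 - raschICC(ip$b[2], ip$b, ip$a))))
  # symmetric around b for one item, and SE = 1/sqrt(I)
  one <- fit
  one@items <- one@items[2, , drop = FALSE]
  x <- seq(0.1, 2, by = 0.3)
  iLeft <- testInformation(one, ip$b[2] - x)$information
  iRight <- testInformation(one, ip$b[2] + x)$information
  expect_equal(iLeft, iRight, tolerance = 1e-10)
  expect_equal(testInformation(one, ip$b[2])$information, ip$a[2]^2 * 0.25)
  curve <- testInformation(fit)
  expect_equal(curve$se, 1 / sqrt(curve$information))
})

test_that("information is unimodal near the difficulty mass on a fitted set", {
  b <- withr::with_seed(41, runif(22, -2, 2))
  rm0 <- simulateResponses(setNames(b, sprintf("i%02d", 1:22)), 400, seed = 43)
  fit <- fitRasch(rm0, se = FALSE)
  curve <- testInformation(fit, theta = seq(-5, 5, by = 0.25))
  peak <- curve$theta[which.max(curve$information)]
  expect_lt(abs(peak - mean(itemParams(fit)$b)), 1)
  # decreasing toward the extremes
  expect_lt(curve$information[1], max(curve$information) / 4)
  expect_lt(curve$information[nrow(curve)], max(curve$information) / 4)
})

test_that("item fit is calibrated on model-true data and detects guessing", {
  infits <- c()
  for (s in 1:5) {
    b <- withr::with_seed(50 + s, runif(15, -1.5, 1.5))
    rm0 <- simulateResponses(setNames(b, sprintf("i%02d", 1:15)), 400, seed = 60 + s)
    fit <- fitRasch(rm0, se = FALSE)
    fs <- itemFit(fit, rm0)
    infits <- c(infits, mean(fs$infit))
    expect_false(any(fs$flagged))
  }
  expect_gt(mean(infits), 0.9)
  expect_lt(mean(infits), 1.1)
  # a guessing-floored, low-discrimination item is detected by the binned
  # chi-square more often than conforming items
  hitsBad <- hitsClean <- 0
  for (s in 1:10) {
    it <- data.frame(item = sprintf("i%02d", 1:15),
                     b = withr::with_seed(70 + s, runif(15, -1.5, 1.5)),
                     a = 1, c = 0)
    it$b[15] <- 0.5; it$a[15] <- 0.5; it$c[15] <- 1 / 3
    rm1 <- simulateResponses(it, 800, seed = 80 + s)
    fit <- fitRasch(rm1, se = FALSE)
    fs <- itemFit(fit, rm1)
    hitsBad <- hitsBad + (fs$p_chisq[15] < 0.05)
    hitsClean <- hitsClean + mean(fs$p_chisq[1:14] < 0.05)
  }
  expect_gt(hitsBad, hitsClean)
  expect_gte(hitsBad, 7)  # detected in most replicates
})

test_that("empirical ICCs are monotone for a conforming item and conserve counts", {
  b <- withr::with_seed(89, runif(20, -1, 1))
  rm0 <- simulateResponses(setNames(b, sprintf("i%02d", 1:20)), 1000, seed = 91)
  fit <- fitRasch(rm0, se = FALSE)
  ab <- eapAbilities(fit, rm0)
  icc <- empiricalICC(rm0, ab, fit = fit)
  one <- icc[icc$item == "i01", ]
  expect_equal(sum(one$n), 1000L)
  # non-decreasing up to sampling noise: regression slope positive
  expect_gt(coef(lm(observed ~ theta_mean, data = one))[2], 0)
  # observed curve tracks the model-implied curve
  expect_gt(cor(one$observed, one$expected), 0.9)
  # an all-correct item yields a flat observed curve at 1
  X <- correctness(rm0)
  X[, "i01"] <- 1L
  fit2 <- suppressWarnings(fitRasch(X, se = FALSE))
  ab2 <- eapAbilities(fit2, X)
  icc2 <- empiricalICC(X, ab2)
  expect_true(all(icc2$observed[icc2$item == "i01"] == 1))
})

test_that("DIF on a duplicated dataset is null", {
  X <- toyResponses(120, c(-1, -0.3, 0.4, 1.2), seed = 101)
  XX <- rbind(X, X)
  rownames(XX) <- sprintf("p%03d", seq_len(nrow(XX)))
  g <- rep(c("A", "B"), each = nrow(X))
  d <- difTest(XX, g)
  expect_lt(d$chisq, 1)
  expect_equal(d$df, ncol(X) - 1L)
  expect_lt(max(abs(d$items$delta)), 0.05)
  expect_false(any(d$items$flagged))
})

test_that("DIF flags a shifted item and guards degenerate groups", {
  it <- data.frame(item = sprintf("i%02d", 1:12),
                   b = withr::with_seed(111, runif(12, -1.5, 1.5)))
  shifts <- data.frame(item = "i05", group_var = "g", group = "B", delta = 1)
  rm1 <- simulateResponses(it, 500, seed = 113,
                           groups = list(g = c(A = 0.5, B = 0.5)),
                           difShifts = shifts)
  d <- difTest(rm1, "g")
  expect_true(d$items$flagged[d$items$item == "i05"])
  expect_equal(d$items$item[which.max(abs(d$items$z))], "i05")
  expect_lt(d$p, 0.05)
  # single group and tiny groups are errors
  expect_error(difTest(rm1, rep("A", 500)), "exactly 2 groups")
  expect_error(difTest(rm1, c(rep("A", 490), rep("B", 10))), "at least 20")
})

test_that("standard errors are finite and shrink with sample size", {
  b <- c(-1, 0, 1)
  rmSmall <- simulateResponses(setNames(b, c("e", "m", "h")), 150, seed = 131)
  rmBig <- simulateResponses(setNames(b, c("e", "m", "h")), 1200, seed = 131)
  seS <- itemParams(fitRasch(rmSmall))$se_b
  seB <- itemParams(fitRasch(rmBig))$se_b
  expect_true(all(is.finite(seS)) && all(seS > 0))
  expect_true(all(seB < seS))
  # roughly 1/sqrt(n) scaling
  expect_equal(mean(seS / seB), sqrt(1200 / 150), tolerance = 0.35)
})

test_that("reliability grows with test length on nested item sets", {
  b <- withr::with_seed(141, runif(22, -2, 2))
  rm0 <- simulateResponses(setNames(b, sprintf("i%02d", 1:22)), 500, seed = 143)
  X <- correctness(rm0)
  fitFull <- fitRasch(X, se = FALSE)
  fitHalf <- fitRasch(X[, 1:11], se = FALSE)
  relFull <- empiricalReliability(eapAbilities(fitFull, X))
  relHalf <- empiricalReliability(eapAbilities(fitHalf, X[, 1:11]))
  expect_gt(relFull, relHalf)
})
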