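# Equilateral triplet search, similarity stratification, target selection,
# and the foil-disjoint assignment search.

test_that("pairwise distances are Euclidean, symmetric, zero-diagonal", {
  sp <- spaceFromCoords(rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1), c(2, 0, 2)))
  D <- pairwiseDistances(sp)
  # 3-4-5 triangle before standardization is not preserved, so recompute
  # from the standardized coordinates independently
  co <- coords(sp)
  expect_equal(D["v01", "v02"], sqrt(sum((co[1, ] - co[2, ])^2)))
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_equal(D, t(D))
  withr::with_seed(2, {
    co6 <- matrix(rnorm(18), 6, 3)
    sp6 <- spaceFromCoords(co6)
    D6 <- pairwiseDistances(sp6)
    z <- coords(sp6)
    for (i in 1:6) for (j in 1:6)
      expect_equal(D6[i, j], sqrt(sum((z[i, ] - z[j, ])^2)))
  })
})

test_that("an exact equilateral triangle is found with zero deviation", {
  # equilateral in the plane z = const after standardization stays
  # equilateral only if scaling is isotropic, so construct coordinates
  # already standardized: bypass scaling with sd-1 columns is fiddly;
  # instead verify on the standardized coordinates directly
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  pts <- rbind(pts, pts + 5)  # 6 points, two exact triangles far apart
  pts[, 3] <- c(0, 0.1, -0.1, 5, 5.1, 4.9)
  sp <- spaceFromCoords(pts)
  tri <- findEquilateralTriplets(sp, tolerance = 0.5)
  oracle <- bruteTriplets(sp, 0.5)
  expect_equal(tri[c("id1", "id2", "id3")], oracle, ignore_attr = TRUE)
})

test_that("collinear points never qualify", {
  # collinear triples with sides a, b, a+b have deviation
  # (a+b-min)/(2(a+b)/3) >= 3/4, so any tolerance below 0.75 rejects them
  sp <- spaceFromCoords(cbind(1:5, 2 * (1:5), -(1:5)))
  expect_equal(nrow(findEquilateralTriplets(sp, tolerance = 0.5)), 0L)
  expect_equal(nrow(findEquilateralTriplets(sp, tolerance = 0.7)), 0L)
})

test_that("triplet search matches exhaustive enumeration on random spaces", {
  for (seed in 1:3) {
    sp <- spaceFromCoords(withr::with_seed(seed, matrix(rnorm(30), 10, 3)))
    for (tol in c(0.1, 0.3)) {
      got <- findEquilateralTriplets(sp, tol)
      oracle <- bruteTriplets(sp, tol)
      expect_equal(got[c("id1", "id2", "id3")], oracle, ignore_attr = TRUE)
      # sides and deviation are internally consistent
      if (nrow(got)) {
        expect_true(all(got$deviation <= tol))
        expect_equal(got$size,
                     unname(rowMeans(got[c("side12", "side13", "side23")])))
      }
    }
  }
})

test_that("triplet search is invariant to input order and monotone in tolerance", {
  co <- withr::with_seed(9, matrix(rnorm(36), 12, 3))
  sp <- spaceFromCoords(co)
  perm <- withr::with_seed(10, sample(12))
  sp2 <- spaceFromCoords(co[perm, ], ids = sprintf("v%02d", seq_len(12))[perm])
  t1 <- findEquilateralTriplets(sp, 0.25)
  t2 <- findEquilateralTriplets(sp2, 0.25)
  expect_equal(t1, t2, ignore_attr = TRUE)
  # enlarging the tolerance never removes a triplet
  keyed <- function(tt) paste(tt$id1, tt$id2, tt$id3)
  for (tols in list(c(0.05, 0.1), c(0.1, 0.2), c(0.2, 0.5))) {
    expect_true(all(keyed(findEquilateralTriplets(sp, tols[1])) %in%
                    keyed(findEquilateralTriplets(sp, tols[2]))))
  }
})

test_that("similarity stratification applies the size boundaries", {
  tri <- data.frame(id1 = c("a", "b", "c"), id2 = c("d", "e", "f"),
                    id3 = c("g", "h", "i"),
                    side12 = 1, side13 = 1, side23 = 1,
                    size = c(0.5, 1.0, 2.0), deviation = 0)
  lab <- stratifyTriplets(tri, boundaries = c(0.8, 1.5))
  expect_equal(as.character(lab$similarity), c("high", "medium", "low"))
  # tertile default: every class non-empty on a spread of sizes
  tri2 <- tri[rep(1:3, each = 4), ]
  tri2$size <- seq(0.2, 3, length.out = 12)
  lab2 <- stratifyTriplets(tri2)
  expect_true(all(table(lab2$similarity) > 0))
  # all same size with boundaries around it: a single class
  tri3 <- tri; tri3$size <- 1
  expect_true(all(stratifyTriplets(tri3, c(0.9, 1.1))$similarity == "medium"))
  expect_error(stratifyTriplets(tri, boundaries = c(2, 1)), "increasing")
})

test_that("target selection follows membership counts with lexicographic ties", {
  tri <- data.frame(
    id1 = c("v1", "v1", "v1", "v2"), id2 = c("v2", "v3", "v4", "v3"),
    id3 = c("v5", "v6", "v7", "v8"),
    side12 = 1, side13 = 1, side23 = 1, size = 1, deviation = 0,
    stringsAsFactors = FALSE)
  # v1 in 3 triplets dominates; v2 and v3 tied at 2 -> v2 first
  expect_equal(selectTargets(tri, 3), c("v1", "v2", "v3"))
  # counting oracle: brute-force tally
  counts <- sort(table(c(tri$id1, tri$id2, tri$id3)), decreasing = TRUE)
  expect_equal(unname(counts["v1"]), 3L)
  expect_error(selectTargets(tri, 99), "cannot select")
})

test_that("assignment satisfies level-completeness and foil-disjointness", {
  # generous instance: per target, per level, disjoint candidate foils
  mk <- function(tg, sim, f1, f2, size, dev = 0.01)
    data.frame(id1 = tg, id2 = f1, id3 = f2, side12 = size, side13 = size,
               side23 = size, size = size, deviation = dev,
               similarity = factor(sim, levels = c("high", "medium", "low")),
               stringsAsFactors = FALSE)
  tri <- rbind(
    mk("t1", "high", "f01", "f02", 0.5), mk("t1", "medium", "f03", "f04", 1),
    mk("t1", "medium", "f05", "f06", 1.1), mk("t1", "low", "f07", "f08", 2),
    mk("t2", "high", "f09", "f10", 0.5), mk("t2", "medium", "f11", "f12", 1),
    mk("t2", "medium", "f13", "f14", 1.1), mk("t2", "low", "f15", "f16", 2))
  asg <- assignTriplets(c("t1", "t2"), tri)
  expect_true(isTRUE(checkAssignment(asg)))
  a <- assignments(asg)
  expect_equal(nrow(a), 8L)
  expect_false(anyDuplicated(c(a$foil1, a$foil2)) > 0)
})

test_that("assignment prefers lower equilaterality defect", {
  mk <- function(tg, sim, f1, f2, dev)
    data.frame(id1 = tg, id2 = f1, id3 = f2, side12 = 1, side13 = 1,
               side23 = 1, size = 1, deviation = dev,
               similarity = factor(sim, levels = c("high", "medium", "low")),
               stringsAsFactors = FALSE)
  tri <- rbind(mk("t1", "high", "fA", "fB", 0.09),
               mk("t1", "high", "fC", "fD", 0.01),
               mk("t1", "medium", "fE", "fF", 0.02),
               mk("t1", "medium", "fG", "fH", 0.03),
               mk("t1", "low", "fI", "fJ", 0.02))
  a <- assignments(assignTriplets("t1", tri))
  high <- a[a$similarity == "high", ]
  expect_equal(sort(c(high$foil1, high$foil2)), c("fC", "fD"))
})

test_that("forced foil conflicts are reported as infeasible", {
  mk <- function(tg, sim, f1, f2)
    data.frame(id1 = tg, id2 = f1, id3 = f2, side12 = 1, side13 = 1,
               side23 = 1, size = 1, deviation = 0,
               similarity = factor(sim, levels = c("high", "medium", "low")),
               stringsAsFactors = FALSE)
  # the only medium triplet shares a foil with the only high triplet
  tri <- rbind(mk("t1", "high", "fA", "fB"),
               mk("t1", "medium", "fB", "fC"),
               mk("t1", "low", "fD", "fE"))
  expect_error(assignTriplets("t1", tri), "infeasible")
  # missing level entirely
  expect_error(assignTriplets("t1", tri[tri$similarity != "low", ]),
               "low level")
})

test_that("backtracking agrees with exhaustive search on feasibility", {
  mk <- function(tg, sim, f1, f2)
    data.frame(id1 = tg, id2 = f1, id3 = f2, side12 = 1, side13 = 1,
               side23 = 1, size = 1, deviation = 0,
               similarity = factor(sim, levels = c("high", "medium", "low")),
               stringsAsFactors = FALSE)
  foilPool <- sprintf("f%02d", 1:12)
  withr::with_seed(21, {
    for (rep in 1:20) {
      tri <- do.call(rbind, lapply(1:20, function(i) {
        tg <- sample(c("t1", "t2"), 1)
        fs <- sample(foilPool, 2)
        mk(tg, sample(c("high", "medium", "low"), 1), fs[1], fs[2])
      }))
      got <- tryCatch({ assignTriplets(c("t1", "t2"), tri); TRUE },
                      error = function(e) FALSE)
      # exhaustive oracle over all slot-candidate combinations
      slots <- list()
      feasible <- TRUE
      for (tg in c("t1", "t2")) for (lv in c("high", "medium", "medium2", "low")) {
        lvq <- if (lv == "medium2") "medium" else lv
        cc <- tri[(tri$id1 == tg) & tri$similarity == lvq, , drop = FALSE]
        if (!nrow(cc)) { feasible <- FALSE; break }
        slots[[paste(tg, lv)]] <- cc
      }
      oracle <- FALSE
      if (feasible) {
        grid <- expand.grid(lapply(slots, function(s) seq_len(nrow(s))))
        for (r in seq_len(nrow(grid))) {
          foils <- unlist(lapply(seq_along(slots), function(si) {
            row <- slots[[si]][grid[r, si], ]
            c(row$id2, row$id3)
          }))
          if (!anyDuplicated(foils)) { oracle <- TRUE; break }
        }
      }
      expect_identical(got, oracle)
    }
  })
})
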