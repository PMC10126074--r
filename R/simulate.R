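# Seeded generators: gender-clustered synthetic voice features and
# simulated 3AFC respondents, so every construction and analysis stage is
# exercisable without any recorded voices or collected data. The defaults
# are configurable stand-ins chosen to be realistic for adult speakers
# (male f0 around 115 Hz, female around 210 Hz, formant dispersion around
# 1 kHz, HNR around 15 dB), not measurements of any real speaker pool.

#' Simulate gender-clustered voice features
#'
#' Draws per-speaker f0 (gender-specific clusters), four strictly
#' increasing formants whose mean successive difference equals a drawn
#' formant-dispersion value exactly, and HNR, all from configurable normal
#' distributions. Deterministic per seed.
#'
#' @param nPerGender speakers per gender stratum (>= 3; default 40, the
#'   pool size the triplet design assumes per gender).
#' @param params list of distribution settings: `f0` (named list
#'   male/female, each c(mean, sd)), `f1`, `fd`, `hnr` (each c(mean, sd)).
#' @param seed integer seed.
#' @return a validated feature data.frame (see [voiceFeatureTable()]).
#' @export
simulateVoiceFeatures <- function(nPerGender = 40L,
                                  params = list(
                                    f0 = list(male = c(115, 15), female = c(210, 20)),
                                    f1 = c(500, 60),
                                    fd = c(1000, 80),
                                    hnr = c(15, 3)),
                                  seed = 1L) {
  if (nPerGender < 3L) stop("need at least 3 speakers per gender stratum")
  for (p in c(params$f0, list(params$f1, params$fd, params$hnr)))
    if (length(p) != 2L || !all(is.finite(p)) || p[2] <= 0)
      stop("distribution parameters must be finite (mean, sd > 0) pairs")
  withLocalSeed(seed, {
    rows <- list()
    for (g in c("female", "male")) {
      f0p <- params$f0[[g]]
      for (k in seq_len(nPerGender)) {
        f0 <- max(50, rnorm(1, f0p[1], f0p[2]))
        f1 <- max(200, rnorm(1, params$f1[1], params$f1[2]))
        fd <- max(300, rnorm(1, params$fd[1], params$fd[2]))
        gaps <- abs(rnorm(3L, fd, 0.12 * fd))
        gaps <- gaps * fd / mean(gaps)  # mean successive difference == fd
        rows[[length(rows) + 1L]] <- data.frame(
          speaker_id = sprintf("%s%02d", substr(g, 1, 1), k), gender = g,
          f0_hz = f0, f1_hz = f1, f2_hz = f1 + gaps[1],
          f3_hz = f1 + gaps[1] + gaps[2], f4_hz = f1 + sum(gaps),
          hnr_db = rnorm(1, params$hnr[1], params$hnr[2]),
          stringsAsFactors = FALSE)
      }
    }
    voiceFeatureTable(do.call(rbind, rows))
  })
}

#' Simulate 3AFC respondents
#'
#' Generates a persons-by-items correctness matrix from
#' \eqn{P = c + (1 - c)\,\mathrm{logistic}(a(\theta - b))}: the Rasch/2PL
#' response function with an optional guessing floor `c` (1/3 is the 3AFC
#' chance level, the canonical misspecification scenario for these tests).
#' Optional per-person groups, per-item group difficulty shifts (DIF), and
#' omissions: omitted trials are missing with a response time at or above
#' 4000 ms; answered trials get plausible sub-cutoff log-normal RTs.
#'
#' @param items numeric vector of difficulties (names become item ids), or
#'   a data.frame with columns `item`, `b` and optionally `a` and `c`
#'   (per-item guessing floors overriding `guessing`).
#' @param nPersons number of respondents.
#' @param seed integer seed.
#' @param abilityMean,abilitySD latent ability distribution (default
#'   standard normal).
#' @param guessing guessing floor c in \[0, 1) (default 0).
#' @param groups optional named list of group factors to draw, e.g.
#'   `list(gender = c(female = 0.5, male = 0.5))` (names = levels, values =
#'   proportions).
#' @param difShifts optional data.frame `item`, `group_var`, `group`,
#'   `delta`: difficulty shift added for persons in that group.
#' @param omissionProb per-trial omission probability (default 0).
#' @param rt list with `meanlog`, `sdlog` for answered-trial RTs in ms.
#' @return a [ResponseMatrix-class] with RTs and group labels.
#' @export
simulateResponses <- function(items, nPersons, seed = 1L,
                              abilityMean = 0, abilitySD = 1,
                              guessing = 0, groups = NULL, difShifts = NULL,
                              omissionProb = 0,
                              rt = list(meanlog = log(1300), sdlog = 0.35)) {
  if (is.data.frame(items)) {
    itemIds <- as.character(items$item)
    b <- items$b
    a <- if ("a" %in% names(items)) items$a else rep(1, length(b))
    cc <- if ("c" %in% names(items)) items$c else rep(guessing, length(b))
  } else {
    b <- as.numeric(items)
    itemIds <- names(items) %||% sprintf("item%02d", seq_along(b))
    a <- rep(1, length(b))
    cc <- rep(guessing, length(b))
  }
  stopifnot(abilitySD > 0, all(cc >= 0), all(cc < 1),
            omissionProb >= 0, omissionProb <= 1)
  J <- length(b)
  withLocalSeed(seed, {
    theta <- rnorm(nPersons, abilityMean, abilitySD)
    gdf <- data.frame(row.names = sprintf("p%04d", seq_len(nPersons)))
    if (!is.null(groups)) {
      for (gv in names(groups)) {
        pr <- groups[[gv]]
        gdf[[gv]] <- sample(names(pr), nPersons, replace = TRUE, prob = pr)
      }
    }
    B <- matrix(b, nPersons, J, byrow = TRUE)
    if (!is.null(difShifts)) {
      for (k in seq_len(nrow(difShifts))) {
        jj <- match(difShifts$item[k], itemIds)
        if (is.na(jj)) stop("difShifts names an unknown item: ", difShifts$item[k])
        sel <- gdf[[difShifts$group_var[k]]] == difShifts$group[k]
        B[sel, jj] <- B[sel, jj] + difShifts$delta[k]
      }
    }
    Cm <- matrix(cc, nPersons, J, byrow = TRUE)
    P <- Cm + (1 - Cm) * plogis(rep(a, each = nPersons) * (theta - B))
    X <- matrix(rbinom(nPersons * J, 1L, P), nPersons, J,
                dimnames = list(sprintf("p%04d", seq_len(nPersons)), itemIds))
    RT <- matrix(pmin(rlnorm(nPersons * J, rt$meanlog, rt$sdlog), 3999),
                 nPersons, J, dimnames = dimnames(X))
    if (omissionProb > 0) {
      om <- matrix(runif(nPersons * J) < omissionProb, nPersons, J)
      X[om] <- NA_integer_
      RT[om] <- 4000 + runif(sum(om), 0, 2000)
    }
    storage.mode(X) <- "integer"
    new("ResponseMatrix", correctness = X, rt = RT, groups = gdf)
  })
}

# Build a combined two-gender assignment from simulated features; the
# equilaterality tolerance escalates through `tolerances` until the
# backtracking assignment is feasible (documented ladder, deterministic).
# Because the most-connected voices tend to be mutually close in the
# space, a membership-ranked target set can be unassignable (a target's
# small triangles may all involve other targets); ranked target
# combinations are therefore tried in deterministic order before the
# tolerance escalates.
simulatedAssignment <- function(features, targetsPerGender = 4L,
                                tolerances = c(0.10, 0.15, 0.20, 0.25, 0.30),
                                maxTargetSets = 15L) {
  parts <- lapply(c("female", "male"), function(g) {
    space <- buildVoiceSpace(features, g)
    for (tolv in tolerances) {
      trip <- tryCatch(stratifyTriplets(findEquilateralTriplets(space, tolv)),
                       error = function(e) NULL)
      if (is.null(trip) || !nrow(trip)) next
      # a usable target needs at least one triplet per similarity level and
      # two at medium (test + learning); filter before ranking
      voices <- unique(c(trip$id1, trip$id2, trip$id3))
      levelCount <- function(v, lv)
        sum((trip$id1 == v | trip$id2 == v | trip$id3 == v) & trip$similarity == lv)
      eligible <- voices[vapply(voices, function(v)
        levelCount(v, "high") >= 1L && levelCount(v, "medium") >= 2L &&
        levelCount(v, "low") >= 1L, logical(1))]
      if (length(eligible) < targetsPerGender) next
      tripElig <- trip[(trip$id1 %in% eligible) | (trip$id2 %in% eligible) |
                       (trip$id3 %in% eligible), , drop = FALSE]
      ranked <- selectTargets(tripElig, length(eligible))
      ranked <- ranked[ranked %in% eligible]
      poolSize <- min(length(ranked), targetsPerGender + 4L)
      ranked <- ranked[seq_len(poolSize)]
      if (length(ranked) < targetsPerGender) next
      sets <- combn(ranked, targetsPerGender, simplify = FALSE)
      for (tg in head(sets, maxTargetSets)) {
        res <- tryCatch(assignTriplets(tg, trip), error = function(e) NULL)
        if (!is.null(res)) return(res)
      }
    }
    stop(sprintf("no feasible triplet assignment for stratum %s up to tolerance %.2f",
                 g, max(tolerances)))
  })
  new("TripletAssignment",
      targets = c(targetIds(parts[[1]]), targetIds(parts[[2]])),
      assignments = rbind(assignments(parts[[1]]), assignments(parts[[2]])),
      config = list(tolerances = tolerances))
}

#' End-to-end synthetic fixture
#'
#' Generates a complete synthetic bundle — voice features, per-gender
#' spaces, triplet assignment, blueprint, and simulated responses — sized
#' like the corresponding construction stage: `"item-selection"` (72 test
#' items, 232 respondents), `"validation"` (26 items, 454 respondents),
#' `"final"` (22 items, 454 respondents). Byte-identical per seed.
#'
#' @param preset one of "item-selection", "validation", "final".
#' @param seed integer seed.
#' @param nPersons override the preset's respondent count.
#' @return list with `features`, `assignment`, `blueprint`, `itemParams`,
#'   `responses`.
#' @export
makeFixture <- function(preset = c("item-selection", "validation", "final"),
                        seed = 1L, nPersons = NULL) {
  preset <- match.arg(preset)
  sizes <- list(`item-selection` = list(items = 72L, persons = 232L, omission = 0.012),
                validation = list(items = 26L, persons = 454L, omission = 0.017),
                final = list(items = 22L, persons = 454L, omission = 0.017))
  sz <- sizes[[preset]]
  n <- nPersons %||% sz$persons
  features <- simulateVoiceFeatures(seed = seed)
  assignment <- simulatedAssignment(features)
  blueprint <- assembleBlueprint(assignment, seed = seed)
  if (sz$items < nrow(testTrials(blueprint))) {
    ids <- withLocalSeed(seed + 7L,
      sort(sample(testTrials(blueprint)$item_id, sz$items)))
    blueprint <- subsetBlueprint(blueprint, ids)
  }
  itemIds <- testTrials(blueprint)$item_id
  itemParams <- data.frame(item = itemIds,
                           a = rep(1, length(itemIds)),
                           b = withLocalSeed(seed + 11L,
                             runif(length(itemIds), -2, 2)),
                           stringsAsFactors = FALSE)
  responses <- simulateResponses(itemParams, n, seed = seed + 13L,
                                 groups = list(gender = c(female = 0.45, male = 0.55),
                                               age_band = c(young = 0.5, old = 0.5)),
                                 omissionProb = sz$omission)
  list(features = features, assignment = assignment, blueprint = blueprint,
       itemParams = itemParams, responses = responses)
}
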