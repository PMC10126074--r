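# Equilateral voice triplets: one target plus two same-gender foils with
# (approximately) equal pairwise distances in the standardized acoustic
# space, so that no member of a 3AFC trial stands out perceptually. Triangle
# size maps inversely to acoustic similarity: small triangles mean similar,
# hence confusable, hence hard trials.

#' Pairwise Euclidean distances between speakers in a voice space
#'
#' @param space a [VoiceSpace-class].
#' @return symmetric distance matrix with zero diagonal, dimnames = speaker
#'   ids.
#' @export
pairwiseDistances <- function(space) {
  stopifnot(is(space, "VoiceSpace"))
  as.matrix(dist(coords(space), method = "euclidean"))
}

#' Find (near-)equilateral triplets in a voice space
#'
#' Scans all unordered triples of speakers and keeps those whose
#' equilaterality defect, `(max side - min side) / mean side`, is at most
#' `tolerance`. The defect is 0 for an exact equilateral triangle and
#' approaches 1 for degenerate (collinear) ones, so any tolerance below 1
#' rejects collinear triples. Output order is deterministic (sorted ids).
#'
#' @param space a [VoiceSpace-class] with at least 3 speakers.
#' @param tolerance maximum relative deviation of side lengths (default
#'   0.10; the size strata stay configurable because published selection
#'   criteria for "equal distances" live in supplementary material).
#' @return data.frame with columns `id1`, `id2`, `id3` (sorted within and
#'   across rows), `side12`, `side13`, `side23`, `size` (mean side),
#'   `deviation`.
#' @export
findEquilateralTriplets <- function(space, tolerance = 0.10) {
  stopifnot(is(space, "VoiceSpace"), tolerance > 0)
  ids <- sort(speakerIds(space))
  n <- length(ids)
  if (n < 3L) stop("need at least 3 speakers")
  D <- pairwiseDistances(space)[ids, ids]
  tri <- combn(n, 3L)
  s12 <- D[cbind(tri[1, ], tri[2, ])]
  s13 <- D[cbind(tri[1, ], tri[3, ])]
  s23 <- D[cbind(tri[2, ], tri[3, ])]
  sides <- cbind(s12, s13, s23)
  mx <- pmax(s12, s13, s23)
  mn <- pmin(s12, s13, s23)
  size <- rowMeans(sides)
  dev <- (mx - mn) / size
  keep <- is.finite(dev) & dev <= tolerance & mn > 0
  out <- data.frame(
    id1 = ids[tri[1, keep]], id2 = ids[tri[2, keep]], id3 = ids[tri[3, keep]],
    side12 = s12[keep], side13 = s13[keep], side23 = s23[keep],
    size = size[keep], deviation = dev[keep],
    stringsAsFactors = FALSE)
  out[order(out$id1, out$id2, out$id3), , drop = FALSE]
}

#' Stratify triplets into similarity levels by triangle size
#'
#' Small triangles (acoustically close voices) are labelled `high`
#' similarity, large ones `low`. By default the two cut-points are the
#' empirical tertiles of the qualifying triplet sizes; absolute cut-points
#' can be supplied instead.
#'
#' @param triplets data.frame from [findEquilateralTriplets()].
#' @param boundaries two strictly increasing size cut-points, or `NULL` for
#'   empirical tertiles.
#' @return the input with a `similarity` factor column (`high`, `medium`,
#'   `low`) and the boundaries used in attribute `"boundaries"`.
#' @export
stratifyTriplets <- function(triplets, boundaries = NULL) {
  if (is.null(boundaries)) {
    boundaries <- unname(quantile(triplets$size, c(1, 2) / 3, type = 7))
  }
  if (length(boundaries) != 2L || diff(boundaries) <= 0)
    stop("boundaries must be two strictly increasing cut-points")
  lab <- ifelse(triplets$size < boundaries[1], "high",
         ifelse(triplets$size < boundaries[2], "medium", "low"))
  triplets$similarity <- factor(lab, levels = c("high", "medium", "low"))
  attr(triplets, "boundaries") <- boundaries
  triplets
}

#' Select learning targets by triplet membership
#'
#' The learning (and subsequent target) voices are the identities that are
#' part of the most triplets, which maximizes the combinations available
#' when assigning foils. Ties are broken by lexicographically smallest
#' speaker id, keeping the design pipeline deterministic without a seed.
#'
#' @param triplets data.frame from [findEquilateralTriplets()] (one gender
#'   stratum).
#' @param n number of targets to select.
#' @return character vector of `n` speaker ids, in selection order.
#' @export
selectTargets <- function(triplets, n) {
  members <- c(triplets$id1, triplets$id2, triplets$id3)
  counts <- table(members)
  if (length(counts) < n)
    stop(sprintf("only %d distinct voices appear in triplets; cannot select %d targets",
                 length(counts), n))
  ord <- order(-as.integer(counts), names(counts))
  names(counts)[ord][seq_len(n)]
}

#' Assign triplets to targets under global foil-disjointness
#'
#' For every target, selects one test triplet per similarity level (high,
#' medium, low) plus one additional medium-similarity triplet for the
#' immediate recognition trials of the learning phase, such that every foil
#' identity appears in exactly one assigned triplet overall and no target
#' ever serves as another target's foil. A backtracking constraint search
#' is used; among feasible choices, triplets with smaller equilaterality
#' defect are preferred (ties by foil ids), making the result deterministic
#' given the input order.
#'
#' @param targets character vector of target ids (see [selectTargets()]).
#' @param triplets stratified triplet data.frame (see
#'   [stratifyTriplets()]).
#' @param maxNodes search budget (backtracking node expansions, default
#'   20000); instances that exhaust it are reported as infeasible within
#'   the budget. Small instances are always searched completely.
#' @return a [TripletAssignment-class].
#' @export
assignTriplets <- function(targets, triplets, maxNodes = 2e4) {
  if (!"similarity" %in% names(triplets))
    stop("triplets must be stratified first (see stratifyTriplets)")
  # one slot per (target, role/level), learning slot is a second medium
  slots <- do.call(rbind, lapply(targets, function(tg) data.frame(
    target = tg,
    role = c("test", "test", "test", "learning"),
    similarity = c("high", "medium", "low", "medium"),
    stringsAsFactors = FALSE)))
  cand <- vector("list", nrow(slots))
  for (k in seq_len(nrow(slots))) {
    tg <- slots$target[k]
    inTrip <- triplets$id1 == tg | triplets$id2 == tg | triplets$id3 == tg
    tt <- triplets[inTrip & triplets$similarity == slots$similarity[k], , drop = FALSE]
    if (nrow(tt)) {
      mem <- cbind(tt$id1, tt$id2, tt$id3)
      foils <- t(apply(mem, 1L, function(r) sort(setdiff(r, tg))))
      ok <- !(foils[, 1] %in% targets) & !(foils[, 2] %in% targets)
      tt <- tt[ok, , drop = FALSE]; foils <- foils[ok, , drop = FALSE]
      o <- order(tt$deviation, foils[, 1], foils[, 2])
      cand[[k]] <- data.frame(foil1 = foils[o, 1], foil2 = foils[o, 2],
                              size = tt$size[o], deviation = tt$deviation[o],
                              stringsAsFactors = FALSE)
    } else {
      cand[[k]] <- data.frame(foil1 = character(), foil2 = character(),
                              size = numeric(), deviation = numeric())
    }
    if (!nrow(cand[[k]]))
      stop(sprintf("infeasible: no candidate triplet for target %s at %s level (%s phase)",
                   tg, slots$similarity[k], slots$role[k]))
  }
  # fill scarcest slots first; report infeasibility at the first slot that
  # cannot be filled along any branch
  orderIdx <- order(vapply(cand, nrow, 0L))
  nSlots <- length(orderIdx)
  cf1 <- lapply(cand, function(cc) cc$foil1)  # plain vectors for the hot loop
  cf2 <- lapply(cand, function(cc) cc$foil2)
  chosen <- integer(nrow(slots))
  deepest <- 1L
  nodes <- 0L
  # forward checking: after each tentative choice, every remaining slot must
  # still have at least one candidate free of the used foils
  remainingOk <- function(pos, used) {
    for (p in seq.int(pos, nSlots)) {
      k <- orderIdx[p]
      if (!any(!(cf1[[k]] %in% used) & !(cf2[[k]] %in% used))) return(FALSE)
    }
    TRUE
  }
  search <- function(pos, used) {
    if (pos > nSlots) return(TRUE)
    nodes <<- nodes + 1L
    if (nodes > maxNodes) stop("assignment search budget exhausted", call. = FALSE)
    k <- orderIdx[pos]
    f1 <- cf1[[k]]; f2 <- cf2[[k]]
    for (i in seq_along(f1)) {
      if (f1[i] %in% used || f2[i] %in% used) next
      usedNew <- c(used, f1[i], f2[i])
      if (pos < nSlots && !remainingOk(pos + 1L, usedNew)) next
      chosen[k] <<- i
      if (pos == nSlots || search(pos + 1L, usedNew)) return(TRUE)
    }
    deepest <<- max(deepest, pos)
    FALSE
  }
  found <- tryCatch(search(1L, character()), error = function(e) {
    if (grepl("budget exhausted", conditionMessage(e))) NA else stop(e)
  })
  if (is.na(found)) {
    stop(sprintf("infeasible within the search budget (%g nodes): could not complete the assignment for %d targets",
                 maxNodes, length(targets)))
  }
  if (!found) {
    k <- orderIdx[deepest]
    stop(sprintf("infeasible: could not satisfy target %s at %s level (%s phase) under foil-disjointness",
                 slots$target[k], slots$similarity[k], slots$role[k]))
  }
  rows <- lapply(seq_len(nrow(slots)), function(k) {
    cc <- cand[[k]][chosen[k], , drop = FALSE]
    data.frame(target = slots$target[k], role = slots$role[k],
               similarity = slots$similarity[k],
               foil1 = cc$foil1, foil2 = cc$foil2,
               size = cc$size, deviation = cc$deviation,
               stringsAsFactors = FALSE)
  })
  asg <- new("TripletAssignment",
             targets = targets,
             assignments = do.call(rbind, rows),
             config = list(boundaries = attr(triplets, "boundaries")))
  stopifnot(isTRUE(checkAssignment(asg)))
  asg
}

#' Independently validate a triplet assignment
#'
#' Re-checks foil-disjointness and level-completeness from the assignment
#' table alone (this is also enforced by the class validity; the function
#' exists so searches can be audited independently of the constructor).
#'
#' @param assignment a [TripletAssignment-class].
#' @return `TRUE`, or a character vector of violations.
#' @export
checkAssignment <- function(assignment) {
  v <- validObject(assignment, test = TRUE)
  if (isTRUE(v)) TRUE else v
}
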