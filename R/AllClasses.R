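#' @import methods
#' @importFrom stats dnorm pchisq plogis pnorm pt qlogis rbinom rlnorm rnorm
#'   runif sd var setNames p.adjust qnorm quantile dist
#' @importFrom utils read.csv write.csv combn head
NULL

# Central containers are S4 with validity so that every downstream stage can
# rely on structural guarantees instead of re-checking its inputs.

#' Standardized 3D acoustic voice space
#'
#' Holds per-speaker coordinates in the standardized (f0, formant dispersion,
#' HNR) space for one gender stratum, together with the standardization
#' parameters that produced them, so any coordinate can be traced back to raw
#' Hz/dB values.
#'
#' @slot stratum single character, the gender stratum (or "pooled").
#' @slot speakerIds character vector of speaker identifiers (row order).
#' @slot coords numeric matrix, speakers x 3, columns f0/fd/hnr, each
#'   dimension standardized to mean 0, SD 1 within the stratum.
#' @slot standardization list with `center`, `scale` (named length-3
#'   numerics) and `transform` ("identity" or "log_f0").
#'
#' @seealso [buildVoiceSpace()]
#' @export
setClass("VoiceSpace",
  representation(
    stratum = "character",
    speakerIds = "character",
    coords = "matrix",
    standardization = "list"
  )
)

setValidity("VoiceSpace", function(object) {
  msg <- character()
  if (length(object@stratum) != 1L) msg <- c(msg, "stratum must be length 1")
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
  if (nrow(object@coords) != length(object@speakerIds))
    msg <- c(msg, "coords row count must equal speaker count")
  if (nrow(object@coords) >= 3L) {
    mu <- colMeans(object@coords)
    s <- apply(object@coords, 2, sd)
    if (any(abs(mu) > 1e-8)) msg <- c(msg, "coordinate dimensions must have mean 0")
    if (any(abs(s - 1) > 1e-8)) msg <- c(msg, "coordinate dimensions must have SD 1")
  } else {
    msg <- c(msg, "a voice space needs at least 3 speakers")
  }
  sc <- object@standardization$scale
  if (!is.null(sc) && any(sc <= 0)) msg <- c(msg, "standardization SDs must be positive")
  if (length(msg)) msg else TRUE
})

#' Triplet assignment for a set of learning targets
#'
#' The outcome of the constrained triplet-to-target assignment: for every
#' learning target one test triplet per similarity level (high, medium, low)
#' plus one additional medium-similarity triplet for the immediate
#' recognition trials of the learning phase. Foils are globally disjoint:
#' every foil identity appears in exactly one assigned triplet.
#'
#' @slot targets character vector of target speaker ids.
#' @slot assignments data.frame with one row per assigned triplet: `target`,
#'   `role` ("learning" or "test"), `similarity`, `foil1`, `foil2`, `size`,
#'   `deviation` (equilaterality defect).
#' @slot config list recording the tolerance and similarity boundaries used.
#'
#' @seealso [assignTriplets()]
#' @export
setClass("TripletAssignment",
  representation(
    targets = "character",
    assignments = "data.frame",
    config = "list"
  )
)

setValidity("TripletAssignment", function(object) {
  msg <- character()
  a <- object@assignments
  need <- c("target", "role", "similarity", "foil1", "foil2", "size", "deviation")
  if (!all(need %in% names(a))) {
    return(paste("assignments must contain columns:", paste(need, collapse = ", ")))
  }
  foils <- c(a$foil1, a$foil2)
  if (anyDuplicated(foils)) msg <- c(msg, "every foil may appear in exactly one triplet")
  if (any(foils %in% object@targets)) msg <- c(msg, "targets may not serve as foils")
  for (tg in object@targets) {
    at <- a[a$target == tg, ]
    test <- at[at$role == "test", ]
    learn <- at[at$role == "learning", ]
    if (nrow(learn) != 1L || learn$similarity != "medium")
      msg <- c(msg, sprintf("target %s needs exactly one medium learning triplet", tg))
    if (!setequal(test$similarity, c("high", "medium", "low")) || nrow(test) != 3L)
      msg <- c(msg, sprintf("target %s needs one test triplet per similarity level", tg))
  }
  if (length(msg)) msg else TRUE
})

#' Three-phase test blueprint
#'
#' The complete trial-level plan of the voice learning and memory test:
#' alternating familiarization and immediate recognition trials over two
#' learning cycles, a passive repetition playlist, and the 3AFC testing
#' phase with its similarity-by-duration factorial design, one fixed
#' randomized order, and balanced target positions.
#'
#' @slot familiarization data.frame: `cycle`, `order`, `speaker`,
#'   `sentence_1`..`sentence_3`.
#' @slot immediate data.frame: `cycle`, `order`, `target`, `foil1`, `foil2`,
#'   `target_position`, `sentence`, `similarity`, `duration`.
#' @slot repetition data.frame: `order`, `speaker`, `sentence`, `source`.
#' @slot test data.frame: `item_id`, `order`, `target`, `foil1`, `foil2`,
#'   `target_position`, `sentence`, `similarity`, `duration`.
#' @slot sentencePool character vector of sentence ids available.
#' @slot practice list of practice/dummy-trial metadata (not analyzed).
#' @slot seed integer seed the assembly was run under.
#' @slot config list of assembly settings (durations, response window).
#'
#' @seealso [assembleBlueprint()], [validateBlueprint()]
#' @export
setClass("TestBlueprint",
  representation(
    familiarization = "data.frame",
    immediate = "data.frame",
    repetition = "data.frame",
    test = "data.frame",
    sentencePool = "character",
    practice = "list",
    seed = "integer",
    config = "list"
  )
)

#' Persons-by-items response matrix
#'
#' Binary correctness with optional response times and per-person group
#' labels. Missing entries (omissions) stay missing: they are excluded from
#' likelihoods and scoring, never imputed or scored incorrect.
#'
#' @slot correctness integer matrix persons x items with values 0, 1 or NA.
#' @slot rt numeric matrix of response times in ms (same shape), or a
#'   0x0 matrix when unavailable.
#' @slot groups data.frame of per-person categorical labels (0 columns when
#'   unavailable), rownames matching person ids.
#'
#' @seealso [simulateResponses()], [fitRasch()], [scoreResponses()]
#' @export
setClass("ResponseMatrix",
  representation(
    correctness = "matrix",
    rt = "matrix",
    groups = "data.frame"
  )
)

setValidity("ResponseMatrix", function(object) {
  msg <- character()
  x <- object@correctness
  if (nrow(x) < 2L || ncol(x) < 2L)
    msg <- c(msg, "need at least 2 persons and 2 items")
  vals <- x[!is.na(x)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msg <- c(msg, "correctness values must be 0, 1 or NA")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    msg <- c(msg, "correctness must carry person and item ids as dimnames")
  if (length(object@rt) && !identical(dim(object@rt), dim(x)))
    msg <- c(msg, "rt must match correctness in shape")
  if (ncol(object@groups) > 0L && nrow(object@groups) != nrow(x))
    msg <- c(msg, "groups must have one row per person")
  if (length(msg)) msg else TRUE
})

#' Fitted IRT model
#'
#' Marginal-maximum-likelihood fit of a Rasch or 2PL model. The Rasch fit
#' fixes the common discrimination at 1 and estimates the latent SD; the 2PL
#' fixes the latent prior to standard normal and frees per-item
#' discriminations, so free-parameter counts (and hence LR/AIC/BIC
#' comparisons) are like-for-like.
#'
#' @slot model "rasch" or "2pl".
#' @slot items data.frame: `item`, `a`, `b`, `se_a`, `se_b`, `estimable`.
#' @slot prior list: `mean` (fixed 0), `sd`, `sd_se` (NA for 2PL).
#' @slot loglik marginal log-likelihood at the solution.
#' @slot npar free-parameter count.
#' @slot AIC,BIC information criteria (BIC uses n = persons).
#' @slot nPersons,nItems data dimensions used in the fit.
#' @slot convergence list: `converged`, `iterations`, `maxChange`,
#'   `loglikTrace`.
#' @slot quad list: `nodes`, `range`, number of quadrature nodes and range.
#'
#' @seealso [fitRasch()], [fit2PL()], [eapAbilities()]
#' @export
setClass("IRTFit",
  representation(
    model = "character",
    items = "data.frame",
    prior = "list",
    loglik = "numeric",
    npar = "integer",
    AIC = "numeric",
    BIC = "numeric",
    nPersons = "integer",
    nItems = "integer",
    convergence = "list",
    quad = "list"
  )
)

setValidity("IRTFit", function(object) {
  msg <- character()
  if (!object@model %in% c("rasch", "2pl")) msg <- c(msg, "model must be rasch or 2pl")
  it <- object@items
  if (!all(c("item", "a", "b", "se_a", "se_b", "estimable") %in% names(it)))
    msg <- c(msg, "items table incomplete")
  if (any(it$a[it$estimable] <= 0, na.rm = TRUE)) msg <- c(msg, "discriminations must be positive")
  bic <- -2 * object@loglik + object@npar * log(object@nPersons)
  if (is.finite(object@BIC) && abs(bic - object@BIC) > 1e-6)
    msg <- c(msg, "BIC inconsistent with loglik and parameter count")
  if (length(msg)) msg else TRUE
})

#' Stepwise item-selection trace
#'
#' Ordered, fully auditable log of the stepwise item-selection workflow:
#' which item was eliminated at which step, for which reason
#' (`below_chance`, `ill_fitting`, `dif`), with the statistic that triggered
#' it; the step at which the model regime switched from 2PL to Rasch; and
#' the retained item set.
#'
#' @slot log data.frame: `step`, `item`, `reason`, `criterion`, `value`,
#'   `model`.
#' @slot initialItems,finalItems character vectors.
#' @slot switchStep step index at which the 2PL-vs-Rasch LR test first
#'   became non-significant (NA if it never was significant / never tested).
#' @slot aborted logical, TRUE if the minimum-items guardrail stopped the
#'   loop before all fit criteria were met.
#' @slot details list of per-step fit summaries (loglik, LR p, etc.).
#'
#' @seealso [stepwiseSelect()], [difScreen()], [finalizeSelection()]
#' @export
setClass("SelectionTrace",
  representation(
    log = "data.frame",
    initialItems = "character",
    finalItems = "character",
    switchStep = "integer",
    aborted = "logical",
    details = "list"
  )
)

setValidity("SelectionTrace", function(object) {
  msg <- character()
  elim <- object@log$item
  if (anyDuplicated(elim)) msg <- c(msg, "an item can be eliminated only once")
  if (!setequal(c(elim, object@finalItems), object@initialItems))
    msg <- c(msg, "eliminated and retained items must partition the initial set")
  if (length(intersect(elim, object@finalItems)))
    msg <- c(msg, "eliminated and retained sets must be disjoint")
  bad <- setdiff(unique(object@log$reason), c("below_chance", "ill_fitting", "dif"))
  if (length(bad)) msg <- c(msg, paste("invalid elimination reason:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Respondent score report
#'
#' Per-person scored-trial counts, omission counts, proportion correct, and
#' (when norms are supplied) extreme-score flags, plus cohort summaries.
#' Flags are labelled "potential": scores at least 2 SDs below or above the
#' norm mean are screening signals only, and clinical conclusions require
#' comprehensive follow-up testing.
#'
#' @slot persons data.frame: `person`, `n_trials`, `n_scored`, `n_omitted`,
#'   `omission_rate`, `sum_correct`, `proportion_correct`, and `flag` when
#'   norms were provided.
#' @slot cohort list of cohort-level summaries.
#' @slot rtCutoff the omission cutoff in ms that was applied.
#'
#' @seealso [scoreResponses()], [flagExtremes()]
#' @export
setClass("ScoreReport",
  representation(
    persons = "data.frame",
    cohort = "list",
    rtCutoff = "numeric"
  )
)

setMethod("show", "VoiceSpace", function(object) {
  cat(sprintf("VoiceSpace (%s): %d speakers, dimensions f0/fd/hnr (standardized, transform=%s)\n",
    object@stratum, length(object@speakerIds),
    object@standardization$transform %||% "identity"))
})

setMethod("show", "TripletAssignment", function(object) {
  cat(sprintf("TripletAssignment: %d targets, %d triplets (%d foils, all disjoint)\n",
    length(object@targets), nrow(object@assignments),
    2L * nrow(object@assignments)))
})

setMethod("show", "TestBlueprint", function(object) {
  cat(sprintf(
    "TestBlueprint: %d familiarization + %d immediate trials (2 cycles), %d repetition slots, %d test trials\n",
    nrow(object@familiarization), nrow(object@immediate),
    nrow(object@repetition), nrow(object@test)))
  cat(sprintf("  sentence pool: %d ids; seed: %d\n",
    length(object@sentencePool), object@seed))
})

setMethod("show", "ResponseMatrix", function(object) {
  x <- object@correctness
  cat(sprintf("ResponseMatrix: %d persons x %d items, %.1f%% missing%s\n",
    nrow(x), ncol(x), 100 * mean(is.na(x)),
    if (length(object@rt)) ", with RTs" else ""))
  if (ncol(object@groups)) {
    cat("  groups:", paste(names(object@groups), collapse = ", "), "\n")
  }
})

setMethod("show", "IRTFit", function(object) {
  cat(sprintf("IRTFit [%s]: %d items, %d persons\n",
    object@model, object@nItems, object@nPersons))
  cat(sprintf("  loglik %.3f, npar %d, AIC %.2f, BIC %.2f\n",
    object@loglik, object@npar, object@AIC, object@BIC))
  cat(sprintf("  converged: %s (%d EM iterations, max change %.2e)\n",
    object@convergence$converged, object@convergence$iterations,
    object@convergence$maxChange))
  if (!object@convergence$converged)
    cat("  NOTE: not converged; estimates are provisional\n")
})

setMethod("show", "SelectionTrace", function(object) {
  cat(sprintf("SelectionTrace: %d -> %d items (%d eliminated%s)\n",
    length(object@initialItems), length(object@finalItems),
    nrow(object@log), if (object@aborted) ", ABORTED at guardrail" else ""))
  if (nrow(object@log)) {
    tab <- table(object@log$reason)
    cat("  reasons:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.na(object@switchStep))
    cat(sprintf("  2PL -> Rasch switch at step %d\n", object@switchStep))
})

setMethod("show", "ScoreReport", function(object) {
  p <- object@persons
  cat(sprintf("ScoreReport: %d persons, RT cutoff %g ms\n", nrow(p), object@rtCutoff))
  cat(sprintf("  mean proportion correct %.3f, overall omission rate %.3f\n",
    mean(p$proportion_correct, na.rm = TRUE),
    sum(p$n_omitted) / sum(p$n_trials)))
  if ("flag" %in% names(p)) {
    tab <- table(p$flag)
    cat("  flags:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
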