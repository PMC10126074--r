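# Stepwise, conformity-driven item selection: eliminate below-chance items,
# then — while the 2PL fits significantly better than the Rasch model —
# drop the item deviating most from a common discrimination under the 2PL;
# once the LR test turns non-significant, continue under the Rasch model
# dropping ill-fitting items until all retained items pass the fit bounds.
# Every elimination is logged with the statistic that triggered it, making
# the workflow an auditable algorithm rather than a judgment call.

#' Stepwise item selection
#'
#' Runs the elimination loop described above on a response matrix. The
#' "worst" item under the 2PL regime is chosen lexicographically: largest
#' absolute deviation of its discrimination from the Rasch-equivalent
#' common slope (the Rasch-estimated latent SD, which is the common
#' discrimination once mapped onto the 2PL's standard-normal-prior scale),
#' ties broken by the worse infit/outfit deviation. Under the Rasch regime
#' the worst item is the flagged item with the largest infit/outfit
#' deviation from 1. Deterministic given the responses and configuration.
#'
#' @param responses a [ResponseMatrix-class] or persons x items matrix.
#' @param alpha significance level of the 2PL-vs-Rasch LR test (default
#'   0.05).
#' @param fitBounds infit/outfit acceptance interval (default c(0.7, 1.3)).
#' @param minItems abort guardrail: stop (with a partial trace) rather than
#'   eliminate below this many retained items (default 10).
#' @param belowChance mean-accuracy threshold; items below it are removed
#'   first, over scored (non-omitted) trials only (default 1/3, the 3AFC
#'   chance level).
#' @param ... fit settings passed on (`nQuad`, `tol`, `maxit`).
#' @return a [SelectionTrace-class].
#' @export
stepwiseSelect <- function(responses, alpha = 0.05, fitBounds = c(0.7, 1.3),
                           minItems = 10L, belowChance = 1 / 3, ...) {
  X <- asCorrectness(responses)
  initial <- colnames(X)
  rem <- initial
  logRows <- list(); details <- list()
  step <- 0L; switchStep <- NA_integer_; aborted <- FALSE
  addLog <- function(item, reason, criterion, value, model) {
    step <<- step + 1L
    logRows[[length(logRows) + 1L]] <<- data.frame(
      step = step, item = item, reason = reason, criterion = criterion,
      value = value, model = model, stringsAsFactors = FALSE)
  }

  acc <- colMeans(X, na.rm = TRUE)
  for (it in rem[acc < belowChance]) {
    addLog(it, "below_chance", "mean_accuracy", unname(acc[it]), "none")
    rem <- setdiff(rem, it)
  }

  # 2PL regime: eliminate while the 2PL fits significantly better
  repeat {
    if (length(rem) <= minItems) { aborted <- TRUE; break }
    fr <- fitRasch(X[, rem, drop = FALSE], se = FALSE, ...)
    f2 <- fit2PL(X[, rem, drop = FALSE], se = FALSE, ...)
    lr <- lrTest(fr, f2)
    details[[length(details) + 1L]] <- list(
      stage = "2pl", step = step, nItems = length(rem),
      loglikRasch = fr@loglik, loglik2PL = f2@loglik,
      chisq = lr$chisq, df = lr$df, p = lr$p)
    if (lr$p >= alpha) { switchStep <- step; break }
    it2 <- itemParams(f2)
    fitStats <- itemFit(f2, X[, rem, drop = FALSE], bounds = fitBounds)
    commonSlope <- priorParams(fr)$sd
    aDev <- abs(it2$a - commonSlope)
    fDev <- pmax(abs(fitStats$infit - 1), abs(fitStats$outfit - 1))[match(it2$item, fitStats$item)]
    ord <- order(-aDev, -fDev, it2$item)
    worst <- it2$item[ord[1]]
    addLog(worst, "ill_fitting", "2pl_discrimination_deviation",
           aDev[ord[1]], "2pl")
    rem <- setdiff(rem, worst)
  }

  # Rasch regime: eliminate until all retained items pass the fit bounds
  while (!aborted) {
    fr <- fitRasch(X[, rem, drop = FALSE], se = FALSE, ...)
    fitStats <- itemFit(fr, X[, rem, drop = FALSE], bounds = fitBounds)
    details[[length(details) + 1L]] <- list(
      stage = "rasch", step = step, nItems = length(rem),
      loglikRasch = fr@loglik, nFlagged = sum(fitStats$flagged))
    if (!any(fitStats$flagged)) break
    if (length(rem) <= minItems) { aborted <- TRUE; break }
    dev <- pmax(abs(fitStats$infit - 1), abs(fitStats$outfit - 1))
    cand <- which(fitStats$flagged)
    ord <- cand[order(-dev[cand], fitStats$item[cand])]
    worst <- fitStats$item[ord[1]]
    addLog(worst, "ill_fitting", "infit_outfit_deviation", dev[ord[1]], "rasch")
    rem <- setdiff(rem, worst)
  }

  new("SelectionTrace",
      log = if (length(logRows)) do.call(rbind, logRows) else
        data.frame(step = integer(), item = character(), reason = character(),
                   criterion = character(), value = numeric(), model = character(),
                   stringsAsFactors = FALSE),
      initialItems = initial, finalItems = rem,
      switchStep = switchStep, aborted = aborted,
      details = details)
}

#' Screen retained items for differential item functioning
#'
#' Runs [difTest()] on the retained items for each grouping variable,
#' adjusts the per-item Wald p-values with Benjamini-Hochberg across items
#' within a grouping, and excludes items significant at the adjusted
#' level, logging each exclusion with reason `dif`.
#'
#' @param responses a [ResponseMatrix-class] carrying group labels.
#' @param trace a [SelectionTrace-class] from [stepwiseSelect()].
#' @param groupings character vector of grouping column names (e.g.
#'   `c("gender", "age_band")`).
#' @param alpha significance level applied to BH-adjusted p-values
#'   (default 0.05).
#' @param ... passed to [difTest()].
#' @return the updated [SelectionTrace-class]; DIF results are appended to
#'   its details.
#' @export
difScreen <- function(responses, trace, groupings, alpha = 0.05, ...) {
  if (!length(groupings)) stop("at least one grouping variable is required")
  gr <- personGroups(responses)
  if (is.null(gr)) stop("responses carry no group labels; grouping required for DIF")
  X <- asCorrectness(responses)
  rem <- finalItems(trace)
  logRows <- list()
  step <- if (nrow(selectionLog(trace))) max(selectionLog(trace)$step) else 0L
  for (gv in groupings) {
    if (!gv %in% names(gr)) stop("unknown grouping variable: ", gv)
    res <- difTest(X[, rem, drop = FALSE], gr[[gv]], ...)
    res$grouping <- gv
    padj <- p.adjust(res$items$p, method = "BH")
    bad <- res$items$item[padj < alpha]
    for (it in bad) {
      step <- step + 1L
      logRows[[length(logRows) + 1L]] <- data.frame(
        step = step, item = it, reason = "dif",
        criterion = sprintf("dif_%s_bh", gv),
        value = res$items$delta[res$items$item == it], model = "rasch",
        stringsAsFactors = FALSE)
      rem <- setdiff(rem, it)
    }
    trace@details[[length(trace@details) + 1L]] <- list(
      stage = "dif", grouping = gv, omnibus = res[c("chisq", "df", "p")],
      items = res$items, p_adjusted = padj)
  }
  if (length(logRows))
    trace@log <- rbind(trace@log, do.call(rbind, logRows))
  trace@finalItems <- rem
  validObject(trace)
  trace
}

#' Finalize a selection: refit, reliability, information, BIC adjudication
#'
#' Refits the Rasch model on the final item set, computes EAP abilities,
#' the empirical marginal reliability, the test information curve, item
#' fit, and compares the Rasch BIC against a 2PL fit on the same set (the
#' parsimony adjudication for the final model choice).
#'
#' @param responses a [ResponseMatrix-class] or matrix.
#' @param trace a [SelectionTrace-class].
#' @param ... fit settings passed on.
#' @return list with `fit`, `fit2pl`, `abilities`, `reliability`,
#'   `information`, `itemFit`, `bic` (named numerics plus `preferred`),
#'   `lr`, and the `trace`.
#' @export
finalizeSelection <- function(responses, trace, ...) {
  X <- asCorrectness(responses)[, finalItems(trace), drop = FALSE]
  fit <- fitRasch(X, ...)
  fit2 <- fit2PL(X, se = FALSE, ...)
  ab <- eapAbilities(fit, X)
  list(fit = fit,
       fit2pl = fit2,
       abilities = ab,
       reliability = empiricalReliability(ab),
       information = testInformation(fit),
       itemFit = itemFit(fit, X),
       bic = list(rasch = fit@BIC, twopl = fit2@BIC,
                  preferred = if (fit@BIC <= fit2@BIC) "rasch" else "2pl"),
       lr = lrTest(fit, fit2),
       trace = trace)
}
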