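#' Leave-one-out classification accuracy
#'
#' Each reference protein in turn is treated as the query: it is excluded
#' from the neighbor search by identity (never by distance, so duplicated
#' structures remain legitimate neighbors for each other) and classified
#' against all remaining references. Accuracy is averaged over all N
#' scenarios.
#'
#' @param db a [ReferenceDatabase-class].
#' @param k neighbors per query (k <= N - 1).
#' @param measure one of [distanceMeasures()].
#' @param p Minkowski exponent.
#' @param attributes optional attribute-index subset overriding the
#'   database's active attributes for this evaluation.
#' @return a [LooResult-class].
#' @export
looAccuracy <- function(db, k = 1L, measure = "manhattan", p = 2,
                        attributes = NULL) {
  stopifnot(methods::is(db, "ReferenceDatabase"))
  if (!is.null(attributes)) activeAttributes(db) <- attributes
  ids <- db@proteinIds
  pred <- character(length(ids))
  for (i in seq_along(ids)) {
    pr <- knnPredict(db@rawMatrix[i, ], db, k = k, measure = measure, p = p,
                     excludeIds = ids[i], queryId = ids[i])
    pred[i] <- pr@predictedClass
  }
  pp <- data.frame(proteinId = ids, trueClass = db@classLabels,
                   predictedClass = pred, stringsAsFactors = FALSE)
  methods::new("LooResult",
               accuracy = mean(pp$trueClass == pp$predictedClass),
               perProtein = pp, k = as.integer(k),
               distanceMeasure = measure)
}

#' Leave-one-out accuracy over a grid of k values and distance measures
#'
#' @param db a [ReferenceDatabase-class].
#' @param ks integer vector of neighbor counts.
#' @param measures character vector of distance measures.
#' @param p Minkowski exponent.
#' @return a data.frame with columns \code{k}, \code{measure},
#'   \code{accuracy}; one row per grid cell, deterministic.
#' @export
accuracySweep <- function(db, ks = 1:10, measures = distanceMeasures(),
                          p = 2) {
  grid <- expand.grid(k = as.integer(ks), measure = measures,
                      stringsAsFactors = FALSE)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    looAccuracy(db, k = grid$k[i], measure = grid$measure[i], p = p)@accuracy
  }, numeric(1))
  grid
}

#' Recursive feature elimination guided by leave-one-out accuracy
#'
#' Greedy backward elimination over the database's active attributes. At
#' each iteration the leave-one-out accuracy is evaluated with each single
#' remaining attribute removed; the attribute whose removal yields the
#' highest accuracy is eliminated (ties: the smallest attribute index).
#' Under the default \code{"non-strict"} stop rule pruning continues while
#' the best post-removal accuracy is at least the current accuracy (so
#' accuracy-neutral removals are taken, preferring smaller subsets) and
#' more than one attribute remains; \code{"strict"} stops at the first
#' removal that does not strictly improve accuracy.
#'
#' @param db a [ReferenceDatabase-class] with >= 2 active attributes.
#' @param k,measure,p classifier settings held fixed throughout.
#' @param stopRule \code{"non-strict"} (default) or \code{"strict"}.
#' @return an [RfeResult-class].
#' @export
rfeRank <- function(db, k = 1L, measure = "manhattan", p = 2,
                    stopRule = c("non-strict", "strict")) {
  stopifnot(methods::is(db, "ReferenceDatabase"))
  stopRule <- match.arg(stopRule)
  remaining <- sort(db@activeAttributes)
  if (length(remaining) < 2L)
    stop("recursive elimination needs at least two active attributes")
  baseline <- looAccuracy(db, k = k, measure = measure, p = p,
                          attributes = remaining)@accuracy
  current <- baseline
  removed <- integer(0)
  trace <- numeric(0)
  while (length(remaining) > 1L) {
    accs <- vapply(remaining, function(a) {
      looAccuracy(db, k = k, measure = measure, p = p,
                  attributes = setdiff(remaining, a))@accuracy
    }, numeric(1))
    bestAcc <- max(accs)
    keepGoing <- if (stopRule == "non-strict") bestAcc >= current
                 else bestAcc > current
    if (!keepGoing) break
    drop <- remaining[accs == bestAcc][1L]   # ties: smallest index
    remaining <- setdiff(remaining, drop)
    removed <- c(removed, drop)
    trace <- c(trace, bestAcc)
    current <- bestAcc
  }
  methods::new("RfeResult",
               eliminationOrder = removed,
               optimalSubset = remaining,
               accuracyTrace = trace,
               baselineAccuracy = baseline,
               k = as.integer(k),
               distanceMeasure = measure)
}

#' Score and rank attributes over a collection of RFE runs
#'
#' An attribute's score is the fraction of runs whose optimal subset
#' retained it (total count / number of experiments). Ranks are assigned by
#' descending score; tied attributes share the better rank.
#'
#' @param results list of [RfeResult-class] objects.
#' @param nAttributes total number of attributes scored (default 18).
#' @return data.frame with columns \code{attribute} (index), \code{name}
#'   (descriptor name when \code{nAttributes} is 18), \code{count},
#'   \code{score}, \code{rank}.
#' @export
attributeScore <- function(results, nAttributes = 18L) {
  if (!length(results)) stop("at least one RFE result is required")
  if (!all(vapply(results, methods::is, logical(1), "RfeResult")))
    stop("results must be a list of RfeResult objects")
  count <- integer(nAttributes)
  for (r in results) {
    idx <- r@optimalSubset
    count[idx] <- count[idx] + 1L
  }
  score <- count / length(results)
  out <- data.frame(
    attribute = seq_len(nAttributes),
    name = if (nAttributes == 18L) descriptorNames() else
      paste0("attr", seq_len(nAttributes)),
    count = count,
    score = score,
    rank = rank(-score, ties.method = "min")
  )
  out
}
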