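# Cell-cycle bookkeeping: stage durations from population frequencies,
# per-stage rates, and predicted vs observed BB counts.  Stage labels are
# morphological inputs (I--IV, staged by oral-apparatus development);
# nothing here is stochastic.

stageLevels <- c("I", "II", "III", "IV")

#' Stage durations from population frequencies
#'
#' In an asynchronous exponentially growing population the time spent in a
#' stage is its relative frequency times the population doubling time.
#'
#' @param stageCounts named numeric(4), cells observed per stage (I--IV).
#' @param doublingTime population doubling time (minutes).
#' @return named numeric(4) of durations (minutes); sums to
#'   \code{doublingTime}.
#' @export
stageDurations <- function(stageCounts, doublingTime) {
  stopifnot(doublingTime > 0, all(stageCounts >= 0))
  if (sum(stageCounts) == 0) stop("no cells staged")
  if (is.null(names(stageCounts))) names(stageCounts) <- stageLevels
  stageCounts / sum(stageCounts) * doublingTime
}

#' Per-stage rates of change
#'
#' The rate over a stage is the parameter change across that stage divided
#' by the stage duration; the whole-cycle rate is the total change over the
#' doubling time.  The baseline (time 0) value is by convention the mean of
#' the quartile of Stage I cells with fewest cortical BBs.
#'
#' @param values named numeric: baseline value followed by the value at the
#'   end of each stage, in stage order (length 5: baseline, I, II, III, IV).
#' @param durations named numeric(4) from \code{\link{stageDurations}} (or
#'   measured durations, minutes).
#' @return data.frame with per-stage change, duration, rate, and rounded
#'   rate (1 decimal, the reporting convention); the whole-cycle rate is
#'   attached as attribute \code{wholeCycle}.
#' @export
stageRates <- function(values, durations) {
  stopifnot(length(values) == 5L, length(durations) == 4L)
  if (any(durations <= 0)) stop("zero or negative stage duration")
  change <- diff(values)
  out <- data.frame(stage = stageLevels, change = as.numeric(change),
                    durationMin = as.numeric(durations),
                    rate = as.numeric(change / durations))
  out$rateRounded <- round(out$rate, 1L)
  attr(out, "wholeCycle") <- (values[5L] - values[1L]) / sum(durations)
  out
}

#' Predicted versus observed stage BB counts
#'
#' Division halves the Stage IV cortical complement; Stage I assembly then
#' adds the observed daughter count.  The discrepancy between that
#' prediction and the observed Stage I mean measures how far the
#' daughter-marker analysis undercounts new assembly.
#'
#' @param stageIVMean mean cortical BB count of Stage IV cells.
#' @param stageIDaughters mean daughter-BB count added during Stage I.
#' @param stageIObserved observed Stage I mean cortical BB count (optional;
#'   NA skips the discrepancy).
#' @return list: \code{postDivision} (halved Stage IV count),
#'   \code{predicted} (plus daughters), \code{discrepancy} (observed -
#'   predicted) and \code{discrepancyPct} (as % of observed).
#' @export
predictedCounts <- function(stageIVMean, stageIDaughters,
                            stageIObserved = NA_real_) {
  post <- stageIVMean / 2
  pred <- post + stageIDaughters
  list(postDivision = post, predicted = pred,
       discrepancy = stageIObserved - pred,
       discrepancyPct = 100 * (stageIObserved - pred) / stageIObserved)
}

#' Population daughter-BB fraction
#'
#' Per-cell fraction of cortical BBs called as daughters, and its
#' population mean.  Starved cells exit the cell cycle and should fall
#' below a few percent; a fraction of 1 is flagged as implausible.
#'
#' @param daughterCounts numeric, daughters per cell.
#' @param bbCounts numeric, cortical BBs per cell.
#' @return list: \code{perCell}, \code{meanFraction}, \code{flagged}.
#' @export
starvedNewBBFraction <- function(daughterCounts, bbCounts) {
  stopifnot(length(daughterCounts) == length(bbCounts), all(bbCounts > 0))
  f <- daughterCounts / bbCounts
  list(perCell = f, meanFraction = mean(f),
       flagged = any(f >= 1))
}

#' Per-stage summary from a cell table
#'
#' @param cells data.frame with columns \code{stage}, \code{bb_count},
#'   \code{surface_area}, \code{mean_spacing}, \code{daughter_count} (the
#'   per-cell CSV contract).
#' @return data.frame of per-stage n, means and sds.
#' @export
stageSummary <- function(cells) {
  stopifnot(all(c("stage", "bb_count") %in% names(cells)))
  do.call(rbind, lapply(stageLevels, function(s) {
    cs <- cells[cells$stage == s, , drop = FALSE]
    msd <- function(col) {
      if (!col %in% names(cs) || !nrow(cs)) return(c(NaN, NA))
      c(mean(cs[[col]]), if (nrow(cs) > 1) sd(cs[[col]]) else NA)
    }
    b <- msd("bb_count"); a <- msd("surface_area"); sp <- msd("mean_spacing")
    d <- msd("daughter_count")
    data.frame(stage = s, n = nrow(cs), meanBB = b[1], sdBB = b[2],
               meanAreaUm2 = a[1], sdAreaUm2 = a[2], meanSpacingUm = sp[1],
               sdSpacingUm = sp[2], meanDaughters = d[1])
  }))
}
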