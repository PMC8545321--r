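#' ROC analysis of CAR as a main-pair classifier
#'
#' Evaluates how well the CAR separates the main biotransformation pair of
#' a reaction from ancillary pairs (cofactor, leaving-group, ... pairs),
#' given a labelled pair set. For `nCutoffs` evenly spaced cutoffs
#' `c = 1/n, 2/n, ..., 1` a pair is predicted "main" when `car >= c`
#' (inclusive, so cutoff 0 would predict everything positive); true/false
#' positives, sensitivity, specificity and Youden's index
#' (sensitivity + specificity - 1) are tabulated per cutoff. The AUC is
#' the trapezoidal area under the (FPR, TPR) points augmented with (0,0)
#' and (1,1); the optimal cutoff is the smallest cutoff maximising
#' Youden's index.
#'
#' @param pairs data.frame with columns `car` (in `[0, 1]`) and `is_main`
#'   (logical or 0/1); typically read with [readLabeledPairs()] or generated
#'   by [makeLabeledPairs()]
#' @param nCutoffs number of cutoffs in the uniform grid on (0, 1]
#' @return a [RocTable-class]
#' @examples
#' lp <- makeLabeledPairs(nPos = 200, nNeg = 200, seed = 1)
#' roc <- rocAnalysis(lp)
#' aucValue(roc); optimalCutoff(roc)
#' @export
rocAnalysis <- function(pairs, nCutoffs = 100) {
  stopifnot(is.data.frame(pairs), all(c("car", "is_main") %in% names(pairs)),
            nCutoffs >= 2)
  car <- as.numeric(pairs$car)
  if (any(!is.finite(car)) || any(car < 0) || any(car > 1)) {
    stop("car values must lie in [0, 1]", call. = FALSE)
  }
  lab <- as.logical(pairs$is_main)
  nPos <- sum(lab)
  nNeg <- sum(!lab)
  if (nPos == 0L || nNeg == 0L) {
    stop("need at least one positive and one negative label; AUC is ",
         "undefined for single-class input", call. = FALSE)
  }
  cutoffs <- seq_len(nCutoffs) / nCutoffs
  tp <- vapply(cutoffs, function(c) sum(car >= c & lab), integer(1))
  fp <- vapply(cutoffs, function(c) sum(car >= c & !lab), integer(1))
  sens <- tp / nPos
  spec <- (nNeg - fp) / nNeg
  youden <- sens + spec - 1
  tb <- data.frame(cutoff = cutoffs, tp = tp, fp = fp,
                   sensitivity = sens, specificity = spec, youden = youden)
  fpr <- c(0, rev(fp / nNeg), 1)
  tpr <- c(0, rev(sens), 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  imax <- which(youden >= max(youden) - 1e-12)[1]
  methods::new("RocTable", table = tb, auc = auc,
               optimalCutoff = cutoffs[imax], youdenMax = youden[imax],
               nPositive = as.integer(nPos), nNegative = as.integer(nNeg))
}

#' Predict whether a pair is a main biotransformation
#'
#' Threshold classifier on the CAR: a pair is predicted "main" when its CAR
#' reaches the cutoff (inclusive). The default cutoff 0.34 maximises
#' Youden's index on the curated reference pair set.
#'
#' @param car numeric vector of CARs in `[0, 1]`
#' @param cutoff classification cutoff in `[0, 1]`
#' @return logical vector
#' @export
predictMain <- function(car, cutoff = 0.34) {
  stopifnot(all(car >= 0 & car <= 1), cutoff >= 0, cutoff <= 1)
  car >= cutoff
}
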