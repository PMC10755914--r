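#' Logistic-regression biomarker combination with ROC analysis
#'
#' Fits an unpenalized maximum-likelihood logistic regression of the binary
#' group label on one or more features (e.g. ROI gwBZ and/or gwBTV means,
#' K-MMSE, CDR), scores each subject with the predicted probability, and
#' evaluates classification by ROC analysis: AUC over all thresholds (the
#' trapezoid rule, equal to the Mann-Whitney statistic with tie correction),
#' sensitivity/specificity in percent at the Youden-J-maximizing threshold
#' (ties resolved to the lowest threshold), and a p-value against AUC = 0.5
#' from the DeLong variance.
#'
#' With a single feature the fitted probability is monotone in the feature,
#' so the AUC equals the raw-feature AUC. Under perfect separation the fit is
#' flagged but probabilities (and AUC = 1) are still returned.
#'
#' @param features numeric vector, matrix or data.frame of predictors.
#' @param labels binary group labels (factor, character or 0/1).
#' @param positive the label treated as case; default the second factor
#'   level.
#' @return list: `auc`, `sensitivity` and `specificity` (percent),
#'   `threshold` (on the probability scale), `p` (vs AUC = 0.5), `nCases`,
#'   `nControls`, `separation` (logical flag), `model` (the glm fit),
#'   `roc` (the underlying ROC object).
#' @export
logisticRoc <- function(features, labels, positive = NULL) {
  feat <- as.data.frame(features)
  stopifnot(nrow(feat) == length(labels))
  if (any(!vapply(feat, function(col) all(is.finite(col)), TRUE)))
    stop("features must be finite")
  y <- as.factor(labels)
  y <- droplevels(y)
  if (nlevels(y) != 2L) stop("labels must contain exactly two classes")
  if (!is.null(positive)) {
    stopifnot(positive %in% levels(y))
    y <- stats::relevel(y, ref = setdiff(levels(y), positive))
  }
  neg <- levels(y)[1]; pos <- levels(y)[2]

  separation <- FALSE
  df <- cbind(data.frame(.y = y), feat)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  prob <- stats::fitted(fit)
  # perfect separation: every case outranks every control in probability
  if (max(prob[y == neg]) < min(prob[y == pos])) separation <- TRUE

  roc <- pROC::roc(response = y, predictor = prob, levels = c(neg, pos),
                   direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  co <- pROC::coords(roc, x = "best", best.method = "youden",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  co <- co[order(co$threshold), , drop = FALSE][1, ]  # ties: lowest threshold

  v <- pROC::var(roc, method = "delong")
  p <- if (v > 0) 2 * stats::pnorm(-abs((auc - 0.5) / sqrt(v))) else 0

  list(auc = auc,
       sensitivity = 100 * co$sensitivity,
       specificity = 100 * co$specificity,
       threshold = co$threshold,
       p = p,
       nCases = sum(y == pos), nControls = sum(y == neg),
       separation = separation, model = fit, roc = roc)
}
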