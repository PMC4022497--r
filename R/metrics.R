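# Confusion-count bookkeeping and evaluation statistics: accuracy, Matthews
# correlation coefficient, auxiliary rates, the per-round report layout,
# and random sub-sampling validation of the training set.

#' Confusion counts for a binary FLIP/FunC classification
#'
#' Either pass the four counts directly, or `predicted` and `truth` label
#' vectors.  The positive class is FLIP: TP = FLIP predicted FLIP,
#' TN = FunC predicted FunC, FP = FunC predicted FLIP, FN = FLIP predicted
#' FunC.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @param predicted,truth Character vectors of `"FLIP"`/`"FunC"` (used when
#'   the counts are not given).
#' @param positive The positive-class label (default `"FLIP"`).
#' @return An object of class `ecr_confusion` (named list `tp`, `fp`, `fn`,
#'   `tn`).
#' @export
confusion_counts <- function(tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                             predicted = NULL, truth = NULL,
                             positive = "FLIP") {
  if (is.null(tp)) {
    stopifnot(!is.null(predicted), !is.null(truth),
              length(predicted) == length(truth))
    p <- predicted == positive
    t <- truth == positive
    tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_input("confusion counts must be non-negative numbers")
  }
  structure(as.list(as.numeric(counts)) |> stats::setNames(names(counts)),
            class = "ecr_confusion")
}

#' @export
print.ecr_confusion <- function(x, ...) {
  cat(sprintf("TP %g  FP %g  FN %g  TN %g  |  accuracy %s, MCC %.2f\n",
              x$tp, x$fp, x$fn, x$tn, fmt_pct(accuracy(x)),
              round_half_up(mcc(x), 2)))
  invisible(x)
}

.total <- function(c) c$tp + c$fp + c$fn + c$tn

#' Classification accuracy
#'
#' `ACC = (TP + TN) / (TP + FP + FN + TN)`, the propensity to correctly
#' identify FLIP or FunC.
#'
#' @param c An `ecr_confusion`.
#' @return A fraction in \[0, 1\].
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "ecr_confusion"))
  tot <- .total(c)
  if (tot == 0) stop_input("accuracy undefined for empty confusion counts")
  (c$tp + c$tn) / tot
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.  When any
#' factor of the denominator is zero the coefficient is defined as 0 (the
#' common convention for a degenerate margin).
#'
#' @param c An `ecr_confusion`.
#' @return A value in \[-1, 1\].
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "ecr_confusion"))
  if (.total(c) == 0) stop_input("MCC undefined for empty confusion counts")
  tp <- c$tp; fp <- c$fp; fn <- c$fn; tn <- c$tn
  f <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(f == 0)) return(0)
  (tp * tn - fp * fn) / sqrt(prod(f))
}

#' Auxiliary classification rates
#'
#' Precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and negative predictive value `TN/(TN+FN)`.  A rate whose
#' denominator is zero is returned as `NA` (undefined).
#'
#' @param c An `ecr_confusion`.
#' @return Named numeric vector `precision`, `sensitivity`, `specificity`,
#'   `npv`.
#' @export
auxiliary_rates <- function(c) {
  stopifnot(inherits(c, "ecr_confusion"))
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  c(precision = rate(c$tp, c$tp + c$fp),
    sensitivity = rate(c$tp, c$tp + c$fn),
    specificity = rate(c$tn, c$tn + c$fp),
    npv = rate(c$tn, c$tn + c$fn))
}

#' Per-round evaluation report
#'
#' Combines per-round confusion counts into the standard layout: one row
#' per clustering round plus a total row (round-1 counts plus the round-2
#' split of the remainder), each with accuracy and MCC.
#'
#' @param round1 `ecr_confusion` of the first clustering round (FLIP cluster
#'   vs rest).
#' @param round2 Optional `ecr_confusion` of the second round (computed on
#'   the interfaces left after removing the round-1 FLIP cluster).
#' @return A data frame of class `ecr_report` with columns `round`, `tp`,
#'   `fp`, `fn`, `tn`, `accuracy`, `mcc`.
#' @export
ecr_report <- function(round1, round2 = NULL) {
  stopifnot(inherits(round1, "ecr_confusion"))
  row_of <- function(name, c) {
    data.frame(round = name, tp = c$tp, fp = c$fp, fn = c$fn, tn = c$tn,
               accuracy = accuracy(c), mcc = mcc(c),
               stringsAsFactors = FALSE)
  }
  out <- row_of("1st clustering", round1)
  if (!is.null(round2)) {
    stopifnot(inherits(round2, "ecr_confusion"))
    out <- rbind(out, row_of("2nd clustering", round2))
    total <- confusion_counts(tp = round1$tp + round2$tp,
                              fp = round1$fp + round2$fp,
                              fn = round2$fn, tn = round2$tn)
    out <- rbind(out, row_of("Total", total))
  }
  class(out) <- c("ecr_report", "data.frame")
  out
}

#' @export
print.ecr_report <- function(x, ...) {
  cat(sprintf("%-16s %4s %4s %4s %4s  %9s  %5s\n",
              "", "TP", "FP", "FN", "TN", "Accuracy", "MCC"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-16s %4g %4g %4g %4g  %9s  %5.2f\n",
                x$round[i], x$tp[i], x$fp[i], x$fn[i], x$tn[i],
                fmt_pct(x$accuracy[i]), round_half_up(x$mcc[i], 2)))
  }
  invisible(x)
}

#' Random sub-sampling validation of the training set
#'
#' For each fraction and replicate, draws a simple random subset of the
#' labeled feature table (without replacement, no stratification), retrains
#' the two-round classifier, and records its overall training accuracy and
#' MCC.  Fraction 1.0 reproduces the full-training result exactly.
#'
#' @param x Labeled feature table (see [ecr_fit()]).
#' @param labels Optional labels; defaults to the table's `category` column.
#' @param fractions Subset fractions in `(0, 1]` (default `0.9` down to
#'   `0.2` in steps of `0.1`).
#' @param replicates Replicates per fraction (default 3).
#' @param seed Integer seed; every draw and refit is deterministic given it.
#' @param ... Passed on to [ecr_fit()].
#' @return A data frame with columns `fraction`, `replicate`, `n`,
#'   `accuracy`, `mcc`, `note`; failed refits (subset too small or
#'   degenerate) are recorded as `NA` with the reason in `note`.
#' @export
subsample_validation <- function(x, labels = NULL,
                                 fractions = seq(0.9, 0.2, by = -0.1),
                                 replicates = 3L, seed = 1L, ...) {
  fm <- as_feature_matrix(x)
  labels <- labels %||% fm$labels
  if (is.null(labels)) stop_input("sub-sampling validation needs labels")
  if (any(fractions <= 0 | fractions > 1)) {
    stop_input("fractions must lie in (0, 1]")
  }
  n <- nrow(fm$values)
  grid <- expand.grid(replicate = seq_len(replicates), fraction = fractions)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- grid$fraction[i]; r <- grid$replicate[i]
    m <- max(1L, round(f * n))
    idx <- sort(with_seed(seed + 1000L * i, sample.int(n, m)))
    df <- as.data.frame(fm$values[idx, , drop = FALSE])
    df$category <- labels[idx]
    res <- tryCatch({
      fit <- ecr_fit(df, seed = seed, ...)
      list(acc = accuracy(fit$confusion$total), mcc = mcc(fit$confusion$total),
           note = "")
    }, error = function(e) list(acc = NA_real_, mcc = NA_real_,
                                note = conditionMessage(e)))
    rows[[i]] <- data.frame(fraction = f, replicate = r, n = m,
                            accuracy = res$acc, mcc = res$mcc, note = res$note,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
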