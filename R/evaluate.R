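#' Score predicted junctions against a truth table
#'
#' A predicted junction is counted correct when a truth junction exists
#' whose two breakpoints lie within `tolerance` nt and whose
#' strand-reversing flag agrees; each truth junction may be matched at most
#' once (greedy nearest-first).  Recall is the fraction of (unique) truth
#' junction loci recovered; the false-positive rate divides the number of
#' wrong predictions by the number of predictions.
#'
#' @param predicted data.frame of predicted junctions (normalized
#'   breakpoints as produced by the pipeline).
#' @param truth data.frame of truth junctions (e.g. `$truth` from
#'   [simulate_isoforms()]); duplicate loci are collapsed.
#' @param tolerance breakpoint tolerance in nt (default 0 = exact).
#' @return an object of class `eval_report`: counts `n_truth`,
#'   `n_predicted`, `n_correct`, `n_wrong`, ratios `recall`, `fpr`,
#'   `precision`, and a per-class `breakdown` data.frame.
#' @export
match_junctions <- function(predicted, truth, tolerance = 0L) {
  pkey <- c("chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2", "class")
  stopifnot(all(pkey %in% names(predicted)), all(pkey %in% names(truth)))
  # unique truth loci
  tu <- truth[!duplicated(paste(truth$chrom1, truth$pos1, truth$chrom2,
                                truth$pos2, truth$strand1 != truth$strand2)),
              , drop = FALSE]
  n_truth <- nrow(tu)
  n_pred <- nrow(predicted)
  if (n_truth == 0L) {
    rep <- structure(list(n_truth = 0L, n_predicted = n_pred,
                          n_correct = 0L, n_wrong = n_pred,
                          recall = NA_real_,
                          fpr = if (n_pred) 1 else NA_real_,
                          precision = if (n_pred) 0 else NA_real_,
                          breakdown = NULL, matched_truth = logical(0),
                          correct_pred = logical(0)),
                     class = "eval_report")
    return(rep)
  }
  rev_t <- tu$strand1 != tu$strand2
  rev_p <- if (n_pred) predicted$strand1 != predicted$strand2 else logical(0)
  matched <- rep(FALSE, n_truth)
  correct <- rep(FALSE, n_pred)
  if (n_pred > 0L) {
    ord <- order(predicted$chrom1, predicted$pos1, predicted$chrom2,
                 predicted$pos2)
    for (p in ord) {
      cand <- which(!matched &
                      tu$chrom1 == predicted$chrom1[p] &
                      tu$chrom2 == predicted$chrom2[p] &
                      abs(tu$pos1 - predicted$pos1[p]) <= tolerance &
                      abs(tu$pos2 - predicted$pos2[p]) <= tolerance &
                      rev_t == rev_p[p])
      if (length(cand)) {
        d <- abs(tu$pos1[cand] - predicted$pos1[p]) +
          abs(tu$pos2[cand] - predicted$pos2[p])
        hit <- cand[which.min(d)]
        matched[hit] <- TRUE
        correct[p] <- TRUE
      }
    }
  }
  n_correct <- sum(matched)
  n_wrong <- n_pred - sum(correct)
  classes <- sort(unique(c(tu$class, predicted$class)))
  breakdown <- do.call(rbind, lapply(classes, function(cl) {
    ti <- tu$class == cl
    pi <- if (n_pred) predicted$class == cl else logical(0)
    data.frame(class = cl, n_truth = sum(ti), n_correct = sum(matched[ti]),
               recall = if (sum(ti)) sum(matched[ti]) / sum(ti) else NA_real_,
               n_predicted = sum(pi), n_wrong = sum(pi & !correct),
               stringsAsFactors = FALSE)
  }))
  structure(list(n_truth = n_truth, n_predicted = n_pred,
                 n_correct = n_correct, n_wrong = n_wrong,
                 recall = n_correct / n_truth,
                 fpr = if (n_pred) n_wrong / n_pred else NA_real_,
                 precision = if (n_pred) 1 - n_wrong / n_pred else NA_real_,
                 breakdown = breakdown, matched_truth = matched,
                 correct_pred = correct),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("junction evaluation\n")
  cat(sprintf("  truth: %d   predicted: %d   correct: %d   wrong: %d\n",
              x$n_truth, x$n_predicted, x$n_correct, x$n_wrong))
  cat(sprintf("  recall: %s   FPR: %s   precision: %s\n",
              fmt_pct(x$recall), fmt_pct(x$fpr), fmt_pct(x$precision)))
  if (!is.null(x$breakdown)) {
    cat("  per class:\n")
    for (i in seq_len(nrow(x$breakdown))) {
      b <- x$breakdown[i, ]
      cat(sprintf("    %-17s recall %s (%d/%d), predicted %d, wrong %d\n",
                  b$class, fmt_pct(b$recall), b$n_correct, b$n_truth,
                  b$n_predicted, b$n_wrong))
    }
  }
  invisible(x)
}

fmt_pct <- function(x) {
  if (is.na(x)) "n/a" else sprintf("%.1f%%", 100 * x)
}
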