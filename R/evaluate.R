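# Scoring in the DDI-challenge style: per-class precision/recall/F1 over
# the four interaction classes and their micro average.

#' Score predictions against gold labels
#'
#' Per-class true positives, false positives and false negatives over the
#' four interaction classes (`none` never contributes a TP), plus the
#' micro-averaged overall row obtained by pooling TP/FP/FN across the four
#' classes -- the DDIExtraction-2013 convention. A positive gold instance
#' that was filtered out before prediction (and therefore scored `none`)
#' lowers recall but never precision. Precision or recall with an empty
#' denominator is reported as 0 and flagged.
#'
#' @param gold Gold standard: a `ddi_dataset` (all instances, filtered ones
#'   included), a list of `ddi_instance`, or a data frame with `pair_id`
#'   and `label`.
#' @param predicted Predictions: the data frame from [predict.ddi_cnn()],
#'   or any data frame with `pair_id` and `predicted`. Instances absent
#'   from `predicted` are scored as predicted `"none"`; a prediction whose
#'   `pair_id` is unknown to the gold set is an error.
#' @return Object of class `ddi_eval`: a data frame with one row per
#'   interaction class plus `overall`; columns `class`, `TP`, `FP`, `FN`,
#'   `precision`, `recall`, `f1` (proportions in `[0, 1]`) and
#'   `zero_division`.
#' @export
ddi_score <- function(gold, predicted) {
  if (inherits(gold, "ddi_dataset")) gold <- gold$instances
  if (is.list(gold) && !is.data.frame(gold))
    gold <- data.frame(
      pair_id = vapply(gold, `[[`, "", "pair_id"),
      label = vapply(gold, `[[`, "", "label"),
      stringsAsFactors = FALSE)
  stopifnot(all(c("pair_id", "label") %in% names(gold)))
  check_labels(gold$label)
  if (anyDuplicated(gold$pair_id))
    stop("duplicate pair id(s) in gold standard")
  if (!is.data.frame(predicted))
    stop("'predicted' must be a data frame with pair_id and predicted")
  stopifnot(all(c("pair_id", "predicted") %in% names(predicted)))
  unknown <- setdiff(predicted$pair_id, gold$pair_id)
  if (length(unknown))
    stop("prediction(s) for unknown instance id: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  pred <- predicted$predicted[match(gold$pair_id, predicted$pair_id)]
  pred[is.na(pred)] <- "none"  # unpredicted (e.g. filtered) -> negative
  check_labels(pred)

  pos <- setdiff(DDI_CLASSES, "none")
  per <- lapply(pos, function(cl) {
    tp <- sum(gold$label == cl & pred == cl)
    fp <- sum(pred == cl & gold$label != cl)
    fn <- sum(gold$label == cl & pred != cl)
    c(TP = tp, FP = fp, FN = fn)
  })
  tab <- as.data.frame(do.call(rbind, per))
  tab <- rbind(tab, colSums(tab))
  tab$class <- c(pos, "overall")
  prf <- function(tp, fp, fn) {
    zd <- FALSE
    p <- if (tp + fp > 0) tp / (tp + fp) else {zd <- TRUE; 0}
    r <- if (tp + fn > 0) tp / (tp + fn) else {zd <- TRUE; 0}
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    list(p = p, r = r, f = f, zd = zd)
  }
  m <- Map(prf, tab$TP, tab$FP, tab$FN)
  tab$precision <- vapply(m, `[[`, 0, "p")
  tab$recall <- vapply(m, `[[`, 0, "r")
  tab$f1 <- vapply(m, `[[`, 0, "f")
  tab$zero_division <- vapply(m, `[[`, TRUE, "zd")
  tab <- tab[, c("class", "TP", "FP", "FN", "precision", "recall", "f1",
                 "zero_division")]
  class(tab) <- c("ddi_eval", "data.frame")
  tab
}

#' @export
print.ddi_eval <- function(x, ...) {
  cat("DDI classification report (micro-averaged overall)\n")
  fmt <- data.frame(
    Class = x$class,
    P = sprintf("%.2f%%", 100 * x$precision),
    R = sprintf("%.2f%%", 100 * x$recall),
    F1 = sprintf("%.2f%%", 100 * x$f1))
  print(fmt, row.names = FALSE)
  if (any(x$zero_division))
    cat("note: empty denominator reported as 0 for: ",
        paste(x$class[x$zero_division], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Rows: the four interaction classes then `Overall`; columns P, R, F1 as
#' percentages with two decimals.
#'
#' @param report A `ddi_eval` from [ddi_score()].
#' @param path File path.
#' @export
write_ddi_eval <- function(report, path) {
  stopifnot(inherits(report, "ddi_eval"))
  out <- data.frame(
    Class = report$class,
    P = sprintf("%.2f", 100 * report$precision),
    R = sprintf("%.2f", 100 * report$recall),
    F1 = sprintf("%.2f", 100 * report$f1))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}
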