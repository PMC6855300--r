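#' Consensus labels from a rater pair
#'
#' Builds the ground truth used to evaluate automatic labeling. A frame is
#' *valid* when both raters assigned it a (non-absent) label; it enters the
#' consensus when, additionally, the two labels agree. Frames the raters
#' disagreed on, and frames either rater could not label (no face, too
#' blurry), are discarded.
#'
#' @param annotations Annotation tibble (`frame_id`, `rater_id`, `label`),
#'   labels canonical or `NA`; see [read_annotations()].
#' @param raters Character vector of exactly two rater ids, both present in
#'   `annotations`.
#' @return Tibble `frame_id`, `label` (the agreed label), sorted by
#'   `frame_id`, with attribute `counts`: a list `total` (distinct frames
#'   seen by either rater), `valid`, `agreed`.
#' @export
#' @examples
#' ann <- tibble::tibble(
#'   frame_id = rep(c("f1", "f2", "f3"), each = 2),
#'   rater_id = rep(c("r1", "r2"), 3),
#'   label = c("happy", "happy", "happy", "neutral", "happy", NA)
#' )
#' cons <- consensus_labels(ann, c("r1", "r2"))
#' attr(cons, "counts")
consensus_labels <- function(annotations, raters) {
  pairs <- rater_pairs(annotations, raters)
  valid <- !is.na(pairs$label_1) & !is.na(pairs$label_2)
  agreed <- valid & pairs$label_1 == pairs$label_2
  out <- tibble::tibble(frame_id = pairs$frame_id[agreed],
                        label = pairs$label_1[agreed])
  out <- dplyr::arrange(out, .data$frame_id)
  attr(out, "counts") <- list(total = nrow(pairs), valid = sum(valid),
                              agreed = sum(agreed))
  out
}

rater_pairs <- function(annotations, raters) {
  if (length(raters) != 2L) {
    stop("exactly two rater ids are supported", call. = FALSE)
  }
  missing <- setdiff(raters, unique(annotations$rater_id))
  if (length(missing)) {
    stop("rater id(s) absent from annotations: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  a1 <- dplyr::filter(annotations, .data$rater_id == raters[[1]])
  a2 <- dplyr::filter(annotations, .data$rater_id == raters[[2]])
  dplyr::full_join(
    dplyr::select(a1, "frame_id", label_1 = "label"),
    dplyr::select(a2, "frame_id", label_2 = "label"),
    by = "frame_id")
}

#' Inter-rater confusion matrix
#'
#' Cross-tabulates the two raters' labels over *valid* frames only (frames
#' both raters labeled). Rows are rater 1, columns rater 2, in the fixed
#' canonical label order.
#'
#' @inheritParams consensus_labels
#' @return Square integer matrix with dimnames over [emotion_levels()].
#' @export
confusion_matrix <- function(annotations, raters) {
  pairs <- rater_pairs(annotations, raters)
  pairs <- dplyr::filter(pairs, !is.na(.data$label_1), !is.na(.data$label_2))
  if (nrow(pairs) == 0L) {
    stop("no valid frames: the raters never both labeled a frame", call. = FALSE)
  }
  lv <- emotion_levels()
  m <- table(factor(pairs$label_1, levels = lv),
             factor(pairs$label_2, levels = lv))
  m <- unclass(m)
  dimnames(m) <- list(rater_1 = lv, rater_2 = lv)
  storage.mode(m) <- "integer"
  m
}

#' Percent agreement of a confusion matrix
#'
#' `100 * trace / total`: the share of valid frames both raters assigned
#' the same label.
#'
#' @param m Square numeric confusion matrix (any label set).
#' @return Percentage in \[0, 100\] (unrounded).
#' @export
percent_agreement <- function(m) {
  m <- as_confusion(m)
  100 * sum(diag(m)) / sum(m)
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected inter-rater agreement:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace/total` and chance agreement
#' `p_e = sum_i row_i * col_i / total^2`. When both raters use a single
#' label on every frame (`p_e = 1`), agreement is perfect and kappa is
#' defined as 1.
#'
#' @param m Square numeric confusion matrix.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(m) {
  m <- as_confusion(m)
  total <- sum(m)
  p_o <- sum(diag(m)) / total
  p_e <- sum(rowSums(m) * colSums(m)) / total^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    return(if (p_o >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

as_confusion <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square", call. = FALSE)
  if (any(m < 0)) stop("confusion matrix entries must be >= 0", call. = FALSE)
  if (sum(m) == 0) stop("confusion matrix is empty", call. = FALSE)
  m
}

#' Inter-rater reliability of an annotation pair
#'
#' Convenience fit object bundling the confusion matrix, the frame counts,
#' percent agreement and Cohen's kappa for one rater pair. Supports
#' [generics::tidy()] (long confusion counts), [generics::glance()]
#' (one-row summary) and [ggplot2::autoplot()] (heatmap).
#'
#' @inheritParams consensus_labels
#' @return Object of class `rater_reliability`.
#' @export
rater_reliability <- function(annotations, raters) {
  m <- confusion_matrix(annotations, raters)
  cons <- consensus_labels(annotations, raters)
  structure(
    list(matrix = m, raters = raters, counts = attr(cons, "counts"),
         percent_agreement = percent_agreement(m),
         kappa = cohens_kappa(m)),
    class = "rater_reliability")
}

#' @export
print.rater_reliability <- function(x, ...) {
  cat("Inter-rater reliability (", x$raters[[1]], " vs ", x$raters[[2]], ")\n",
      sep = "")
  cat(sprintf("  frames: %d total, %d valid, %d agreed\n",
              x$counts$total, x$counts$valid, x$counts$agreed))
  cat(sprintf("  percent agreement: %.1f%%\n", x$percent_agreement))
  cat(sprintf("  Cohen's kappa: %.3f\n", x$kappa))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy rater_reliability
#' @export
tidy.rater_reliability <- function(x, ...) {
  as.data.frame(as.table(x$matrix), stringsAsFactors = FALSE) |>
    stats::setNames(c("rater_1", "rater_2", "n")) |>
    tibble::as_tibble()
}

#' @method glance rater_reliability
#' @export
glance.rater_reliability <- function(x, ...) {
  tibble::tibble(
    total = x$counts$total, valid = x$counts$valid, agreed = x$counts$agreed,
    percent_agreement = x$percent_agreement, kappa = x$kappa)
}

#' @method autoplot rater_reliability
#' @export
autoplot.rater_reliability <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rater_2, y = .data$rater_1,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "rater 2", y = "rater 1", fill = "frames",
                  title = "Inter-rater confusion matrix") +
    ggplot2::theme_minimal()
}
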