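#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted word learner
#'
#' Returns the word-object matrix in long form, one row per
#' (object, word) cell, with the row-normalized value alongside.
#'
#' @param x An `xsit_fit`.
#' @param ... Unused.
#' @return A tibble with columns `object`, `word`, `value`, `normalized`.
#' @method tidy xsit_fit
#' @export
tidy.xsit_fit <- function(x, ...) {
  qw <- qw_matrix(x)
  nqw <- normalize_qw(qw)
  tibble::tibble(
    object = rep(rownames(qw), times = ncol(qw)),
    word = rep(colnames(qw), each = nrow(qw)),
    value = as.vector(qw),
    normalized = as.vector(nqw)
  )
}

#' Glance at a fitted word learner
#'
#' @param x An `xsit_fit`.
#' @param ... Unused.
#' @return A one-row tibble summarizing the run: algorithm, corpus and
#'   vocabulary sizes, episodes, and mean episode reward over the first and
#'   last deciles of training.
#' @method glance xsit_fit
#' @export
glance.xsit_fit <- function(x, ...) {
  hist <- x$reward_history
  decile <- max(1L, floor(length(hist) / 10))
  tibble::tibble(
    algorithm = x$algorithm,
    encoding = if (!is.null(x$encoding)) x$encoding else NA_character_,
    n_objects = nrow(qw_matrix(x)),
    n_words = ncol(qw_matrix(x)),
    episodes = length(hist),
    reward_first_decile = if (length(hist)) mean(utils::head(hist, decile)) else NA_real_,
    reward_last_decile = if (length(hist)) mean(utils::tail(hist, decile)) else NA_real_
  )
}

#' @export
print.xsit_fit <- function(x, ...) {
  qw <- qw_matrix(x)
  cat(
    "<xsit_fit> ", x$algorithm,
    if (!is.null(x$encoding)) paste0(" (", x$encoding, " encoding)") else "",
    ": ", nrow(qw), " objects x ", ncol(qw), " words, ",
    length(x$reward_history), " episodes\n",
    sep = ""
  )
  if (length(x$reward_history) > 0) {
    cat(
      "  episode reward: first = ", format(x$reward_history[[1]]),
      ", last = ", format(x$reward_history[[length(x$reward_history)]]), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Plot the per-episode reward history of a fit
#'
#' @param object An `xsit_fit` with a reward history.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot xsit_fit
#' @export
autoplot.xsit_fit <- function(object, ...) {
  df <- tibble::tibble(
    episode = seq_along(object$reward_history),
    reward = object$reward_history
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$episode, y = .data$reward)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "episode", y = "total reward",
      title = paste0("Episode reward (", object$algorithm, ")")
    )
}

#' Plot a precision/recall/F threshold sweep
#'
#' @param object An `xsit_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object; the best-F threshold is marked.
#' @method autoplot xsit_sweep
#' @export
autoplot.xsit_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("threshold", "precision", "recall", "f_score")],
    cols = c("precision", "recall", "f_score"),
    names_to = "measure", values_to = "value"
  )
  best <- best_scores(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$threshold, y = .data$value,
    colour = .data$measure
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = best$threshold, linetype = "dashed") +
    ggplot2::labs(x = "lexicon threshold", y = NULL, colour = NULL)
}

#' Heatmap of a gold-word confusion matrix
#'
#' @param cm A matrix from [confusion_matrix()].
#' @return A ggplot tile plot, gold words on the y axis, objects on x.
#' @export
plot_confusion <- function(cm) {
  df <- tibble::tibble(
    word = rep(rownames(cm), times = ncol(cm)),
    object = rep(colnames(cm), each = nrow(cm)),
    value = as.vector(cm)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$object, y = .data$word,
    fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "normalized Q")
}

#' @importFrom rlang .data
NULL
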