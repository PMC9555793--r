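#' Categorical Naive Bayes baseline
#'
#' A baseline classifier for the TRT category: class priors are the observed
#' class proportions and each attribute contributes a conditional frequency
#' table with additive (Laplace) smoothing. Fitting is delegated to
#' [e1071::naiveBayes()]; this wrapper fixes the attribute/level bookkeeping
#' and the tie-breaking conventions used throughout the package.
#'
#' @param table Data frame of categorical/discretized attributes.
#' @param target_attr Name of the class column.
#' @param smoothing Additive pseudo-count (default 1).
#' @return A model of class `trt_nb`.
#' @export
fit_naive_bayes <- function(table, target_attr = "Cat", smoothing = 1) {
  if (!target_attr %in% names(table)) stop("unknown target attribute: ", target_attr)
  attrs <- setdiff(names(table), target_attr)
  if (!length(attrs)) stop("no predictor attributes")
  x <- table[attrs]
  x[] <- lapply(x, function(col) factor(as.character(col)))
  classes <- sort(unique(as.character(table[[target_attr]])))
  y <- factor(as.character(table[[target_attr]]), levels = classes)
  fit <- e1071::naiveBayes(x, y, laplace = smoothing)
  structure(list(fit = fit, attrs = attrs,
                 levels = lapply(x, levels), classes = classes,
                 smoothing = smoothing),
            class = "trt_nb")
}

#' @rdname fit_naive_bayes
#' @param model A fitted `trt_nb`.
#' @param case Named list or one-row data frame of attribute values; unknown
#'   attributes and unseen levels are ignored (treated as missing), never an
#'   error.
#' @return `predict_category()` returns a list with `category` (argmax of
#'   the posterior, ties broken by class order), `posterior` (named, sums to
#'   1) and `prior_only` (TRUE when no known attribute informed the
#'   prediction).
#' @export
predict_category <- function(model, case) {
  stopifnot(inherits(model, "trt_nb"))
  newdata <- as.data.frame(
    lapply(model$attrs, function(a) {
      v <- if (a %in% names(case)) as.character(case[[a]]) else NA_character_
      if (length(v) != 1 || is.na(v) || !v %in% model$levels[[a]]) v <- NA_character_
      factor(v, levels = model$levels[[a]])
    }),
    col.names = model$attrs, stringsAsFactors = FALSE)
  informative <- !vapply(newdata, function(col) is.na(col[1]), logical(1))
  if (length(model$classes) == 1) {
    post <- stats::setNames(1, model$classes)
    return(list(category = model$classes, posterior = post,
                prior_only = !any(informative)))
  }
  if (any(informative)) {
    post <- stats::predict(model$fit, newdata, type = "raw")[1, ]
  } else {
    prior <- model$fit$apriori
    post <- as.numeric(prior) / sum(prior)
    names(post) <- names(prior)
  }
  post <- post[model$classes]
  post <- post / sum(post)
  best <- model$classes[which.max(post)]   # which.max: first max = class order
  list(category = best, posterior = post, prior_only = !any(informative))
}
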