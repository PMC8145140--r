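#' Exact Jenks natural breaks
#'
#' Finds the `k`-class partition of a numeric vector that minimises the
#' total within-class sum of squared deviations, by exact dynamic
#' programming over the sorted values (the Fisher optimal-partition
#' algorithm). Unlike heuristic reallocation variants, the result is
#' deterministic and globally optimal; ties are broken toward the earliest
#' feasible boundary.
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of classes (`>= 2`).
#' @return Numeric vector of `k - 1` class boundaries, strictly increasing.
#'   Each boundary is the largest value of its class, so classification uses
#'   `value <= boundary`.
#' @examples
#' jenks_breaks(c(1, 2, 10, 11), k = 2) # 2: splits {1,2} from {10,11}
#' @export
jenks_breaks <- function(values, k) {
  if (!is.numeric(values) || anyNA(values)) {
    abort("`values` must be numeric and non-missing.",
          class = "hotspotr_classification_error")
  }
  if (!is.numeric(k) || length(k) != 1 || k < 2) {
    abort("`k` must be a single integer >= 2.",
          class = "hotspotr_classification_error")
  }
  k <- as.integer(k)
  s <- sort(values)
  n <- length(s)
  if (length(unique(s)) < k) {
    abort("fewer distinct values than classes.",
          class = "hotspotr_classification_error")
  }
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  sse <- function(i, j) { # within-class SSE of s[i..j]
    len <- j - i + 1
    su <- cs[j] - if (i > 1) cs[i - 1] else 0
    sq <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    max(0, sq - su^2 / len)
  }
  cost <- matrix(Inf, n, k)
  back <- matrix(0L, n, k)
  for (j in seq_len(n)) cost[j, 1] <- sse(1, j)
  for (cls in 2:k) {
    for (j in cls:n) {
      for (t in (cls - 1):(j - 1)) {
        v <- cost[t, cls - 1] + sse(t + 1, j)
        if (v < cost[j, cls] - 1e-12) {
          cost[j, cls] <- v
          back[j, cls] <- t
        }
      }
    }
  }
  bounds <- integer(k - 1)
  j <- n
  for (cls in k:2) {
    j <- back[j, cls]
    bounds[cls - 1] <- j
  }
  s[bounds]
}

#' Reliability classification schemes
#'
#' A classification scheme maps reliability values in `[0, 1]` to ordered
#' class labels. Two methods are provided:
#' * `"fixed"` — the three-class scheme with thresholds 0.45 and 0.6:
#'   Low is `[0, 0.45)`, Mean is `[0.45, 0.6]`, High is `(0.6, 1]`.
#' * `"jenks"` — boundaries computed from data with [jenks_breaks()];
#'   classes are right-closed (`value <= boundary` falls in the lower
#'   class).
#'
#' @param method `"fixed"` or `"jenks"`.
#' @param values Numeric vector the Jenks boundaries are estimated from
#'   (required for `method = "jenks"`).
#' @param k Number of classes for `method = "jenks"`.
#' @param labels Ordered class labels, lowest class first. Length must be
#'   one more than the number of boundaries.
#' @return An object of class `"reliability_scheme"`: list with `method`,
#'   `breaks`, `labels` and `right` (for each boundary, whether a value
#'   equal to it belongs to the lower class).
#' @examples
#' reliability_scheme()
#' reliability_scheme("jenks", values = naples_hotspots()$reliability)
#' @export
reliability_scheme <- function(method = c("fixed", "jenks"), values = NULL,
                               k = 3, labels = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    labels <- labels %||% c("Low", "Mean", "High")
    if (length(labels) != 3) {
      abort("the fixed scheme has exactly 3 classes.",
            class = "hotspotr_classification_error")
    }
    breaks <- c(0.45, 0.6)
    right <- c(FALSE, TRUE) # 0.45 -> Mean, 0.6 -> Mean
  } else {
    if (is.null(values)) {
      abort("`values` are required for a Jenks scheme.",
            class = "hotspotr_classification_error")
    }
    breaks <- jenks_breaks(values, k)
    labels <- labels %||% if (k == 3) c("Low", "Mean", "High") else
      paste0("class", seq_len(k))
    if (length(labels) != length(breaks) + 1) {
      abort("`labels` must have one more element than there are breaks.",
            class = "hotspotr_classification_error")
    }
    right <- rep(TRUE, length(breaks))
  }
  structure(list(method = method, breaks = breaks, labels = labels,
                 right = right),
            class = "reliability_scheme")
}

#' @export
print.reliability_scheme <- function(x, ...) {
  cat(sprintf("reliability scheme (%s): %s\n", x$method,
              paste(x$labels, collapse = " < ")))
  cat("  boundaries:", paste(signif(x$breaks, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Classify hotspot reliabilities
#'
#' `classify_reliability()` adds an ordered `reliability_class` factor
#' column to a hotspot report (any data frame with a `reliability` column);
#' `reliability_class()` is the underlying vector version.
#'
#' @param data Data frame with a `reliability` column in `[0, 1]`.
#' @param scheme A [reliability_scheme()]. The default is the fixed
#'   0.45/0.6 Low/Mean/High scheme.
#' @param x Numeric vector of reliabilities in `[0, 1]`.
#' @return `classify_reliability()`: `data` with a `reliability_class`
#'   column appended; `reliability_class()`: an ordered factor.
#' @examples
#' reliability_class(c(0.41, 0.57, 0.69))
#' classify_reliability(naples_hotspots())
#' @export
classify_reliability <- function(data, scheme = reliability_scheme()) {
  if (!is.data.frame(data) || !"reliability" %in% names(data)) {
    abort("`data` must contain a `reliability` column.",
          class = "hotspotr_input_error")
  }
  dplyr::mutate(
    data,
    reliability_class = reliability_class(.data$reliability, scheme)
  )
}

#' @rdname classify_reliability
#' @export
reliability_class <- function(x, scheme = reliability_scheme()) {
  x <- check_unit_interval(x, "reliability values")
  if (!inherits(scheme, "reliability_scheme")) {
    abort("`scheme` must be a reliability_scheme().",
          class = "hotspotr_input_error")
  }
  idx <- vapply(x, function(v) {
    i <- 1L
    for (b in seq_along(scheme$breaks)) {
      above <- if (scheme$right[b]) v > scheme$breaks[b] else
        v >= scheme$breaks[b]
      if (above) i <- b + 1L
    }
    i
  }, integer(1))
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

#' Agreement between two label vectors
#'
#' Cross-tabulates predicted against reference class labels (for example
#' the fixed-scheme classes against an expert panel's evaluation) and
#' counts the exact agreements on the diagonal.
#'
#' @param predicted,reference Equal-length vectors of class labels.
#' @param levels Label order for the table; defaults to the sorted union
#'   (with `Low`, `Mean`, `High` recognised and kept in that order).
#' @return A list of class `"agreement_table"`: `table` (contingency
#'   table), `agreement` (diagonal count), `n`.
#' @examples
#' ref <- naples_expert_labels()
#' agreement_table(ref$reliability_class, ref$expert_class)
#' @export
agreement_table <- function(predicted, reference, levels = NULL) {
  if (length(predicted) != length(reference)) {
    abort("`predicted` and `reference` must have the same length.",
          class = "hotspotr_input_error")
  }
  predicted <- as.character(predicted)
  reference <- as.character(reference)
  if (is.null(levels)) {
    lv <- union(predicted, reference)
    std <- c("Low", "Mean", "High")
    levels <- if (all(lv %in% std)) std[std %in% lv] else sort(lv)
  }
  tb <- table(predicted = factor(predicted, levels = levels),
              reference = factor(reference, levels = levels))
  structure(list(table = tb, agreement = sum(diag(tb)),
                 n = length(predicted)),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  print(x$table)
  cat(sprintf("agreement: %d / %d (%.1f%%)\n", x$agreement, x$n,
              100 * x$agreement / x$n))
  invisible(x)
}
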