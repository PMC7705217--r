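#' Define a questionnaire scale
#'
#' A `scale_definition` carries the metadata needed to score an instrument
#' and compute its reliability: number of items, the response range shared by
#' all items, whether items are dichotomous (0/1), optional named subscales
#' (1-based item indices), and an optional set of reverse-keyed items.
#'
#' @param name short identifier, e.g. `"pswq"`.
#' @param n_items positive integer number of items.
#' @param item_min,item_max integer bounds of the response options;
#'   `item_min < item_max`.
#' @param dichotomous logical; if `TRUE`, responses must be 0/1.
#' @param subscales named list of integer vectors of 1-based item indices.
#' @param reverse_items integer vector of 1-based indices of reverse-keyed
#'   items; a reversed response `x` is scored as `item_min + item_max - x`.
#'   Defaults to none.
#' @param reference_window free-text recall window, e.g. `"last 4 weeks"`.
#' @return an object of class `scale_definition`.
#' @seealso [default_scale_registry()], [score_scale()]
#' @export
scale_definition <- function(name, n_items, item_min, item_max,
                             dichotomous = FALSE, subscales = list(),
                             reverse_items = integer(0),
                             reference_window = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  assert_number(n_items, "n_items", lower = 1)
  assert_number(item_min, "item_min")
  assert_number(item_max, "item_max")
  assert_flag(dichotomous, "dichotomous")
  if (item_min >= item_max) stop("item_min must be < item_max", call. = FALSE)
  if (dichotomous && !(item_min == 0 && item_max == 1)) {
    stop("a dichotomous scale must have item_min = 0 and item_max = 1",
         call. = FALSE)
  }
  if (length(subscales)) {
    if (is.null(names(subscales)) || any(!nzchar(names(subscales)))) {
      stop("subscales must be a named list", call. = FALSE)
    }
    for (nm in names(subscales)) {
      idx <- subscales[[nm]]
      if (!length(idx) || any(idx < 1 | idx > n_items | idx != floor(idx))) {
        stop(sprintf("subscale '%s' has item indices outside 1..%d", nm, n_items),
             call. = FALSE)
      }
    }
  }
  if (length(reverse_items) &&
      any(reverse_items < 1 | reverse_items > n_items)) {
    stop("reverse_items outside 1..n_items", call. = FALSE)
  }
  structure(
    list(name = name, n_items = as.integer(n_items),
         item_min = as.integer(item_min), item_max = as.integer(item_max),
         dichotomous = dichotomous, subscales = subscales,
         reverse_items = as.integer(reverse_items),
         reference_window = reference_window),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items, range %d-%d%s\n",
              x$name, x$n_items, x$item_min, x$item_max,
              if (x$dichotomous) " (dichotomous)" else ""))
  if (length(x$subscales)) {
    cat("  subscales:", paste(sprintf("%s[%d]", names(x$subscales),
                                      lengths(x$subscales)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default instrument registry
#'
#' Ships the shapes of the instruments used in the pre/post change survey:
#' item counts, response ranges, dichotomous coding and subscale structure.
#' Subscale item indices are positional within each instrument's item block
#' as administered (item wordings are out of scope).  No default scale
#' applies reverse scoring.
#'
#' Instruments: FKS (body dysmorphic symptoms, 18 items 0-4), CAHSA
#' (hallucination spectrum, 9 items 0-10), DASS-D (depression, 7 items 0-3),
#' EDE-Q (eating pathology, 22 items 0-6 with restraint / eating-concern /
#' shape-concern / weight-concern subscales), PHQ panic module (15
#' dichotomous items with an 11-item physical-symptom severity subscale),
#' PHQ stress subscale (10 items 0-2), PSWQ (worry, 16 items 1-5), SIAS and
#' SPS (social anxiety, 20 items 0-4 each), WI (illness anxiety, 14
#' dichotomous items), Y-BOCS symptom checklist (10 items 0-4 with
#' obsession and compulsion subscales).
#'
#' @return named list of [scale_definition()] objects.
#' @export
default_scale_registry <- function() {
  defs <- list(
    scale_definition("fks", 18, 0, 4, reference_window = "last week"),
    scale_definition("cahsa", 9, 0, 10, reference_window = "last 4 weeks"),
    scale_definition("dass_d", 7, 0, 3, reference_window = "past week"),
    scale_definition("edeq", 22, 0, 6,
                     subscales = list(restraint = 1:5, eating_concern = 6:10,
                                      shape_concern = 11:18, weight_concern = 19:22),
                     reference_window = "past 28 days"),
    scale_definition("phq_panic", 15, 0, 1, dichotomous = TRUE,
                     subscales = list(severity = 5:15),
                     reference_window = "last 4 weeks"),
    scale_definition("phq_stress", 10, 0, 2, reference_window = "last 4 weeks"),
    scale_definition("pswq", 16, 1, 5),
    scale_definition("sias", 20, 0, 4),
    scale_definition("sps", 20, 0, 4),
    scale_definition("wi", 14, 0, 1, dichotomous = TRUE),
    scale_definition("ybocs", 10, 0, 4,
                     subscales = list(obsessions = 1:5, compulsions = 6:10),
                     reference_window = "last 7 days")
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

check_item_matrix <- function(item_matrix, scale = NULL, n_items = NULL) {
  m <- as.matrix(item_matrix)
  if (!is.numeric(m)) stop("item matrix must be numeric", call. = FALSE)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing response at respondent %d, item %d (missing data are rejected, not imputed)",
                 idx[1], idx[2]), call. = FALSE)
  }
  if (!is.null(n_items) && ncol(m) != n_items) {
    stop(sprintf("expected %d item columns, found %d", n_items, ncol(m)),
         call. = FALSE)
  }
  if (!is.null(scale)) {
    bad <- m < scale$item_min | m > scale$item_max
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("response out of range [%d, %d] at respondent %d, item %d (value %g)",
                   scale$item_min, scale$item_max, idx[1], idx[2],
                   m[idx[1], idx[2]]), call. = FALSE)
    }
  }
  m
}

#' Score a scale or subscale as a per-respondent sum
#'
#' Sums item responses per respondent, after applying any per-item reversal
#' flagged in the scale definition.  Out-of-range and missing entries are
#' rejected with the offending respondent/item coordinates; imputation and
#' prorating are deliberately unsupported.
#'
#' @param item_matrix numeric matrix, respondents in rows, items in columns.
#'   Must have `n_items` columns (or `length(subset items)` columns when the
#'   matrix holds only the subscale's items).
#' @param scale a [scale_definition()].
#' @param subset optional subscale name; if given and the matrix has
#'   `n_items` columns, the subscale's columns are selected from it.
#' @return numeric vector of sum scores, one per respondent, each within the
#'   implied range `[k * item_min, k * item_max]` for `k` scored items.
#' @export
score_scale <- function(item_matrix, scale, subset = NULL) {
  stopifnot(inherits(scale, "scale_definition"))
  if (!is.null(subset)) {
    if (!subset %in% names(scale$subscales)) {
      stop(sprintf("unknown subscale '%s' for scale '%s'", subset, scale$name),
           call. = FALSE)
    }
    idx <- scale$subscales[[subset]]
    m <- as.matrix(item_matrix)
    if (ncol(m) == scale$n_items) {
      m <- check_item_matrix(m, scale, scale$n_items)
      m <- m[, idx, drop = FALSE]
      rev_local <- which(idx %in% scale$reverse_items)
    } else {
      m <- check_item_matrix(m, scale, length(idx))
      rev_local <- which(idx %in% scale$reverse_items)
    }
  } else {
    m <- check_item_matrix(item_matrix, scale, scale$n_items)
    rev_local <- scale$reverse_items
  }
  if (length(rev_local)) {
    m[, rev_local] <- scale$item_min + scale$item_max - m[, rev_local]
  }
  as.numeric(rowSums(m))
}

new_reliability_result <- function(scale_name, type, value, n, timepoint) {
  structure(
    list(scale_name = scale_name, coefficient_type = type, value = value,
         n_respondents = n, timepoint = timepoint),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  label <- if (x$coefficient_type == "alpha") "alpha" else "rho_KR20"
  cat(sprintf("%s(%s%s) = %.3f  [n = %d]\n", label, x$scale_name,
              if (is.na(x$timepoint)) "" else paste0(", ", x$timepoint),
              x$value, x$n_respondents))
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal consistency as
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`,
#' with all variances using the sample (n-1) convention.
#'
#' @param item_matrix numeric matrix of item responses (respondents x items);
#'   at least 2 items and 3 respondents.
#' @param scale_name identifier recorded in the result.
#' @param timepoint optional label (`"T0"`/`"T1"`) recorded in the result.
#' @return a `reliability_result` with `coefficient_type = "alpha"`.  The
#'   value is at most 1; it can be negative for inconsistent items.
#' @export
cronbach_alpha <- function(item_matrix, scale_name = "scale",
                           timepoint = NA_character_) {
  m <- check_item_matrix(item_matrix)
  k <- ncol(m)
  n <- nrow(m)
  if (k < 2) stop("Cronbach's alpha requires at least 2 items", call. = FALSE)
  if (n < 3) stop("Cronbach's alpha requires at least 3 respondents", call. = FALSE)
  total_var <- var(rowSums(m))
  if (total_var <= 0) {
    stop("degenerate data: total-score variance is zero", call. = FALSE)
  }
  item_var <- sum(apply(m, 2, var))
  value <- k / (k - 1) * (1 - item_var / total_var)
  new_reliability_result(scale_name, "alpha", value, n, timepoint)
}

#' Kuder-Richardson formula 20
#'
#' Reliability of a dichotomous scale via item proportions,
#' `rho_KR20 = k/(k-1) * (1 - sum(p*q * n/(n-1)) / var(total))`.
#' The `n/(n-1)` factor puts the item variances `p*q` on the same sample
#' convention as the total-score variance, which makes KR-20 identical to
#' Cronbach's alpha on the same binary matrix (it is alpha's dichotomous
#' special case).
#'
#' @inheritParams cronbach_alpha
#' @param binary_matrix numeric matrix with entries in \{0, 1\}.
#' @return a `reliability_result` with `coefficient_type = "kr20"`.
#' @export
kr20 <- function(binary_matrix, scale_name = "scale",
                 timepoint = NA_character_) {
  m <- check_item_matrix(binary_matrix)
  if (!all(m %in% c(0, 1))) {
    stop("KR-20 requires dichotomous (0/1) responses", call. = FALSE)
  }
  k <- ncol(m)
  n <- nrow(m)
  if (k < 2) stop("KR-20 requires at least 2 items", call. = FALSE)
  if (n < 3) stop("KR-20 requires at least 3 respondents", call. = FALSE)
  total_var <- var(rowSums(m))
  if (total_var <= 0) {
    stop("degenerate data: total-score variance is zero", call. = FALSE)
  }
  p <- colMeans(m)
  item_var <- sum(p * (1 - p)) * n / (n - 1)
  value <- k / (k - 1) * (1 - item_var / total_var)
  new_reliability_result(scale_name, "kr20", value, n, timepoint)
}
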