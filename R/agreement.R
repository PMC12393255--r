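#' Construct a multi-rater rating table
#'
#' Items by categories count matrix: `counts[i, q]` is the number of raters
#' who placed item `i` in category `q`. Raters may differ per item (missing
#' ratings simply lower an item's rater total).
#'
#' @param counts Integer matrix (items x categories) of non-negative counts.
#' @param items Optional item identifiers (default row numbers).
#' @param categories Optional category labels (default a 5-point scale is
#'   assumed only when the matrix has five columns and no names).
#' @return Object of class `rating_table`.
#' @export
rating_table <- function(counts, items = NULL, categories = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(items)) items <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  if (is.null(categories)) {
    categories <- colnames(counts)
    if (is.null(categories)) {
      categories <- if (ncol(counts) == 5L) {
        c("very poor", "poor", "fair", "good", "excellent")
      } else {
        as.character(seq_len(ncol(counts)))
      }
    }
  }
  dimnames(counts) <- list(items, categories)
  structure(list(counts = counts, items = items, categories = categories),
            class = "rating_table")
}

#' @export
print.rating_table <- function(x, ...) {
  cat("<rating_table>", nrow(x$counts), "items x", ncol(x$counts),
      "categories;", sum(x$counts), "ratings\n")
  invisible(x)
}

#' Build a rating table from long-format ratings
#'
#' @param df Data frame with columns `item_id`, `rater_id`, `category` (and
#'   optionally more, ignored).
#' @param categories Ordered category levels; default the sorted unique
#'   categories observed.
#' @return A [rating_table()].
#' @export
ratings_from_long <- function(df, categories = NULL) {
  stopifnot(all(c("item_id", "category") %in% names(df)))
  if (is.null(categories)) categories <- sort(unique(as.character(df$category)))
  tab <- table(factor(as.character(df$item_id), levels = unique(as.character(df$item_id))),
               factor(as.character(df$category), levels = categories))
  rating_table(unclass(as.matrix(tab)))
}

#' Gwet's AC1 chance-corrected agreement coefficient
#'
#' For items `i` with per-item rater totals `r_i` and per-category counts
#' `r_iq`: observed agreement `Pa = mean_i sum_q r_iq (r_iq - 1) /
#' (r_i (r_i - 1))`, category prevalences `pi_q = mean_i r_iq / r_i`, chance
#' agreement `Pe = sum_q pi_q (1 - pi_q) / (Q - 1)`, and
#' `AC1 = (Pa - Pe) / (1 - Pe)`. Unlike kappa, the chance term shrinks as
#' the category prevalences grow skewed, which keeps the coefficient stable
#' on the highly skewed rating patterns typical of quality surveys. Items
#' with fewer than two raters are dropped with a tally; a degenerate table
#' with `Pe = 1` yields `NA`.
#'
#' @param t A [rating_table()].
#' @return List with `ac1`, `pa`, `pe`, `n_items`, `n_dropped`.
#' @export
gwet_ac1 <- function(t) {
  counts <- t$counts
  r_i <- rowSums(counts)
  keep <- r_i >= 2L
  n_dropped <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  r_i <- r_i[keep]
  if (nrow(counts) == 0L) {
    stop("no items with at least two raters", call. = FALSE)
  }
  q <- ncol(counts)
  if (q < 2L) stop("AC1 needs at least two categories", call. = FALSE)
  pa_items <- rowSums(counts * (counts - 1L)) / (r_i * (r_i - 1L))
  pa <- mean(pa_items)
  pi_q <- colMeans(counts / r_i)
  pe <- sum(pi_q * (1 - pi_q)) / (q - 1L)
  ac1 <- if (1 - pe < .Machine$double.eps) {
    warning("degenerate table: chance agreement is 1; AC1 undefined",
            call. = FALSE)
    NA_real_
  } else (pa - pe) / (1 - pe)
  list(ac1 = ac1, pa = pa, pe = pe, n_items = nrow(counts),
       n_dropped = n_dropped)
}

#' AC1 stratified by item quality band
#'
#' Computes [gwet_ac1()] independently within each stratum of items (for
#' instance low / middle / high overall impression). Empty strata yield
#' `NA`.
#'
#' @param t A [rating_table()].
#' @param band_of_item Named character vector or function mapping item id to
#'   a band label.
#' @return Tibble with columns `band`, `ac1`, `n_items`.
#' @export
ac1_by_band <- function(t, band_of_item) {
  bands <- if (is.function(band_of_item)) {
    vapply(t$items, band_of_item, character(1))
  } else {
    unname(band_of_item[t$items])
  }
  out <- lapply(unique(bands), function(b) {
    idx <- which(bands == b)
    res <- tryCatch(
      gwet_ac1(rating_table(t$counts[idx, , drop = FALSE],
                            items = t$items[idx], categories = t$categories)),
      error = function(e) list(ac1 = NA_real_, n_items = 0L))
    tibble::tibble(band = b, ac1 = res$ac1, n_items = res$n_items)
  })
  dplyr::bind_rows(out)
}

#' Paired t-test with a significance verdict
#'
#' Classical two-sided paired t-test on the per-item score differences
#' between two systems, via [stats::t.test()]. A zero-variance difference
#' vector (for example two identical score columns) makes the statistic
#' undefined; such cases are reported as degenerate rather than failing.
#'
#' @param x,y Equal-length numeric vectors (length >= 2) of paired scores.
#' @param alpha Significance level, default 0.05.
#' @return List with `t`, `p`, `significant` (logical, `NA` when
#'   degenerate), `label` (significance bucket), `degenerate`.
#' @export
paired_t_test <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, significant = NA,
                label = "degenerate", degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  p <- unname(ht$p.value)
  list(t = unname(ht$statistic), p = p, significant = p < alpha,
       label = significance_legend(p), degenerate = FALSE)
}

#' Significance bucket for a p-value
#'
#' The conventional star legend: `ns` for p >= 0.05, `*` for 0.01 <= p <
#' 0.05, `**` for 0.001 <= p < 0.01, `***` for p < 0.001.
#'
#' @param p A p-value in `[0, 1]`.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
significance_legend <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single value in [0, 1]", call. = FALSE)
  }
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}
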