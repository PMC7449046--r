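#' Leaf-to-panicle ratio from a class mask
#'
#' LPR = L / P, where L and P are the leaf- and panicle-labeled pixel
#' counts of the image. The ratio proxies the partitioning of intercepted
#' light between source (leaf) and sink (panicle) organs. When P = 0 the
#' record is kept with the ratio marked missing (NA) rather than infinite;
#' \code{strict = TRUE} raises an error instead.
#'
#' @param mask H x W integer matrix with labels 0/1/2.
#' @param metadata optional named list (e.g. stage, genotype, treatment,
#'   timestamp) copied into the record.
#' @param image_id id string.
#' @param strict error on P = 0 instead of flagging the ratio missing.
#' @return one-row data.frame: image_id, L, P, lpr, background_count, plus
#'   one column per metadata entry.
#' @export
compute_lpr <- function(mask, metadata = list(), image_id = "image",
                        strict = FALSE) {
  if (!all(mask %in% 0:2))
    stop("compute_lpr: labels outside {0, 1, 2}", call. = FALSE)
  counts <- tabulate(mask + 1L, nbins = 3L)
  L <- counts[2]; P <- counts[3]
  if (P == 0 && strict)
    stop("compute_lpr: no panicle pixels; LPR undefined", call. = FALSE)
  rec <- data.frame(image_id = image_id, L = L, P = P,
                    lpr = if (P > 0) L / P else NA_real_,
                    background_count = counts[1],
                    stringsAsFactors = FALSE)
  for (nm in names(metadata)) rec[[nm]] <- metadata[[nm]]
  rec
}

#' Per-group summary of LPR records
#'
#' Records with undefined (missing) LPR are excluded, with their count
#' reported in the \code{n_undefined} attribute.
#'
#' @param records data.frame of LPR records (rows as returned by
#'   \code{\link{compute_lpr}}).
#' @param group_by character vector of grouping column names.
#' @return data.frame with one row per group: n, mean, sd, min, max of LPR.
#' @export
summarize_lpr <- function(records, group_by) {
  if (nrow(records) == 0)
    stop("summarize_lpr: no records", call. = FALSE)
  n_undef <- sum(is.na(records$lpr))
  ok <- records[!is.na(records$lpr), , drop = FALSE]
  if (nrow(ok) == 0)
    stop("summarize_lpr: all records have undefined LPR", call. = FALSE)
  key <- interaction(ok[group_by], drop = TRUE, sep = ":")
  agg <- function(f) as.vector(tapply(ok$lpr, key, f))
  out <- data.frame(group = levels(key),
                    n = as.vector(table(key)),
                    mean = agg(mean), sd = agg(stats::sd),
                    min = agg(min), max = agg(max),
                    stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- n_undef
  out
}

## shortest significant range for spans p = 2..k at protection level
## 1 - (1 - alpha)^(p - 1), scaled by sqrt(MSE / harmonic mean group size)
.ssr_ranges <- function(k, df, mse, n_h, alpha) {
  p <- 2:k
  q <- stats::qtukey(1 - (1 - alpha)^(p - 1), p, df, lower.tail = FALSE)
  r <- q * sqrt(mse / n_h)
  stats::setNames(c(NA, r), as.character(c(1, p)))[-1]
}

#' Shortest-significant-ranges (Duncan-style) multiple range test
#'
#' One-way analysis of variance provides the residual mean square and its
#' degrees of freedom; group means are ranked and every pair is compared
#' against the shortest significant range for the span it covers, computed
#' from the studentized-range quantile at protection level
#' 1 - (1 - alpha)^(p - 1) and scaled by sqrt(MSE / harmonic mean group
#' size). Ranges declared non-significant protect all sub-ranges
#' (containment closure), and the resulting pairwise decisions are
#' converted to a compact letter display: groups sharing a letter are not
#' significantly different at level alpha.
#'
#' @param records data.frame of LPR records; rows with missing \code{lpr}
#'   are dropped.
#' @param group_by name of the grouping column.
#' @param alpha significance level (default 0.05).
#' @param response name of the response column (default \code{"lpr"}).
#' @return list of class \code{group_comparison}: \code{means} (data.frame
#'   sorted by descending mean, with n and letters), \code{mse}, \code{df},
#'   \code{ranges} (shortest significant range per span), \code{alpha},
#'   \code{nonsig} (logical matrix of pairwise non-significance in sorted
#'   order).
#' @export
ssr_test <- function(records, group_by, alpha = 0.05, response = "lpr") {
  ok <- records[!is.na(records[[response]]), , drop = FALSE]
  g <- factor(ok[[group_by]])
  y <- ok[[response]]
  if (nlevels(g) < 2)
    stop("ssr_test: need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2))
    stop("ssr_test: every group needs at least 2 defined values",
         call. = FALSE)
  fit <- stats::aov(y ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df <- an["Residuals", "Df"]
  if (df < 1) stop("ssr_test: zero residual degrees of freedom",
                   call. = FALSE)
  means <- tapply(y, g, mean)
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]
  sizes <- as.vector(sizes)[ord]
  k <- length(means)
  n_h <- k / sum(1 / sizes) # harmonic mean group size
  ranges <- if (mse > 0) .ssr_ranges(k, df, mse, n_h, alpha)
            else stats::setNames(rep(0, k - 1), as.character(2:k))
  ## pairwise significance on the sorted means, with containment closure
  nonsig <- diag(TRUE, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      span <- j - i + 1L
      crit <- ranges[as.character(span)]
      nonsig[i, j] <- nonsig[j, i] <-
        (means[i] - means[j]) <= crit + 1e-12
    }
  }
  ## closure: a non-significant range protects everything inside it
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (nonsig[i, j])
        nonsig[i:j, i:j] <- TRUE
    }
  }
  letters_ <- .compact_letters(nonsig)
  out <- list(
    means = data.frame(group = names(means), n = sizes,
                       mean = as.vector(means), letters = letters_,
                       stringsAsFactors = FALSE),
    mse = mse, df = df, ranges = ranges, alpha = alpha, nonsig = nonsig
  )
  class(out) <- "group_comparison"
  out
}

## compact letter display from a pairwise non-significance matrix whose
## non-significant sets are intervals in sorted-mean order (true for range
## tests after containment closure): one letter per maximal interval
.compact_letters <- function(nonsig) {
  k <- nrow(nonsig)
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1L]) j <- j + 1L
    intervals[[i]] <- c(i, j)
  }
  ## keep maximal intervals only
  keep <- vapply(seq_len(k), function(i) {
    !any(vapply(seq_len(k), function(m) {
      m != i && intervals[[m]][1] <= intervals[[i]][1] &&
        intervals[[m]][2] >= intervals[[i]][2]
    }, logical(1)))
  }, logical(1))
  maximal <- unique(intervals[keep])
  lab <- rep("", k)
  for (m in seq_along(maximal)) {
    span <- maximal[[m]][1]:maximal[[m]][2]
    lab[span] <- paste0(lab[span], letters[(m - 1L) %% 26L + 1L])
  }
  lab
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Shortest significant ranges test (alpha = %g, MSE = %.4g, df = %d)\n",
    x$alpha, x$mse, x$df))
  print(x$means, row.names = FALSE)
  cat("Groups sharing a letter are not significantly different.\n")
  invisible(x)
}

#' LPR records for a set of masks
#'
#' @param masks named list of H x W label matrices (names become image ids).
#' @param metadata optional data.frame with one row per mask (matched by
#'   position) whose columns are copied into the records.
#' @return data.frame of LPR records.
#' @export
lpr_records <- function(masks, metadata = NULL) {
  ids <- names(masks)
  if (is.null(ids)) ids <- sprintf("image_%04d", seq_along(masks))
  rows <- lapply(seq_along(masks), function(i) {
    md <- if (!is.null(metadata)) as.list(metadata[i, , drop = FALSE])
          else list()
    compute_lpr(masks[[i]], metadata = md, image_id = ids[i])
  })
  do.call(rbind, rows)
}
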