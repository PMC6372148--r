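# Downstream statistics over the sensitivity table: PCA of sensitivities
# and of parameter values, per-set z-scores across reactions, pairwise
# dominance percentages, pairwise log2 sensitivity ratios, and
# integral-sensitivity Pearson correlations.
#
# "Sensitivity strength" comparisons between reactions (z-scores, dominance,
# ratios) default to the magnitude |s_log|: activating and deactivating
# reactions have opposite signs by network structure, so signed comparisons
# would only restate the sign structure, whereas the question of interest is
# which reaction the output responds to more strongly.

#' Principal component analysis with a fixed sign convention
#'
#' Standard PCA via the singular value decomposition of the centered (and,
#' when `standardize`, scaled) data. Component signs are fixed by making
#' the largest-magnitude loading of each component positive, so results are
#' fully deterministic. Rank-deficient input is allowed; components beyond
#' the rank have zero explained variance.
#'
#' @param x numeric matrix, observations x variables (no missing values).
#' @param standardize use correlation-scale PCA (divide columns by their
#'   SD). Default `TRUE`: sensitivity magnitudes differ across reactions by
#'   orders of magnitude.
#' @return a `hub_pca`: `scores`, `loadings`,
#'   `explained_variance_ratio`, `center`, `scale`.
#' @export
hub_pca <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("PCA needs at least 2 observations and 2 variables", call. = FALSE)
  if (any(!is.finite(x))) stop("PCA input has missing values", call. = FALSE)
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      # constant columns carry no information on the correlation scale
      x[, sds == 0] <- 0
      sds[sds == 0] <- 1
    }
    p <- stats::prcomp(x, center = TRUE, scale. = sds)
  } else {
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  }
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  evr <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr,
                 center = p$center,
                 scale = if (standardize) p$scale else NULL),
            class = "hub_pca")
}

#' @export
print.hub_pca <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat("<hub_pca> ", nrow(x$scores), " observations x ", nrow(x$loadings),
      " variables; explained variance: ",
      paste(sprintf("PC%d %.1f%%", seq_len(min(3, length(evr))),
                    100 * evr[seq_len(min(3, length(evr)))]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# wide matrix of one value column: rows = sets, columns = reaction (within
# one pattern) or reaction.pattern (all patterns)
sens_wide <- function(table, pattern = NULL, value = "s_log",
                      measure = c("magnitude", "signed")) {
  measure <- match.arg(measure)
  df <- as.data.frame(table)
  if (!is.null(pattern)) df <- df[df$pattern %in% pattern, , drop = FALSE]
  v <- df[[value]]
  if (value == "s_log" && measure == "magnitude") v <- abs(v)
  col <- if (is.null(pattern) || length(pattern) > 1)
    paste(df$reaction, df$pattern, sep = ".") else df$reaction
  sets <- unique(df$set_id)
  cols <- unique(col)
  m <- matrix(NA_real_, nrow = length(sets), ncol = length(cols),
              dimnames = list(sets, cols))
  m[cbind(match(df$set_id, sets), match(col, cols))] <- v
  m
}

#' PCA of sensitivity strengths
#'
#' Observations are parameter sets, variables are reaction x pattern
#' sensitivity magnitudes (or one pattern's reactions when `pattern` is
#' given).
#'
#' @param table a `sensitivity_table`.
#' @param pattern optional pattern id(s) to restrict to.
#' @param label_filter restrict to `"positive"`, `"negative"` or `"all"`.
#' @param measure `"magnitude"` (default) or `"signed"`.
#' @param standardize correlation-scale PCA (default).
#' @return a `hub_pca`.
#' @export
sensitivity_pca <- function(table, pattern = NULL, label_filter = "all",
                            measure = "magnitude", standardize = TRUE) {
  df <- filter_label(table, label_filter)
  m <- sens_wide(df, pattern = pattern, measure = measure)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  hub_pca(m, standardize = standardize)
}

#' PCA of parameter values (log scale)
#'
#' @param sets a `hub_param_sets` data frame.
#' @param label_filter restrict by label.
#' @param standardize correlation-scale PCA.
#' @return a `hub_pca`.
#' @export
parameter_pca <- function(sets, label_filter = "all", standardize = TRUE) {
  keep <- if (label_filter == "all") rep(TRUE, nrow(sets)) else
    sets$label == label_filter
  m <- param_values(sets, log = TRUE)[keep, , drop = FALSE]
  rownames(m) <- sets$id[keep]
  hub_pca(m, standardize = standardize)
}

filter_label <- function(table, label_filter) {
  if (identical(label_filter, "all")) return(table)
  out <- table[table$label %in% label_filter, , drop = FALSE]
  attributes(out)[c("model_id", "reactions", "pattern_ids")] <-
    attributes(table)[c("model_id", "reactions", "pattern_ids")]
  out
}

#' Per-set z-scores of sensitivity strength across reactions
#'
#' For each parameter set at one signal pattern, the sensitivity strengths
#' of all reactions are standardised within the set:
#' z = (s - mean over reactions) / SD over reactions. Rows therefore have
#' mean 0 and SD 1 (sets whose reactions all tie give a row of zeros).
#'
#' @param table a `sensitivity_table`.
#' @param pattern pattern id.
#' @param measure `"magnitude"` (default) or `"signed"` strengths.
#' @param sd_type `"sample"` (n-1, default) or `"population"`.
#' @param label_filter restrict by label.
#' @return matrix, sets x reactions.
#' @export
zscore_across_reactions <- function(table, pattern,
                                    measure = c("magnitude", "signed"),
                                    sd_type = c("sample", "population"),
                                    label_filter = "all") {
  measure <- match.arg(measure)
  sd_type <- match.arg(sd_type)
  m <- sens_wide(filter_label(table, label_filter), pattern = pattern,
                 measure = measure)
  if (ncol(m) < 2) stop("need at least 2 reactions", call. = FALSE)
  t(apply(m, 1, function(r) {
    mu <- mean(r)
    s <- stats::sd(r)
    if (sd_type == "population")
      s <- s * sqrt((length(r) - 1) / length(r))
    if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mu) / s
  }))
}

#' Pairwise dominance percentages between reactions
#'
#' For every ordered reaction pair (upper, left) at one signal pattern, the
#' percentage of parameter sets in which the upper reaction's sensitivity
#' strength strictly exceeds, is strictly below, or ties the left
#' reaction's (ties within relative tolerance `tie_tol`). The three
#' percentages sum to 100 per pair; a pair that always orders the same way
#' across every reproducible set (100/0) is an invariant relative-
#' sensitivity trend of the network.
#'
#' @param table a `sensitivity_table`.
#' @param pattern pattern id.
#' @param label_filter default `"positive"` (reproducible sets only).
#' @param measure `"magnitude"` (default) or `"signed"`.
#' @param tie_tol relative tie tolerance.
#' @return data frame: upper, left, pct_greater, pct_less, pct_equal, n.
#' @export
pairwise_dominance <- function(table, pattern, label_filter = "positive",
                               measure = c("magnitude", "signed"),
                               tie_tol = 1e-9) {
  measure <- match.arg(measure)
  m <- sens_wide(filter_label(table, label_filter), pattern = pattern,
                 measure = measure)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) == 0)
    stop("no parameter sets with label in '",
         paste(label_filter, collapse = ","),
         "'; relax the band or enlarge the search", call. = FALSE)
  reac <- colnames(m)
  pairs <- expand.grid(upper = reac, left = reac, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$upper != pairs$left, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- m[, pairs$upper[i]]
    b <- m[, pairs$left[i]]
    tie <- abs(a - b) <= tie_tol * pmax(abs(a), abs(b))
    data.frame(upper = pairs$upper[i], left = pairs$left[i],
               pct_greater = 100 * sum(!tie & a > b) / nrow(m),
               pct_less = 100 * sum(!tie & a < b) / nrow(m),
               pct_equal = 100 * sum(tie) / nrow(m),
               n = nrow(m), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Log2 sensitivity ratio for a reaction pair
#'
#' log2(|s_A| / |s_B|) per parameter set; 0 means equal magnitude. Records
#' with a zero denominator are dropped (with a warning).
#'
#' @param table a `sensitivity_table`.
#' @param pair character vector of two reaction labels (A, B).
#' @param pattern optional pattern id(s) to restrict to.
#' @param label_filter restrict by label.
#' @return data frame: set_id, pattern, log2_ratio.
#' @export
sensitivity_ratio <- function(table, pair, pattern = NULL,
                              label_filter = "all") {
  stopifnot(length(pair) == 2)
  df <- as.data.frame(filter_label(table, label_filter))
  if (!is.null(pattern)) df <- df[df$pattern %in% pattern, , drop = FALSE]
  a <- df[df$reaction == pair[1], c("set_id", "pattern", "s_log")]
  b <- df[df$reaction == pair[2], c("set_id", "pattern", "s_log")]
  mg <- merge(a, b, by = c("set_id", "pattern"), suffixes = c("_a", "_b"))
  zero <- mg$s_log_b == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) dropped: zero denominator sensitivity")
    mg <- mg[!zero, , drop = FALSE]
  }
  data.frame(set_id = mg$set_id, pattern = mg$pattern,
             log2_ratio = log2(abs(mg$s_log_a) / abs(mg$s_log_b)),
             stringsAsFactors = FALSE)
}

#' Pearson correlation between output integral and sensitivity
#'
#' For each (reaction, pattern) cell, the Pearson correlation across
#' parameter sets between the output time integral q and the
#' log-sensitivity s_log. Cells with fewer than 3 sets or zero variance in
#' either variable are reported as `NA`.
#'
#' @param table a `sensitivity_table`.
#' @param label_filter default `"positive"`.
#' @return data frame: reaction, pattern, r, n.
#' @export
integral_sensitivity_correlation <- function(table,
                                             label_filter = "positive") {
  df <- as.data.frame(filter_label(table, label_filter))
  if (nrow(df) == 0)
    stop("no records with the requested label", call. = FALSE)
  cells <- unique(df[, c("reaction", "pattern")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- df[df$reaction == cells$reaction[i] &
                df$pattern == cells$pattern[i], , drop = FALSE]
    r <- if (nrow(sub) < 3 || stats::sd(sub$q) == 0 ||
             stats::sd(sub$s_log) == 0) NA_real_
    else stats::cor(sub$q, sub$s_log)
    data.frame(reaction = cells$reaction[i], pattern = cells$pattern[i],
               r = r, n = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
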