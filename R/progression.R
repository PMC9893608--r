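# Progression statistics: complete-linkage hierarchical clustering with
# documented tie-breaking, temporal PTM categories relative to tangle onset,
# fold changes vs baseline, Welch t-tests, and burden correlations.

#' Complete-linkage hierarchical clustering (euclidean distance)
#'
#' Agglomerative clustering authored in-package so that tie-breaking is
#' documented and outputs are bit-stable: among equally distant pairs, the
#' pair whose clusters contain the lowest original row indices merges first;
#' the leaf order comes from a recursive traversal that visits the smaller
#' subtree first (ties: the subtree holding the lower row index). Rows with
#' missing values are dropped with a message (complete-case policy).
#'
#' @param m Numeric (or 0/1) matrix, rows = objects to cluster.
#' @return An object of class `c("tau_hclust", "hclust")` with the usual
#'   `merge`, `height`, `order`, `labels` components, plus a `fingerprint`
#'   attribute of the clustered matrix.
#' @export
hierarchical_cluster <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  cc <- complete.cases(m)
  if (!all(cc)) {
    message("hierarchical_cluster: dropping ", sum(!cc),
            " row(s) with missing values")
    m <- m[cc, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 2) stop("need >= 2 complete rows to cluster")
  D <- as.matrix(dist(m, method = "euclidean"))
  # active cluster bookkeeping: id (hclust convention: -leaf or +merge row),
  # minimum original leaf index (tie-break key), leaf count
  id <- -seq_len(n)
  minleaf <- seq_len(n)
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  children <- vector("list", n - 1)
  diag(D) <- Inf
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    # order candidates by min original leaf index so ties resolve to the
    # lowest-row pair
    idx <- idx[order(minleaf[idx])]
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (a in seq_len(length(idx) - 1)) {
      for (b in seq((a + 1), length(idx))) {
        dab <- D[idx[a], idx[b]]
        if (dab < best_d) {
          best_d <- dab
          best <- c(idx[a], idx[b])
        }
      }
    }
    i <- best[1]; j <- best[2]
    first <- if (minleaf[i] <= minleaf[j]) i else j
    second <- if (first == i) j else i
    merge[step, ] <- c(id[first], id[second])
    height[step] <- best_d
    children[[step]] <- c(first, second)
    # complete linkage update onto slot i
    newd <- pmax(D[i, ], D[j, ])
    D[i, ] <- newd
    D[, i] <- newd
    D[i, i] <- Inf
    D[j, ] <- Inf
    D[, j] <- Inf
    active[j] <- FALSE
    id[i] <- step
    minleaf[i] <- min(minleaf[i], minleaf[j])
    size[i] <- size[i] + size[j]
  }
  # leaf order: smaller subtree first; ties -> subtree with lower leaf index
  leaves <- function(node) {
    if (node < 0) return(-node)
    c(leaves(merge[node, 1]), leaves(merge[node, 2]))
  }
  traverse <- function(node) {
    if (node < 0) return(-node)
    l1 <- leaves(merge[node, 1]); l2 <- leaves(merge[node, 2])
    swap <- length(l2) < length(l1) ||
      (length(l2) == length(l1) && min(l2) < min(l1))
    if (swap) {
      c(traverse(merge[node, 2]), traverse(merge[node, 1]))
    } else {
      c(traverse(merge[node, 1]), traverse(merge[node, 2]))
    }
  }
  res <- structure(list(merge = merge, height = height,
                        order = traverse(n - 1L),
                        labels = rownames(m), method = "complete",
                        dist.method = "euclidean",
                        call = match.call()),
                   class = c("tau_hclust", "hclust"))
  attr(res, "fingerprint") <- c(nrow = nrow(m), ncol = ncol(m),
                                sum = sum(m), sumsq = sum(m^2))
  res
}

#' Temporal category of PTM sites relative to tangle onset
#'
#' Given a binary presence matrix over ordered time points (one model/region),
#' a site present at every time point is `all_timepoints`; otherwise its
#' first-presence time classifies it as `pre_onset` (< onset),
#' `concomitant_with_onset` (= onset) or `post_onset` (> onset). Sites absent
#' everywhere are excluded.
#'
#' @param binary Sites-by-time 0/1 matrix; column names (or `times`) give the
#'   numeric time points in increasing order.
#' @param onset Tangle-onset time point (must be among the time points).
#' @param times Optional numeric vector overriding column-name times.
#' @return Data frame: `site`, `first_present`, `category` (factor with the
#'   four levels).
#' @export
annotate_temporal <- function(binary, onset, times = NULL) {
  binary <- as.matrix(binary)
  if (is.null(times)) times <- as.numeric(colnames(binary))
  stopifnot(length(times) == ncol(binary), !is.unsorted(times))
  if (!onset %in% times) stop("onset time ", onset, " not among time points")
  present <- binary > 0
  keep <- rowSums(present) > 0
  if (!all(keep)) {
    message("annotate_temporal: excluding ", sum(!keep),
            " site(s) absent at every time point")
  }
  present <- present[keep, , drop = FALSE]
  first <- times[apply(present, 1, function(x) which(x)[1])]
  category <- ifelse(rowSums(present) == ncol(present), "all_timepoints",
                     ifelse(first < onset, "pre_onset",
                            ifelse(first == onset, "concomitant_with_onset",
                                   "post_onset")))
  data.frame(site = rownames(present) %||% seq_len(nrow(present)),
             first_present = first,
             category = factor(category,
                               levels = c("all_timepoints", "pre_onset",
                                          "concomitant_with_onset",
                                          "post_onset")),
             stringsAsFactors = FALSE)
}

#' Fold change of mean abundance versus the earliest time point
#'
#' Baseline is the earliest time point with at least one non-missing value;
#' `fold(t) = mean(t) / mean(baseline)`. A zero baseline mean flags all folds
#' undefined.
#'
#' @param abundance Numeric vector (e.g. fmol/mg per sample).
#' @param time Numeric vector of time points, parallel to `abundance`.
#' @return Data frame: `time`, `n`, `mean`, `fold`, `flag`.
#' @examples
#' fold_change_vs_baseline(c(100, 100, 510, 510), c(2, 2, 4, 4))
#' @export
fold_change_vs_baseline <- function(abundance, time) {
  stopifnot(length(abundance) == length(time))
  ok <- !is.na(abundance) & !is.na(time)
  abundance <- abundance[ok]; time <- time[ok]
  tps <- sort(unique(time))
  means <- vapply(tps, function(t) mean(abundance[time == t]), numeric(1))
  ns <- vapply(tps, function(t) sum(time == t), integer(1))
  base <- means[1]
  flag <- if (base == 0) "undefined_baseline" else "ok"
  data.frame(time = tps, n = ns, mean = means,
             fold = if (base == 0) NA_real_ else means / base,
             flag = flag)
}

#' Welch two-sided t-test (unequal variances)
#'
#' Implemented from the Welch statistic and Welch-Satterthwaite degrees of
#' freedom. Each group needs n >= 2; zero variance in both groups is an
#' error.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List: `t`, `df`, `p` (two-sided, uncorrected).
#' @export
welch_t_test <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("degenerate: zero variance in both groups")
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson correlation of a quantity with insoluble Tau burden
#'
#' @param x Per-sample values (e.g. unmodified fraction of a peptide).
#' @param burden Per-sample insoluble Tau (fmol/mg), paired with `x`.
#' @param log_transform Correlate against `log10(burden)` (default `TRUE`);
#'   requires positive burdens.
#' @return List: `r` (NA when either vector is constant), `n`.
#' @export
correlate_with_burden <- function(x, burden, log_transform = TRUE) {
  if (length(x) != length(burden)) stop("length mismatch")
  ok <- !is.na(x) & !is.na(burden)
  x <- x[ok]; burden <- burden[ok]
  if (length(x) < 3) stop("need n >= 3 paired observations")
  if (log_transform) {
    if (any(burden <= 0)) stop("burden must be > 0 for log transform")
    burden <- log10(burden)
  }
  r <- if (stats::sd(x) == 0 || stats::sd(burden) == 0) {
    NA_real_
  } else {
    cor(x, burden)
  }
  list(r = r, n = length(x))
}

#' Correlation table: every peptide's unmodified fraction vs log10 burden
#'
#' @param extents A `mod_extent_matrix`.
#' @param burden Named numeric vector of fmol/mg, names = sample ids.
#' @param log_transform Passed to [correlate_with_burden()].
#' @param condition Optional label stored in the output.
#' @return Data frame of class `correlation_table`: `interval`, `start`, `r`,
#'   `n`, `condition`.
#' @export
correlation_table <- function(extents, burden, log_transform = TRUE,
                              condition = NA_character_) {
  stopifnot(inherits(extents, "mod_extent_matrix"))
  samples <- intersect(colnames(extents$unmodified), names(burden))
  rows <- lapply(rownames(extents$unmodified), function(iv) {
    x <- extents$unmodified[iv, samples]
    ok <- !is.na(x) & !is.na(burden[samples])
    if (sum(ok) < 3) {
      return(data.frame(interval = iv, start = NA_integer_, r = NA_real_,
                        n = sum(ok), condition = condition))
    }
    cr <- correlate_with_burden(x[ok], burden[samples][ok], log_transform)
    data.frame(interval = iv,
               start = suppressWarnings(as.integer(sub("-.*", "", iv))),
               r = cr$r, n = cr$n, condition = condition)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Rank peptides by correlation strength
#'
#' Sorts by absolute Pearson r, descending; when a peptide appears under
#' several conditions, its mean absolute r across conditions is used. Ties
#' break by canonical start position (ascending). `k` larger than the table
#' returns everything.
#'
#' @param table A `correlation_table` (or data frame with `interval`, `r`,
#'   optionally `start`).
#' @param k Number of peptides to return.
#' @return Data frame: `interval`, `start`, `mean_abs_r`, ordered.
#' @export
rank_top_correlating <- function(table, k = 5) {
  if (!nrow(table)) stop("empty correlation table")
  agg <- aggregate(abs(table$r), by = list(interval = table$interval),
                   FUN = mean, na.rm = TRUE)
  names(agg)[2] <- "mean_abs_r"
  agg$start <- table$start[match(agg$interval, table$interval)]
  agg <- agg[order(-agg$mean_abs_r, agg$start), c("interval", "start",
                                                  "mean_abs_r")]
  rownames(agg) <- NULL
  head(agg, min(k, nrow(agg)))
}
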