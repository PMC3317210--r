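#' Contingency table of true versus estimated counts
#'
#' @param true_counts,est_counts equal-length integer vectors of paired
#'   cells-per-cluster counts.
#' @param classes class labels; defaults to `1:max` over both inputs.
#' @return square integer matrix with `dimnames` `true` x `est`.
#' @export
build_contingency <- function(true_counts, est_counts, classes = NULL) {
  if (length(true_counts) != length(est_counts))
    stop("true_counts and est_counts must have equal length")
  if (length(true_counts) == 0) {
    m <- matrix(integer(), 0, 0)
    dimnames(m) <- list(true = character(), est = character())
    return(m)
  }
  classes <- classes %||% seq_len(max(true_counts, est_counts))
  tab <- table(factor(true_counts, levels = classes),
               factor(est_counts, levels = classes))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab))
  dimnames(m) <- list(true = rownames(tab), est = colnames(tab))
  m
}

#' Fleiss' kappa for algorithm-versus-reference agreement
#'
#' Treats each cluster as a subject rated by two raters (the algorithm
#' and the reference) assigning it to a cells-per-cluster category, and
#' computes Fleiss' chance-corrected agreement with its large-sample
#' standard error (the standard error is the null-hypothesis asymptotic
#' form of Fleiss' statistic).
#'
#' @param table square contingency matrix from [build_contingency()].
#' @return list with `kappa`, `se`, `p_bar` (observed agreement), `p_e`
#'   (chance agreement), `n_subjects` and the category marginals `p_j`.
#'   `kappa` is `NA` (with a warning) when fewer than two categories are
#'   used or agreement is degenerate.
#' @export
fleiss_kappa <- function(table) {
  N <- sum(table)
  if (N == 0) { warning("empty table: kappa undefined"); return(list(kappa = NA_real_, se = NA_real_)) }
  r <- 2
  p_j <- (rowSums(table) + colSums(table)) / (N * r)
  used <- p_j > 0
  if (sum(used) < 2) {
    warning("fewer than two categories used: kappa undefined")
    return(list(kappa = NA_real_, se = NA_real_, p_bar = 1, p_e = 1,
                n_subjects = N, p_j = p_j))
  }
  p_bar <- sum(diag(table)) / N      # per-subject agreement with r = 2
  p_e <- sum(p_j^2)
  kappa <- (p_bar - p_e) / (1 - p_e)
  q_j <- 1 - p_j
  spq <- sum(p_j * q_j)
  se <- sqrt(2 / (N * r * (r - 1))) *
    sqrt(spq^2 - sum(p_j * q_j * (q_j - p_j))) / spq
  list(kappa = kappa, se = se, p_bar = p_bar, p_e = p_e,
       n_subjects = N, p_j = p_j)
}

#' Cohen's kappa (two-rater comparison statistic)
#'
#' Reported alongside [fleiss_kappa()] for a two-rater design; the two
#' differ only in how the chance-agreement marginals are pooled.
#'
#' @param table square contingency matrix.
#' @return list with `kappa`, `p_o`, `p_e`.
#' @export
cohen_kappa <- function(table) {
  N <- sum(table)
  if (N == 0) return(list(kappa = NA_real_))
  p_o <- sum(diag(table)) / N
  p_e <- sum(rowSums(table) * colSums(table)) / N^2
  list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e)
}

#' Per-class sensitivity and specificity
#'
#' One-vs-rest metrics per cells-per-cluster class: sensitivity is the
#' fraction of true class-k clusters estimated as k; specificity the
#' fraction of non-k clusters not estimated as k. Classes with no true
#' instances have undefined sensitivity and are excluded from the mean.
#'
#' @param table square contingency matrix.
#' @return list with `per_class` (data frame), `mean_sensitivity` and
#'   `min_specificity` (over classes with defined values).
#' @export
sensitivity_specificity <- function(table) {
  N <- sum(table)
  k <- nrow(table)
  cls <- rownames(table) %||% as.character(seq_len(k))
  rs <- rowSums(table); cs <- colSums(table); d <- diag(table)
  sens <- ifelse(rs > 0, d / rs, NA_real_)
  spec <- ifelse(N - rs > 0, (N - rs - cs + d) / (N - rs), NA_real_)
  per_class <- data.frame(class = cls, n_true = as.integer(rs),
                          sensitivity = as.numeric(sens),
                          specificity = as.numeric(spec))
  list(per_class = per_class,
       mean_sensitivity = mean(sens, na.rm = TRUE),
       min_specificity = suppressWarnings(min(spec, na.rm = TRUE)))
}

#' Relative error of the total cell count
#'
#' @param true_counts,est_counts paired per-cluster counts.
#' @return `|sum(est) - sum(true)| / sum(true)`.
#' @export
total_count_error <- function(true_counts, est_counts) {
  if (length(true_counts) != length(est_counts))
    stop("true_counts and est_counts must have equal length")
  st <- sum(true_counts)
  if (st == 0) stop("total true count is zero: relative error undefined")
  abs(sum(est_counts) - st) / st
}

#' Histograms of cluster volume and integrated intensity
#'
#' The dominant intensity peak locates single cells (the two-cell peak
#' sits at about twice it); the windows feed [select_singletons()].
#'
#' @param features cluster feature table.
#' @param breaks passed to [hist()].
#' @return object of class `feature_histograms`: binned counts for
#'   intensity and volume plus estimated peak locations.
#' @export
feature_histograms <- function(features, breaks = "Sturges") {
  if (nrow(features) == 0) {
    return(structure(list(intensity = data.frame(mid = numeric(),
                                                 count = integer()),
                          volume = data.frame(mid = numeric(),
                                              count = integer()),
                          peaks = list(intensity = NA_real_,
                                       volume = NA_real_)),
                     class = "feature_histograms"))
  }
  hi <- hist(features$intensity, breaks = breaks, plot = FALSE)
  hv <- hist(features$volume, breaks = breaks, plot = FALSE)
  ipeak <- if (nrow(features) >= 5) {
    d <- density(features$intensity); d$x[which.max(d$y)]
  } else hi$mids[which.max(hi$counts)]
  structure(list(intensity = data.frame(mid = hi$mids, count = hi$counts),
                 volume = data.frame(mid = hv$mids, count = hv$counts),
                 peaks = list(intensity = ipeak,
                              volume = hv$mids[which.max(hv$counts)])),
            class = "feature_histograms")
}

#' @export
plot.feature_histograms <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  barplot(x$intensity$count, names.arg = signif(x$intensity$mid, 3),
          xlab = "integrated intensity", ylab = "clusters", las = 2)
  barplot(x$volume$count, names.arg = signif(x$volume$mid, 3),
          xlab = "volume (voxels)", ylab = "clusters", las = 2)
  invisible(x)
}

#' Match ground-truth clusters to detected labels
#'
#' Each true cell votes for the label at its rendered center; a cluster's
#' detected id is the majority non-zero vote (0 when undetected).
#'
#' @param truth phantom ground truth (list with `cells`, `clusters`).
#' @param labels label volume from detection.
#' @return data frame `cluster_id`, `n_cells`, `det_id`.
#' @export
match_to_truth <- function(truth, labels) {
  labels <- as_volume(labels)
  d <- dim(labels)
  cells <- truth$cells
  lab <- labels[cbind(clamp(round(cells$y), 1, d[1]),
                      clamp(round(cells$x), 1, d[2]),
                      clamp(cells$slice, 1, d[3]))]
  det <- vapply(split(lab, cells$cluster_id), function(v) {
    v <- v[v > 0]
    if (length(v) == 0) return(0L)
    as.integer(names(which.max(table(v))))
  }, integer(1))
  data.frame(cluster_id = as.integer(names(det)),
             n_cells = truth$clusters$n_cells[
               match(as.integer(names(det)), truth$clusters$cluster_id)],
             det_id = as.integer(det))
}

#' Match ground truth to counted clusters by center proximity
#'
#' File-based alternative to [match_to_truth()] when only the counts
#' table (with cluster centers of mass) is available: each true cluster
#' is matched to the nearest counted cluster center within `max_dist`
#' pixels (in-plane) and one slice.
#'
#' @param truth ground truth list.
#' @param counts a `count_result` (or its data frame).
#' @param max_dist maximum in-plane center distance, pixels.
#' @return data frame `cluster_id`, `n_cells`, `det_id` (0 = unmatched).
#' @export
match_by_center <- function(truth, counts, max_dist = 5) {
  tc <- truth$clusters
  cx <- vapply(split(truth$cells$x, truth$cells$cluster_id), mean, numeric(1))
  cy <- vapply(split(truth$cells$y, truth$cells$cluster_id), mean, numeric(1))
  cz <- vapply(split(truth$cells$slice, truth$cells$cluster_id), mean, numeric(1))
  det <- integer(nrow(tc))
  for (i in seq_len(nrow(tc))) {
    dx <- counts$com_x - cx[i]; dy <- counts$com_y - cy[i]
    dz <- abs(counts$com_z - cz[i])
    dd <- sqrt(dx^2 + dy^2)
    ok <- which(dd <= max_dist & dz <= 1.5)
    det[i] <- if (length(ok)) counts$cluster_id[ok[which.min(dd[ok])]] else 0L
  }
  data.frame(cluster_id = tc$cluster_id, n_cells = tc$n_cells, det_id = det)
}

#' Score algorithm counts against ground truth
#'
#' Builds the true-versus-estimated contingency table over matched
#' clusters and reports Fleiss' and Cohen's kappa, per-class sensitivity
#' and specificity, the relative total-count error (all estimated cells
#' versus all true cells, so missed clusters count against the total),
#' and detection tallies.
#'
#' @param truth phantom ground truth.
#' @param counts a `count_result`.
#' @param match matching data frame from [match_to_truth()] or
#'   [match_by_center()].
#' @param exclude optional vector of true cluster ids to exclude (e.g.
#'   visually ambiguous references).
#' @return object of class `cryo_eval`.
#' @export
evaluate_counts <- function(truth, counts, match, exclude = NULL) {
  if (!is.null(exclude)) match <- match[!match$cluster_id %in% exclude, ]
  m <- match[match$det_id > 0, , drop = FALSE]
  est <- counts$n_est[match(m$det_id, counts$cluster_id)]
  ok <- !is.na(est)
  pairs <- data.frame(cluster_id = m$cluster_id[ok], true_n = m$n_cells[ok],
                      est_n = est[ok])
  tab <- build_contingency(pairs$true_n, pairs$est_n)
  ss <- sensitivity_specificity(tab)
  total_true <- sum(truth$clusters$n_cells[
    !truth$clusters$cluster_id %in% exclude])
  total_est <- sum(counts$n_est, na.rm = TRUE)
  structure(list(pairs = pairs, contingency = tab,
                 fleiss = fleiss_kappa(tab), cohen = cohen_kappa(tab),
                 sensitivity_specificity = ss,
                 total_true = total_true, total_est = total_est,
                 total_count_error = abs(total_est - total_true) /
                   max(total_true, 1),
                 within_one = mean(abs(pairs$est_n - pairs$true_n) <= 1),
                 n_true_clusters = nrow(match),
                 n_matched = nrow(pairs),
                 n_missed = sum(match$det_id == 0),
                 n_spurious = sum(!counts$cluster_id %in% match$det_id)),
            class = "cryo_eval")
}

#' @export
print.cryo_eval <- function(x, ...) {
  cat(sprintf("<cryo_eval> %d/%d true clusters matched (%d missed, %d spurious)\n",
              x$n_matched, x$n_true_clusters, x$n_missed, x$n_spurious))
  cat(sprintf("  total count %d est vs %d true (error %.2f%%); within +/-1: %.1f%%\n",
              x$total_est, x$total_true, 100 * x$total_count_error,
              100 * x$within_one))
  cat(sprintf("  Fleiss kappa %.3f +/- %.3f; Cohen kappa %.3f\n",
              x$fleiss$kappa, x$fleiss$se, x$cohen$kappa))
  cat(sprintf("  mean sensitivity %.3f; min specificity %.3f\n",
              x$sensitivity_specificity$mean_sensitivity,
              x$sensitivity_specificity$min_specificity))
  invisible(x)
}
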