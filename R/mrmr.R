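# Minimum-redundancy maximum-relevance feature ranking. Mutual information
# is estimated after equal-frequency discretization into `bins` bins
# (internally in nats, reported in bits). Ranking granularity is the
# feature TYPE: a type's relevance is the mean MI with the class over its
# channel columns, and the redundancy between two types is the mean MI over
# their column pairs (matched by channel, to keep the cost linear in
# channels). Greedy MID scheme: first pick maximizes relevance, each later
# pick maximizes relevance minus mean redundancy with the already-selected
# types. Ties break by canonical feature-list order.

discretize_ef <- function(x, bins = 10) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

mi_discrete <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
}

#' Rank feature types by minimum-redundancy maximum-relevance
#'
#' @param fm a `FeatureMatrix` with at least two classes.
#' @param bins equal-frequency discretization bins (default 10).
#' @param granularity `"type"` (default: rank the feature types,
#'   aggregating channel columns) or `"column"` (rank all columns
#'   individually).
#' @return A `FeatureRanking`: data frame with `feature` (or column name),
#'   `score` (mRMR score in bits), `relevance` (MI with the class, bits)
#'   and `rank`, ordered by selection; plus attributes `transform`,
#'   `subband`.
#' @export
rank_features <- function(fm, bins = 10, granularity = c("type", "column")) {
  granularity <- match.arg(granularity)
  if (nlevels(droplevels(fm$labels)) < 2)
    stop("feature ranking needs at least two classes")
  y <- droplevels(fm$labels)
  V <- fm$values
  disc <- lapply(seq_len(ncol(V)), function(j) discretize_ef(V[, j], bins))
  const_col <- vapply(seq_len(ncol(V)), function(j)
    stats::var(V[, j]) < .Machine$double.eps, logical(1))
  rel_col <- vapply(seq_len(ncol(V)), function(j) {
    if (const_col[j]) 0 else mi_discrete(disc[[j]], y)
  }, numeric(1))

  if (granularity == "type") {
    # canonical feature-list order first (it is also the tie-break order),
    # then any non-canonical names by first appearance
    lev <- c(intersect(feature_names(), fm$column_meta$feature),
             setdiff(unique(fm$column_meta$feature), feature_names()))
    groups <- split(seq_len(ncol(V)),
                    factor(fm$column_meta$feature, levels = lev))
    groups <- groups[vapply(groups, length, integer(1)) > 0]
  } else {
    groups <- as.list(seq_len(ncol(V)))
    names(groups) <- colnames(V)
  }
  gnames <- names(groups)
  rel <- vapply(groups, function(ix) mean(rel_col[ix]), numeric(1))

  # redundancy cache: mean MI between the columns of two groups, paired by
  # position (channel-matched)
  red_cache <- matrix(NA_real_, length(groups), length(groups))
  redundancy <- function(i, j) {
    if (!is.na(red_cache[i, j])) return(red_cache[i, j])
    gi <- groups[[i]]; gj <- groups[[j]]
    v <- mean(vapply(seq_along(gi), function(t)
      mi_discrete(disc[[gi[t]]], disc[[gj[t]]]), numeric(1)))
    red_cache[i, j] <<- v; red_cache[j, i] <<- v
    v
  }

  selected <- integer(0)
  score <- numeric(length(groups))
  remaining <- seq_along(groups)
  for (step in seq_along(groups)) {
    cand_score <- vapply(remaining, function(i) {
      if (length(selected) == 0) return(rel[i])
      rel[i] - mean(vapply(selected, function(s) redundancy(i, s),
                           numeric(1)))
    }, numeric(1))
    best <- remaining[order(-cand_score, remaining)[1]]  # tie: list order
    score[best] <- cand_score[match(best, remaining)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  out <- data.frame(feature = gnames[selected],
                    score = score[selected] / log(2),
                    relevance = rel[selected] / log(2),
                    rank = seq_along(selected),
                    stringsAsFactors = FALSE)
  structure(out, class = c("FeatureRanking", "data.frame"),
            transform = unique(fm$column_meta$transform),
            subband = unique(fm$column_meta$subband),
            granularity = granularity)
}

#' Keep the top-k ranked feature types (all channels of each)
#'
#' @param fm a `FeatureMatrix`.
#' @param ranking a [rank_features()] result for `fm`.
#' @param k number of feature types to keep (1..number ranked).
#' @return A `FeatureMatrix` with `k * channels` columns, ordered by rank.
#' @export
select_top <- function(fm, ranking, k) {
  if (k < 1 || k > nrow(ranking))
    stop("k must be in 1..", nrow(ranking))
  keep <- ranking$feature[seq_len(k)]
  idx <- unlist(lapply(keep, function(f)
    which(fm$column_meta$feature == f)), use.names = FALSE)
  new_feature_matrix(fm$values[, idx, drop = FALSE], fm$labels,
                     fm$column_meta[idx, , drop = FALSE])
}

#' Fuse top-ranked features across transforms
#'
#' Column-wise concatenation of `select_top(fm, ranking, k)` for each
#' (matrix, ranking) pair; all matrices must share segment order and
#' labels. Column metadata keeps each column's source transform.
#'
#' @param matrices list of `(FeatureMatrix, FeatureRanking)` pairs, i.e.
#'   `list(list(fm = ..., ranking = ...), ...)`.
#' @param k features per transform.
#' @return A fused `FeatureMatrix` (`k * channels * length(matrices)`
#'   columns) with attribute `k`.
#' @export
fuse_features <- function(matrices, k) {
  stopifnot(length(matrices) >= 1)
  tops <- lapply(matrices, function(mr) select_top(mr$fm, mr$ranking, k))
  lab0 <- tops[[1]]$labels
  for (tp in tops[-1]) {
    if (nrow(tp$values) != nrow(tops[[1]]$values) ||
        !identical(as.character(tp$labels), as.character(lab0)))
      stop("fused matrices must share segment order and labels")
  }
  fused <- new_feature_matrix(
    do.call(cbind, lapply(tops, `[[`, "values")),
    lab0,
    do.call(rbind, lapply(tops, `[[`, "column_meta")))
  attr(fused, "k") <- k
  fused
}

#' Export a ranking as CSV
#' @param ranking a `FeatureRanking`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)
  df$transform <- paste(attr(ranking, "transform"), collapse = "+")
  df$subband <- paste(attr(ranking, "subband"), collapse = "+")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
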