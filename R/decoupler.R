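#' Token-level Levenshtein distance between preference sequences
#'
#' Minimum number of single-token insertions, deletions or substitutions
#' transforming one indicator sequence into the other. Tokens are whole
#' indicator names, not characters: `c("Angle", "IAN")` and `c("Angle")`
#' are one deletion apart regardless of how the names are spelled.
#'
#' @param a,b Character vectors of indicator tokens (empty allowed).
#' @return Non-negative integer distance.
#' @examples
#' seq_levenshtein(c("A", "B", "C", "D"), c("B", "C", "D", "E"))
#' @export
seq_levenshtein <- function(a, b) {
  alphabet <- unique(c(a, b))
  if (!length(alphabet)) return(0L)
  # map tokens to single characters so base R's generalized edit distance
  # (utils::adist) operates at token level
  enc <- function(x) intToUtf8(match(x, alphabet) + 64L)
  as.integer(utils::adist(enc(a), enc(b)))
}

#' Pairwise Levenshtein distance matrix between surgeons
#'
#' @param seqs Either the tibble returned by [preference_sequences()]
#'   (columns `surgeon_id` and `tokens`) or a named list of token vectors.
#' @return A symmetric numeric matrix with zero diagonal, dimnames set to
#'   the surgeon ids.
#' @export
pairwise_distances <- function(seqs) {
  if (is.data.frame(seqs)) {
    ids <- seqs$surgeon_id
    toks <- seqs$tokens
  } else {
    ids <- names(seqs)
    toks <- seqs
  }
  if (length(ids) < 2L) stop("need at least 2 sequences")
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequences must carry unique surgeon ids")
  }
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- seq_levenshtein(toks[[i]], toks[[j]])
    }
  }
  D
}

#' Decouple surgeons into experience groups by hierarchical clustering
#'
#' Agglomerative clustering (average linkage by default) on a precomputed
#' Levenshtein distance matrix, cut into `k` groups. Surgeons are ordered
#' by id before clustering so that tied merges resolve deterministically in
#' id order.
#'
#' @param D Symmetric distance matrix with surgeon ids as dimnames.
#' @param k Number of groups (default 2: grade-1-trained vs novice).
#' @param linkage One of `"average"`, `"complete"`, `"single"`.
#' @return A tibble of class `ddss_partition` with columns `surgeon_id`
#'   and `cluster` (1..k, numbered by first appearance in id order), and
#'   the `hclust` merge tree in attribute `tree`.
#' @export
cluster_surgeons <- function(D, k = 2L,
                             linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  ids <- rownames(D)
  if (is.null(ids)) stop("distance matrix must carry surgeon ids as dimnames")
  if (k > nrow(D)) stop("k = ", k, " exceeds the number of surgeons (", nrow(D), ")")
  ord <- order(ids)
  D <- D[ord, ord, drop = FALSE]
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  cl <- stats::cutree(tree, k = k)
  out <- tibble::tibble(surgeon_id = ids[ord], cluster = as.integer(cl))
  attr(out, "tree") <- tree
  class(out) <- c("ddss_partition", class(out))
  out
}

#' Full sequence-based decoupling pipeline
#'
#' Convenience wrapper running [preference_sequences()],
#' [pairwise_distances()] and [cluster_surgeons()] in order.
#'
#' @param records A `ddss_records` tibble with >= 2 surgeons.
#' @param schema Indicator schema.
#' @param k,linkage Passed to [cluster_surgeons()].
#' @param grid_size Passed to [preference_sequences()].
#' @return A `ddss_partition` with the preference sequences attached in
#'   attribute `sequences` and the distance matrix in attribute
#'   `distances`.
#' @export
decouple_surgeons <- function(records, schema = ddss_schema(), k = 2L,
                              linkage = "average", grid_size = 200L) {
  if (length(unique(records$surgeon_id)) < 2L) {
    stop("need >= 2 surgeons to decouple")
  }
  seqs <- preference_sequences(records, schema, grid_size = grid_size)
  D <- pairwise_distances(seqs)
  part <- cluster_surgeons(D, k = k, linkage = linkage)
  attr(part, "sequences") <- seqs
  attr(part, "distances") <- D
  part
}

#' Assign a new surgeon to an experience group
#'
#' Returns the cluster whose member sequences have the smallest mean
#' Levenshtein distance to the new surgeon's preference sequence; ties go
#' to the lower cluster id.
#'
#' @param tokens Character vector: the new surgeon's preference sequence.
#' @param partition A `ddss_partition`.
#' @param member_seqs Sequences tibble for the partitioned surgeons
#'   (defaults to the sequences stored on the partition).
#' @return Integer cluster id.
#' @export
assign_surgeon <- function(tokens, partition,
                           member_seqs = attr(partition, "sequences")) {
  if (is.null(member_seqs)) stop("member sequences are required")
  df <- dplyr::inner_join(partition, member_seqs, by = "surgeon_id")
  if (!nrow(df)) stop("no member sequences for any partitioned surgeon")
  d <- vapply(df$tokens, function(m) seq_levenshtein(tokens, m), numeric(1))
  mean_d <- tapply(d, df$cluster, mean)
  cl_ids <- as.integer(names(mean_d))
  # ties resolve to the lower cluster id (ids are sorted by tapply)
  cl_ids[which.min(mean_d)]
}

# standardization stats (mean, pop sd) of indicator codes on training data
train_feature_stats <- function(train, schema) {
  m <- record_matrix(train, schema)
  list(mu = colMeans(m), sd = apply(m, 2, pop_sd))
}

standardize_features <- function(records, schema, stats_) {
  m <- record_matrix(records, schema)
  m <- sweep(m, 2, stats_$mu, "-")
  sd_ <- ifelse(stats_$sd > 0, stats_$sd, 1)
  sweep(m, 2, sd_, "/")
}

#' Route test records to experience groups
#'
#' Records from surgeons present in the partition inherit that surgeon's
#' cluster (`method = "surgeon"`, the default). Records from unknown
#' surgeons - and all records under `method = "centroid"` - are routed to
#' the cluster whose training-record centroid is nearest in the
#' standardized feature space (standardization statistics from the
#' training data); ties go to the lower cluster id.
#'
#' @param records Test records tibble.
#' @param partition A `ddss_partition`.
#' @param train Training records tibble (source of standardization
#'   statistics and centroids).
#' @param schema Indicator schema.
#' @param method `"surgeon"` (lookup first, centroid fallback) or
#'   `"centroid"` (feature-space routing for every record).
#' @return Integer vector of cluster ids, one per test record.
#' @export
assign_samples <- function(records, partition, train,
                           schema = ddss_schema(),
                           method = c("surgeon", "centroid")) {
  method <- match.arg(method)
  train_cl <- dplyr::inner_join(train, partition, by = "surgeon_id")
  if (!nrow(train_cl)) stop("no training records for any partitioned surgeon")
  clusters <- sort(unique(partition$cluster))
  stats_ <- train_feature_stats(train, schema)
  zs_train <- standardize_features(train_cl, schema, stats_)
  centroids <- lapply(clusters, function(cl) {
    rows <- which(train_cl$cluster == cl)
    if (!length(rows)) stop("training cluster ", cl, " is empty")
    colMeans(zs_train[rows, , drop = FALSE])
  })
  zs_test <- standardize_features(records, schema, stats_)
  nearest <- function(i) {
    d2 <- vapply(centroids, function(ct) sum((zs_test[i, ] - ct)^2),
                 numeric(1))
    clusters[which.min(d2)] # which.min takes the first = lowest cluster id
  }
  lookup <- stats::setNames(partition$cluster, partition$surgeon_id)
  vapply(seq_len(nrow(records)), function(i) {
    sid <- records$surgeon_id[i]
    if (method == "surgeon" && sid %in% names(lookup)) {
      as.integer(lookup[[sid]])
    } else {
      as.integer(nearest(i))
    }
  }, integer(1))
}

#' Gaussian-mixture baseline partition of surgeons
#'
#' Comparison partitioner: each surgeon is summarized by the mean of their
#' standardized indicator codes (14 values) plus the mean and SD of their
#' dataset-standardized operative duration (2 values capturing speed level
#' and spread), and the summary vectors are clustered with a k-component
#' Gaussian mixture: full covariance when the number of surgeons exceeds
#' the summary dimension, otherwise the most general covariance family BIC
#' can estimate, always under mclust's conjugate prior regularization (an
#' unregularized full covariance is singular for a handful of surgeons in
#' a 16-dimensional summary).
#'
#' @param records A `ddss_records` tibble.
#' @param schema Indicator schema.
#' @param k Number of components (default 2).
#' @param seed Integer seed for the mixture initialization.
#' @return A `ddss_partition` tibble (cluster ids numbered by first
#'   appearance in surgeon-id order).
#' @export
gmm_partition <- function(records, schema = ddss_schema(), k = 2L,
                          seed = 1L) {
  ids <- sort(unique(records$surgeon_id))
  if (length(ids) < k) stop("need at least k surgeons")
  stats_ <- train_feature_stats(records, schema)
  zs <- standardize_features(records, schema, stats_)
  dz <- (records$duration_s - mean(records$duration_s)) /
    pop_sd(records$duration_s)
  summ <- t(vapply(ids, function(s) {
    rows <- which(records$surgeon_id == s)
    c(colMeans(zs[rows, , drop = FALSE]),
      dur_mean = mean(dz[rows]), dur_sd = pop_sd(dz[rows]))
  }, numeric(ncol(zs) + 2L)))
  cl <- withr::with_seed(seed, {
    if (k == 1L) {
      rep(1L, length(ids))
    } else {
      # full covariance needs more surgeons than summary dimensions; below
      # that, BIC picks the most general estimable covariance family
      models <- if (nrow(summ) > ncol(summ) + 1) "VVV" else NULL
      fit <- Mclust(summ, G = k, modelNames = models,
                    prior = priorControl(), verbose = FALSE)
      if (is.null(fit)) {
        stop("Gaussian mixture fit failed (degenerate covariance); ",
             "reduce the summary dimension or add regularization")
      }
      fit$classification
    }
  })
  cl <- as.integer(factor(cl, levels = unique(cl))) # relabel 1..k by appearance
  out <- tibble::tibble(surgeon_id = ids, cluster = cl)
  class(out) <- c("ddss_partition", class(out))
  out
}

#' Compare operative durations between the two experience groups
#'
#' Two-sided pooled-variance (Student) two-sample t-test on raw operative
#' durations between the partition's groups.
#'
#' @param records A `ddss_records` tibble.
#' @param partition A `ddss_partition` with exactly 2 clusters.
#' @return A one-row tibble: `statistic` (t), `df`, `p_value`,
#'   `mean_cluster1`, `mean_cluster2`, `n_cluster1`, `n_cluster2`.
#' @export
group_duration_test <- function(records, partition) {
  df <- dplyr::inner_join(records, partition, by = "surgeon_id")
  cls <- sort(unique(df$cluster))
  if (length(cls) != 2L) stop("partition must have exactly 2 non-empty clusters")
  x <- df$duration_s[df$cluster == cls[1]]
  y <- df$duration_s[df$cluster == cls[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need at least 2 records")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero pooled variance; t-test undefined")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_cluster1 = mean(x),
    mean_cluster2 = mean(y),
    n_cluster1 = length(x),
    n_cluster2 = length(y)
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a recovered partition and a
#' reference (e.g. the generator's planted groups); 1 means identical up
#' to relabeling.
#'
#' @param partition,reference Tibbles with columns `surgeon_id` and
#'   `cluster`.
#' @return Numeric scalar in (-1, 1].
#' @export
partition_ari <- function(partition, reference) {
  df <- dplyr::inner_join(partition, reference, by = "surgeon_id",
                          suffix = c("", "_ref"))
  if (!nrow(df)) stop("partitions share no surgeons")
  mclust::adjustedRandIndex(df$cluster, df$cluster_ref)
}
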