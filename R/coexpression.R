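#' Parameters for signed co-expression network construction
#'
#' Defaults follow the conventional signed-network analysis settings used for
#' TCGA-scale cohorts: minimum module size 30, eigengene merge height 0.25,
#' no post-hoc gene reassignment, single-block analysis up to 30000 genes.
#' The soft-thresholding power is data-set specific (4 and 7 for the breast
#' and gastric cohorts that motivated this package); [pick_soft_threshold()]
#' suggests one from the scale-free topology fit.
#'
#' @param power soft-thresholding exponent `beta > 0`.
#' @param min_module_size smallest cluster kept as a module; smaller clusters
#'   are assigned to the unassigned ("grey") label 0.
#' @param merge_cut_height eigengene dissimilarity (1 - cor) below which two
#'   modules are merged.
#' @param reassign_threshold 0 = no post-hoc reassignment of genes between
#'   modules (the only supported value).
#' @param max_block_size genes handled in one block; larger inputs are split
#'   by k-means on correlation profiles.
#' @param static_cut_quantile quantile of the merge heights at which the
#'   dendrogram is first cut statically.
#' @param cohesion_frac fraction of the maximum merge height below which a
#'   subtree counts as cohesive during the recursive descent (see
#'   [detect_modules()]).
#' @param trim_frac rider-trimming strictness: a member of an accepted
#'   cluster is kept only if it joins below
#'   `median attach height + trim_frac * (max height - median attach height)`.
#' @param candidate_powers powers scanned by [pick_soft_threshold()].
#' @param scale_free_r2_target minimum signed scale-free fit R^2.
#' @return a validated `nfyar_network_params` list.
#' @export
network_params <- function(power = 4,
                           min_module_size = 30L,
                           merge_cut_height = 0.25,
                           reassign_threshold = 0,
                           max_block_size = 30000L,
                           static_cut_quantile = 0.995,
                           cohesion_frac = 0.9,
                           trim_frac = 0.3,
                           candidate_powers = c(1:10, seq(12, 20, 2)),
                           scale_free_r2_target = 0.85) {
  if (power <= 0) stop_config("config field `power` must be > 0")
  if (merge_cut_height <= 0 || merge_cut_height >= 1)
    stop_config("config field `merge_cut_height` must be in (0, 1)")
  if (reassign_threshold != 0)
    stop_config("config field `reassign_threshold` supports only 0 (no reassignment)")
  structure(list(power = power,
                 min_module_size = as.integer(min_module_size),
                 merge_cut_height = merge_cut_height,
                 reassign_threshold = reassign_threshold,
                 max_block_size = as.integer(max_block_size),
                 static_cut_quantile = static_cut_quantile,
                 cohesion_frac = cohesion_frac,
                 trim_frac = trim_frac,
                 candidate_powers = candidate_powers,
                 scale_free_r2_target = scale_free_r2_target),
            class = "nfyar_network_params")
}

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^power`, so perfectly anticorrelated genes get
#' adjacency 0 and perfectly correlated genes adjacency 1. The diagonal is
#' set to 0 for connectivity computations.
#'
#' @param cor_mat symmetric correlation matrix with entries in `[-1, 1]`.
#' @param power soft-thresholding exponent.
#' @return symmetric adjacency matrix with entries in `[0, 1]`, zero diagonal.
#' @examples
#' signed_adjacency(matrix(c(1, 0, 0, 1), 2), power = 4)
#' @export
signed_adjacency <- function(cor_mat, power) {
  if (!is.matrix(cor_mat) || nrow(cor_mat) != ncol(cor_mat))
    stop_input("`cor_mat` must be a square matrix")
  if (any(cor_mat < -1 - 1e-8, na.rm = TRUE) || any(cor_mat > 1 + 1e-8, na.rm = TRUE))
    stop_input("correlation entries outside [-1, 1]")
  a <- ((1 + pmin(pmax(cor_mat, -1), 1)) / 2)^power
  diag(a) <- 0
  a
}

#' Topological overlap similarity
#'
#' For adjacency `a` with connectivities `k_i = sum_j a_ij`,
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_u a_iu a_uj`; the diagonal is 1. Two genes are similar when
#' they share the same weighted neighbourhood even if their direct adjacency
#' is moderate.
#'
#' @param adjacency symmetric matrix, entries in `[0, 1]`, zero diagonal.
#' @return symmetric TOM matrix, entries in `[0, 1]`, unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop_input("`adjacency` must be a square matrix")
  if (any(adjacency < 0) || any(adjacency > 1))
    stop_input("adjacency entries must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- colSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  # numerical guard: theory bounds TOM in [0, 1]
  pmin(pmax(tom, 0), 1)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into `n_bins` equal-width bins and regresses
#' `log10 p(k)` on `log10 k` over nonempty bins. The returned `r_squared` is
#' signed: negated when the slope is positive, since scale-free topology
#' requires a decreasing degree distribution.
#'
#' @param k nonnegative connectivity vector.
#' @param n_bins number of bins (default 10).
#' @return list with `r_squared` (signed), `slope`, and the bin table
#'   (tibble: k_mean, freq).
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  if (breaks[1] == breaks[n_bins + 1L])
    return(list(r_squared = NA_real_, slope = NA_real_, bins = tibble::tibble()))
  bin <- cut(k, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  tab <- tibble::tibble(bin = bin, k = k) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(k_mean = mean(.data$k), freq = dplyr::n() / length(!!k),
                     .groups = "drop") |>
    dplyr::filter(.data$k_mean > 0, .data$freq > 0)
  if (nrow(tab) < 3L)
    return(list(r_squared = NA_real_, slope = NA_real_, bins = tab))
  fit <- stats::lm(log10(freq) ~ log10(k_mean), data = tab)
  # a perfect fit is legitimate here (exact power-law degree sequences)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- unname(stats::coef(fit)[2])
  list(r_squared = if (!is.na(slope) && slope > 0) -r2 else r2,
       slope = slope, bins = tab)
}

#' Scan soft-thresholding powers for scale-free topology
#'
#' For each candidate power, builds the signed adjacency, computes the
#' connectivity of every gene and the signed scale-free fit R^2, and suggests
#' the smallest power reaching `r2_target` (or, with a warning, the power of
#' maximal fit if none does).
#'
#' @param features genes x samples numeric matrix (log2 scale).
#' @param candidate_powers powers to scan.
#' @param r2_target signed R^2 threshold.
#' @param n_bins connectivity bins for the fit.
#' @return list with `table` (tibble: power, sft_r_squared, slope,
#'   mean_connectivity, median_connectivity, max_connectivity) and
#'   `suggested_power`.
#' @export
pick_soft_threshold <- function(features,
                                candidate_powers = c(1:10, seq(12, 20, 2)),
                                r2_target = 0.85, n_bins = 10L) {
  if (ncol(features) < 30L)
    warn(sprintf("only %d samples; scale-free fit may be unstable", ncol(features)))
  keep <- apply(features, 1, stats::sd) > 0
  cm <- cor(t(features[keep, , drop = FALSE]))
  rows <- purrr::map(candidate_powers, function(p) {
    a <- signed_adjacency(cm, p)
    k <- colSums(a)
    fit <- scale_free_fit(k, n_bins)
    tibble::tibble(power = p, sft_r_squared = fit$r_squared, slope = fit$slope,
                   mean_connectivity = mean(k),
                   median_connectivity = median(k),
                   max_connectivity = max(k))
  })
  tab <- dplyr::bind_rows(rows)
  ok <- which(!is.na(tab$sft_r_squared) & tab$sft_r_squared >= r2_target)
  if (length(ok)) {
    suggested <- tab$power[min(ok)]
  } else {
    suggested <- tab$power[which.max(tab$sft_r_squared)]
    warn(sprintf("no candidate power reaches R^2 >= %.2f; using power %g (max fit)",
                 r2_target, suggested))
  }
  list(table = tab, suggested_power = suggested)
}

#' Module eigengene: first principal component of a module
#'
#' Genes are standardized, the first right singular vector across samples is
#' taken as the eigengene (unit norm), and its sign is oriented so that its
#' correlation with the module's mean expression profile is nonnegative.
#'
#' @param module_expr genes x samples matrix restricted to one module
#'   (>= 2 genes, >= 3 samples).
#' @return numeric per-sample vector of unit length with attribute
#'   `var_explained` (proportion of variance carried by the first component).
#' @export
module_eigengene <- function(module_expr) {
  if (!is.matrix(module_expr) || nrow(module_expr) < 2L || ncol(module_expr) < 3L)
    stop_input("module must have >= 2 genes and >= 3 samples")
  sds <- apply(module_expr, 1, sd)
  keep <- sds > 0
  if (!any(keep)) stop_input("zero-variance module submatrix")
  x <- module_expr[keep, , drop = FALSE]
  xs <- (x - rowMeans(x)) / apply(x, 1, sd)
  if (nrow(xs) == 1L) {
    v <- xs[1, ] / sqrt(sum(xs[1, ]^2))
    attr(v, "var_explained") <- 1
    return(v)
  }
  sv <- svd(xs, nu = 0, nv = 1)
  v <- sv$v[, 1]
  mean_profile <- colMeans(xs)
  if (cor(v, mean_profile) < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  names(v) <- colnames(module_expr)
  attr(v, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  v
}

#' @noRd
tree_cut_cohesive <- function(hc, min_size, static_cut_quantile, cohesion_frac,
                              trim_frac = 0.3) {
  n <- length(hc$order)
  h <- hc$height
  m <- hc$merge
  h0 <- quantile7(h, static_cut_quantile)
  hmax <- max(h)
  # TOM dissimilarity of uncorrelated genes sits near 1; a tree whose top
  # merge stays below this ceiling contains no background at all and is
  # cohesive as a whole (and must not be trimmed against its own spread)
  no_background <- hmax <= 0.8
  coh <- if (no_background) hmax else cohesion_frac * hmax

  # leaves of each internal node, built bottom-up
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- m[i, ]
    members[[i]] <- c(if (kids[1] < 0) -kids[1] else members[[kids[1]]],
                      if (kids[2] < 0) -kids[2] else members[[kids[2]]])
  }
  # parent merge index of each internal node (0 for the root) and the attach
  # height of every leaf (height of the merge that first includes it)
  parent <- integer(n - 1L)
  attach <- numeric(n)
  for (i in seq_len(n - 1L)) for (kid in m[i, ]) {
    if (kid > 0) parent[kid] <- i else attach[-kid] <- h[i]
  }

  # static clusters: maximal subtrees with root height <= h0
  static_roots <- which(h <= h0 & (parent == 0L | h[pmax(parent, 1L)] > h0))
  if (h[n - 1L] <= h0) static_roots <- n - 1L
  # leaves whose parent merge lies above h0 form singleton static clusters;
  # singletons can never reach min_size so they stay grey implicitly.

  labels <- integer(n)
  next_label <- 0L
  stack <- as.list(static_roots)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (h[node] <= coh) {
      leaves <- members[[node]]
      # trim riders: members joining far above the cluster's median attach
      # height belong to the loose background, not the module core
      core <- median(attach[leaves])
      keep <- if (no_background) leaves else
        leaves[attach[leaves] <= core + trim_frac * (hmax - core)]
      if (length(keep) >= min_size) {
        next_label <- next_label + 1L
        labels[keep] <- next_label
      }
    } else {
      for (kid in m[node, ]) if (kid > 0) stack[[length(stack) + 1L]] <- kid
      # negative kids are single leaves: grey
    }
  }
  if (!is.null(hc$labels)) names(labels) <- hc$labels
  labels
}

#' @noRd
merge_by_eigengene <- function(features, labels, cut_height) {
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    if (length(mods) < 2L) break
    E <- vapply(mods, function(mod)
      module_eigengene(features[labels == mod, , drop = FALSE]),
      numeric(ncol(features)))
    diss <- 1 - cor(E)
    diag(diss) <- Inf
    idx <- arrayInd(which.min(diss), dim(diss))
    if (diss[idx] >= cut_height) break
    a <- mods[min(idx)]; b <- mods[max(idx)]
    labels[labels == b] <- a
  }
  labels
}

#' Detect co-expression modules in a feature matrix
#'
#' Runs the full signed-network pipeline: Pearson correlation across samples,
#' signed adjacency at the chosen power, topological overlap, average-linkage
#' hierarchical clustering of `1 - TOM`, a two-step tree cut, removal of
#' undersized clusters to the unassigned label 0, and iterative merging of
#' modules whose eigengenes are closer than `merge_cut_height`. Final labels
#' are renumbered by decreasing module size (1 = largest).
#'
#' The tree cut is a simplified substitute for dynamic hybrid cutting:
#' (1) a static cut at the `static_cut_quantile` of the merge heights yields
#' maximal subtrees; (2) each subtree is recursively split at its root until
#' the subtree is *cohesive* — its root merge height is at most
#' `cohesion_frac` times the maximum merge height — so loose
#' background-correlation clusters dissolve into unassigned leaves while
#' tight planted modules survive intact.
#'
#' Inputs wider than `max_block_size` genes are split into blocks by k-means
#' on gene correlation profiles, detected per block, and merged across blocks
#' by the same eigengene criterion.
#'
#' @param features genes x samples numeric matrix (log2 scale), e.g. from
#'   [build_feature_matrix()]. Constant rows are dropped with a warning.
#' @param params an `nfyar_network_params` from [network_params()].
#' @return an `nfyar_modules` object: list with `labels` (named integer
#'   vector, 0 = unassigned), `eigengenes` (samples x modules matrix, columns
#'   `ME1`, `ME2`, ...), `dendrogram` (`hclust`, single-block runs only),
#'   `params`, and `var_explained` (per-module proportion of variance).
#' @export
detect_modules <- function(features, params = network_params()) {
  check_expression_matrix(features, "features")
  if (nrow(features) < 3L) stop_input("need at least 3 genes to detect modules")
  sds <- apply(features, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant gene(s)", sum(sds == 0)))
    features <- features[sds > 0, , drop = FALSE]
  }
  if (nrow(features) > params$max_block_size)
    return(detect_modules_blockwise(features, params))

  cm <- cor(t(features))
  adj <- signed_adjacency(cm, params$power)
  tom <- tom_similarity(adj)
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  labels <- tree_cut_cohesive(hc, params$min_module_size,
                              params$static_cut_quantile, params$cohesion_frac,
                              params$trim_frac)
  names(labels) <- rownames(features)
  labels <- merge_by_eigengene(features, labels, params$merge_cut_height)
  finalize_modules(features, labels, params, dendrogram = hc)
}

#' @noRd
detect_modules_blockwise <- function(features, params) {
  n_blocks <- ceiling(nrow(features) / params$max_block_size)
  # deterministic correlation profile against an evenly spaced gene panel
  panel <- unique(round(seq(1L, nrow(features), length.out = 200L)))
  cm_profile <- cor(t(features), t(features[panel, , drop = FALSE]))
  km <- stats::kmeans(cm_profile, centers = cm_profile[
    unique(round(seq(1L, nrow(cm_profile), length.out = n_blocks))), ,
    drop = FALSE])
  labels <- integer(nrow(features)); names(labels) <- rownames(features)
  offset <- 0L
  for (b in seq_len(n_blocks)) {
    idx <- which(km$cluster == b)
    if (length(idx) < 3L) next
    sub <- detect_modules(features[idx, , drop = FALSE], params)
    lb <- sub$labels
    lb[lb > 0L] <- lb[lb > 0L] + offset
    offset <- offset + max(0L, max(sub$labels))
    labels[idx] <- lb
  }
  labels <- merge_by_eigengene(features, labels, params$merge_cut_height)
  finalize_modules(features, labels, params, dendrogram = NULL)
}

#' @noRd
finalize_modules <- function(features, labels, params, dendrogram = NULL) {
  mods <- sort(unique(labels[labels > 0L]))
  sizes <- vapply(mods, function(mod) sum(labels == mod), integer(1))
  new_ids <- integer(max(c(mods, 0L)))
  new_ids[mods[order(-sizes, mods)]] <- seq_along(mods)
  relabel <- labels
  relabel[labels > 0L] <- new_ids[labels[labels > 0L]]
  mods <- seq_along(sizes)
  egs <- NULL; ve <- NULL
  if (length(mods)) {
    egs <- vapply(mods, function(mod)
      as.numeric(module_eigengene(features[relabel == mod, , drop = FALSE])),
      numeric(ncol(features)))
    ve <- vapply(mods, function(mod)
      attr(module_eigengene(features[relabel == mod, , drop = FALSE]),
           "var_explained"), numeric(1))
    dimnames(egs) <- list(colnames(features), paste0("ME", mods))
    names(ve) <- paste0("ME", mods)
  }
  structure(list(labels = relabel, eigengenes = egs, dendrogram = dendrogram,
                 params = params, var_explained = ve),
            class = "nfyar_modules")
}

#' @export
print.nfyar_modules <- function(x, ...) {
  n_mod <- length(unique(x$labels[x$labels > 0L]))
  cat(sprintf("<nfyar_modules> %d genes, %d modules (+ %d unassigned)\n",
              length(x$labels), n_mod, sum(x$labels == 0L)))
  invisible(x)
}
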