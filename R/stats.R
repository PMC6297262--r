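#' Voxel-wise Student t statistics on log-Jacobian maps
#'
#' Computes a per-voxel one- or two-sample t statistic across subjects.
#' Two-sample designs use the pooled-variance statistic (EtOH vs Con);
#' one-sample designs test the group mean against zero. The tail records
#' the directional hypothesis (`"greater"`: expansion in the first group,
#' or positive mean). Parametric p-values are not used for inference -
#' permutation p-values from [permutation_p()] are.
#'
#' @param maps list of `log_jacobian_map`s (or plain 3D arrays) on a
#'   common grid.
#' @param design list: `type` = `"two_sample"` with `groups` a vector of
#'   `"EtOH"`/`"Con"` labels (first level tested minus second), or
#'   `"one_sample"`.
#' @param tail `"greater"` or `"less"`.
#' @param mask optional logical array restricting computation.
#' @return a `stat_map`: list with `t` (3D array; `Inf` flags
#'   zero-variance voxels with nonzero effect), `p` (`NULL` until
#'   permutation), `tail`, `design`, `df`, `mask`.
#' @export
voxelwise_t <- function(maps, design, tail = c("greater", "less"), mask = NULL) {
  tail <- match.arg(tail)
  X <- maps_matrix(maps)
  d <- attr(X, "dim3")
  if (is.null(mask)) mask <- array(TRUE, d)
  if (design$type == "two_sample") {
    gr <- design$groups
    lev <- unique(gr)
    if (length(lev) != 2) stop("two-sample design needs exactly 2 groups")
    i1 <- which(gr == lev[1]); i2 <- which(gr == lev[2])
    if (length(i1) < 2 || length(i2) < 2)
      stop("each group needs at least 2 subjects")
    t_flat <- two_sample_t(X, i1, i2)
    df <- length(i1) + length(i2) - 2
  } else if (design$type == "one_sample") {
    if (ncol(X) < 2) stop("one-sample design needs at least 2 maps")
    t_flat <- one_sample_t(X)
    df <- ncol(X) - 1
  } else stop("unknown design type: ", design$type)
  tarr <- array(t_flat, d)
  tarr[!mask] <- 0
  structure(list(t = tarr, p = NULL, tail = tail, design = design, df = df,
                 mask = mask),
            class = "stat_map")
}

maps_matrix <- function(maps) {
  vals <- lapply(maps, function(m) if (inherits(m, "log_jacobian_map")) m$values else m)
  d <- dim(vals[[1]])
  for (v in vals) if (!identical(dim(v), d)) stop("maps must share geometry")
  X <- vapply(vals, as.vector, numeric(prod(d)))
  attr(X, "dim3") <- d
  X
}

two_sample_t <- function(X, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(X[, i1, drop = FALSE]); m2 <- rowMeans(X[, i2, drop = FALSE])
  v1 <- rowSums((X[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((X[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  num <- m1 - m2
  t <- ifelse(se > 0, num / se, ifelse(num == 0, 0, sign(num) * Inf))
  t
}

one_sample_t <- function(X) {
  n <- ncol(X)
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (n - 1))
  se <- s / sqrt(n)
  ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
}

#' Permutation p-values for voxel-wise tests
#'
#' Builds the permutation null of the voxel-wise t statistic: group-label
#' permutations for two-sample designs, sign flips for one-sample designs.
#' All arrangements are enumerated when their number is at most `n_perm`;
#' otherwise `n_perm` distinct random arrangements (always including the
#' identity) are drawn. p-values use the unbiased estimator
#' `p = (b + 1) / (m + 1)`, where `b` counts non-identity arrangements
#' whose statistic is at least as extreme as the observed one and `m` is
#' the number of non-identity arrangements, so the smallest attainable p
#' is 1 / (number of arrangements). Deterministic given `seed`.
#'
#' @inheritParams voxelwise_t
#' @param n_perm maximum number of arrangements (>= 100 advised; < 20
#'   rejected).
#' @param seed integer seed for the sampled case.
#' @return a `stat_map` with the permutation `p` array filled in.
#' @export
permutation_p <- function(maps, design, tail = c("greater", "less"),
                          n_perm = 5000, seed = 1L, mask = NULL) {
  tail <- match.arg(tail)
  if (n_perm < 20) stop("n_perm < 20 gives meaningless p-values")
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  sm <- voxelwise_t(maps, design, tail, mask)
  X <- maps_matrix(maps)
  d <- attr(X, "dim3")
  flat_mask <- as.vector(sm$mask)
  Xm <- X[flat_mask, , drop = FALSE]
  n <- ncol(X)
  obs <- as.vector(sm$t)[flat_mask]
  cmp_ge <- function(a, b) a >= b - 1e-12
  count <- numeric(length(obs))
  if (design$type == "two_sample") {
    gr <- design$groups
    lev <- unique(gr)
    i1_obs <- which(gr == lev[1])
    n1 <- length(i1_obs)
    total <- choose(n, n1)
    sets <- enumerate_or_sample_groups(n, n1, i1_obs, total, n_perm, seed)
    m <- length(sets)
    for (s in sets) {
      tp <- two_sample_t(Xm, s, setdiff(seq_len(n), s))
      extreme <- if (tail == "greater") cmp_ge(tp, obs) else cmp_ge(obs, tp)
      count <- count + extreme
    }
  } else {
    total <- 2^n
    signs <- enumerate_or_sample_signs(n, total, n_perm, seed)
    m <- nrow(signs)
    for (r in seq_len(m)) {
      Xs <- sweep(Xm, 2, signs[r, ], `*`)
      tp <- one_sample_t(Xs)
      extreme <- if (tail == "greater") cmp_ge(tp, obs) else cmp_ge(obs, tp)
      count <- count + extreme
    }
  }
  p <- array(1, d)
  p[flat_mask] <- (count + 1) / (m + 1)
  sm$p <- p
  sm$n_arrangements <- m + 1
  sm
}

# All non-identity subsets of size n1 (exhaustive) or a seeded sample of
# distinct non-identity subsets.
enumerate_or_sample_groups <- function(n, n1, i1_obs, total, n_perm, seed) {
  if (total <= n_perm) {
    all_sets <- combn(n, n1, simplify = FALSE)
    keys <- vapply(all_sets, paste, character(1), collapse = ",")
    obs_key <- paste(sort(i1_obs), collapse = ",")
    all_sets[keys != obs_key]
  } else {
    with_seed(as.integer(seed), {
      seen <- new.env(hash = TRUE)
      assign(paste(sort(i1_obs), collapse = ","), TRUE, envir = seen)
      out <- vector("list", n_perm - 1)
      got <- 0L
      while (got < n_perm - 1) {
        s <- sort(sample.int(n, n1))
        key <- paste(s, collapse = ",")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          got <- got + 1L
          out[[got]] <- s
        }
      }
      out
    })
  }
}

enumerate_or_sample_signs <- function(n, total, n_perm, seed) {
  if (total <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    ident <- rowSums(signs == 1) == n
    unname(signs[!ident, , drop = FALSE])
  } else {
    with_seed(as.integer(seed), {
      seen <- new.env(hash = TRUE)
      assign(paste(rep(1, n), collapse = ""), TRUE, envir = seen)
      out <- matrix(0, n_perm - 1, n)
      got <- 0L
      while (got < n_perm - 1) {
        s <- sample(c(1, -1), n, replace = TRUE)
        key <- paste((s + 1) / 2, collapse = "")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          got <- got + 1L
          out[got, ] <- s
        }
      }
      out
    })
  }
}

#' Smoothness (FWHM) of residual maps
#'
#' Gaussian-equivalent smoothness per axis from the variance of spatial
#' first differences of standardised residuals (the classic gradient
#' estimator): for a unit-variance field, the lag-one correlation is
#' `rho = 1 - var(diff) / 2`, and a Gaussian autocorrelation gives
#' `sigma = sqrt(-1 / (4 log rho))` voxels. Estimates are averaged across
#' maps and floored at half a voxel.
#'
#' @param residual_maps list of >= 2 residual arrays (or
#'   `log_jacobian_map`s), e.g. subject maps minus their group mean.
#' @param mask logical array; differences are taken only between
#'   in-mask neighbours.
#' @param spacing voxel spacing (mm) used to express FWHM in mm.
#' @return a `smoothness_estimate`: list with `fwhm_mm`, `fwhm_vox`.
#' @export
estimate_fwhm <- function(residual_maps, mask, spacing) {
  if (length(residual_maps) < 2) stop("need >= 2 residual maps")
  if (!any(mask)) stop("empty mask")
  vals <- lapply(residual_maps, function(m) if (inherits(m, "log_jacobian_map")) m$values else m)
  d <- dim(vals[[1]])
  fwhm_vox <- matrix(NA_real_, length(vals), 3)
  for (mi in seq_along(vals)) {
    v <- vals[[mi]]
    s <- sd(v[mask])
    if (s <= 0) next
    v <- v / s
    for (ax in 1:3) {
      n <- d[ax]
      take <- function(x, idx) switch(ax, x[idx, , , drop = FALSE],
                                      x[, idx, , drop = FALSE], x[, , idx, drop = FALSE])
      dv <- take(v, 2:n) - take(v, 1:(n - 1))
      dm <- take(mask, 2:n) & take(mask, 1:(n - 1))
      if (!any(dm)) next
      vd <- mean(dv[dm]^2)
      rho <- max(min(1 - vd / 2, 1 - 1e-8), 1e-8)
      sig <- sqrt(-1 / (4 * log(rho)))
      fwhm_vox[mi, ax] <- 2 * sqrt(2 * log(2)) * sig
    }
  }
  fv <- pmax(colMeans(fwhm_vox, na.rm = TRUE), 0.5)
  structure(list(fwhm_vox = fv, fwhm_mm = fv * spacing),
            class = "smoothness_estimate")
}

#' Monte-Carlo minimum cluster size
#'
#' Simulates null statistic fields (white Gaussian noise smoothed to the
#' given FWHM, masked and standardised), thresholds them one-tailed at
#' `voxel_p`, and records the largest suprathreshold cluster per
#' simulation. The returned minimum cluster size is the smallest `k` such
#' that the fraction of simulations whose largest cluster reaches `k` is
#' at most `alpha` - i.e. clusters of at least `min_cluster_size` voxels
#' control the family-wise false-positive rate at `alpha`.
#'
#' @param geometry grid geometry (`dim`, `spacing`).
#' @param mask logical array (analysis mask).
#' @param fwhm_mm per-axis smoothness (mm); below one voxel simulates
#'   unsmoothed noise with a warning.
#' @param voxel_p one-tailed voxel threshold (e.g. 0.01).
#' @param alpha family-wise false-positive rate (e.g. 0.05).
#' @param connectivity 6, 18 or 26.
#' @param n_sim number of null simulations (>= 200).
#' @param seed integer seed.
#' @return an `mc_threshold`: list with `min_cluster_size`, `voxel_p`,
#'   `alpha`, `n_sim`, `connectivity`, `seed`, `max_sizes`.
#' @export
mc_cluster_threshold <- function(geometry, mask, fwhm_mm, voxel_p = 0.01,
                                 alpha = 0.05, connectivity = 6, n_sim = 500,
                                 seed = 1L) {
  stopifnot(voxel_p > 0, voxel_p < 1, alpha > 0, alpha <= 1)
  if (n_sim < 200) stop("n_sim < 200 gives an unstable threshold")
  sigma_vox <- fwhm_mm / geometry$spacing / (2 * sqrt(2 * log(2)))
  if (all(fwhm_mm < geometry$spacing)) {
    warning("FWHM below voxel size; simulating unsmoothed noise")
    sigma_vox <- rep(0, 3)
  }
  zthr <- qnorm(1 - voxel_p)
  d <- geometry$dim
  max_sizes <- integer(n_sim)
  with_seed(as.integer(seed), {
    for (s in seq_len(n_sim)) {
      noise <- array(rnorm(prod(d)), d)
      if (any(sigma_vox > 0)) noise <- cpp_gauss_smooth(noise, sigma_vox)
      vals <- noise[mask]
      z <- (noise - mean(vals)) / sd(vals)
      supra <- z > zthr & mask
      if (!any(supra)) next
      lab <- cpp_label_components(supra, as.integer(connectivity))
      max_sizes[s] <- max(tabulate(lab[lab > 0]))
    }
  })
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  structure(list(min_cluster_size = k, voxel_p = voxel_p, alpha = alpha,
                 n_sim = n_sim, connectivity = connectivity, seed = seed,
                 max_sizes = max_sizes),
            class = "mc_threshold")
}

#' Extract suprathreshold clusters
#'
#' Connected components of the voxels with permutation p below `voxel_p`,
#' under the given connectivity; components smaller than
#' `min_cluster_size` are discarded. The direction label is taken from
#' the map's tail (`greater` = expansion of the tested contrast,
#' `less` = shrinkage).
#'
#' @param pmap a `stat_map` with permutation p-values.
#' @param voxel_p voxel-level threshold.
#' @param min_cluster_size minimum surviving cluster extent (voxels).
#' @param connectivity 6, 18 or 26.
#' @param comparison optional comparison identifier stored with the set.
#' @return a `cluster_set`: list with `clusters` (list of integer voxel
#'   index vectors), `sizes`, `peak_t`, `direction`, `dim`, `comparison`.
#' @export
extract_clusters <- function(pmap, voxel_p = 0.01, min_cluster_size = 1,
                             connectivity = 6, comparison = NULL) {
  if (is.null(pmap$p)) stop("stat_map has no permutation p-values")
  supra <- pmap$p < voxel_p & pmap$mask
  d <- dim(pmap$p)
  direction <- if (pmap$tail == "greater") "expand" else "shrink"
  if (!any(supra)) {
    return(structure(list(clusters = list(), sizes = integer(0),
                          peak_t = numeric(0), direction = direction,
                          dim = d, comparison = comparison),
                     class = "cluster_set"))
  }
  lab <- cpp_label_components(supra, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_cluster_size)
  clusters <- lapply(keep, function(k) which(lab == k))
  structure(list(clusters = clusters,
                 sizes = sizes[keep],
                 peak_t = vapply(clusters, function(ix) {
                   tv <- pmap$t[ix]
                   tv[which.max(abs(tv))]
                 }, numeric(1)),
                 direction = direction, dim = d, comparison = comparison),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", length(x$clusters), " ", x$direction,
      " cluster(s); sizes: ", paste(x$sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Union mask of a cluster set
#' @param cs a `cluster_set`.
#' @return logical array of the set's grid shape.
#' @export
cluster_union_mask <- function(cs) {
  m <- array(FALSE, cs$dim)
  for (ix in cs$clusters) m[ix] <- TRUE
  m
}
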