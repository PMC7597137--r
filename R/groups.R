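# ---- profile groups: cyclic correlation Q, group statistic Z, (Gamma, Z)
# features, nearest-centroid classification ----

# coerce a profile argument to a numeric vector of normalized values
as_profile_vector <- function(p) {
  if (inherits(p, "bls_profile")) p$normalized
  else if (is.numeric(p)) as.numeric(p)
  else abort2("profiles must be bls_profile objects or numeric vectors",
              "blse_invalid_spec")
}

#' Maximal cyclic-shift correlation between two profiles
#'
#' `Q` is the maximum, over all `L` cyclic shifts `s`, of the Pearson
#' correlation between `p1` shifted by `s` and `p2`. Because a cyclic
#' shift changes neither mean nor variance, the whole correlation-vs-shift
#' curve is a circular cross-covariance, computed here in O(L log L) with
#' the FFT.
#'
#' @param p1,p2 profiles of a common length `L >= 3` (numeric vectors or
#'   `bls_profile`s); both must be non-constant.
#' @return `Q` in \[-1, 1\]; symmetric in its arguments.
#' @examples
#' p <- sin(2 * pi * (0:99) / 100)
#' max_shift_correlation(p, c(p[31:100], p[1:30]))  # 1
#' @export
max_shift_correlation <- function(p1, p2) {
  a <- as_profile_vector(p1); b <- as_profile_vector(p2)
  L <- length(a)
  if (length(b) != L) abort2("profiles must have equal length", "blse_length")
  if (L < 3L) abort2("profiles must have length >= 3", "blse_too_small")
  a <- a - mean(a); b <- b - mean(b)
  sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
  if (sa == 0 || sb == 0)
    abort2("correlation undefined for a constant profile", "blse_constant")
  cross <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / L
  min(max(cross / (sa * sb)), 1)
}

check_group <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L)
    abort2("a profile group needs at least 2 profiles", "blse_invalid_spec")
  vs <- lapply(profiles, as_profile_vector)
  if (length(unique(lengths(vs))) != 1L)
    abort2("all profiles in a group must have equal length", "blse_length")
  vs
}

# symmetric matrix of pairwise Q over a list of profile vectors
pairwise_Q <- function(vs) {
  g <- length(vs)
  q <- diag(1, g)
  for (i in seq_len(g - 1L))
    for (j in seq.int(i + 1L, g))
      q[i, j] <- q[j, i] <- max_shift_correlation(vs[[i]], vs[[j]])
  q
}

#' Per-shape mean cyclic correlation within a group
#'
#' For each profile `j` of the group, the mean of `Q` between profile `j`
#' and every *other* profile of the same group (self-comparison excluded).
#'
#' @param profiles list of >= 2 profiles of a common length.
#' @return numeric vector, one mean per profile.
#' @export
group_mean_Q <- function(profiles) {
  vs <- check_group(profiles)
  q <- pairwise_Q(vs)
  diag(q) <- NA_real_
  rowMeans(q, na.rm = TRUE)
}

#' Group homogeneity statistic Z
#'
#' The per-shape mean-Q values of a group are treated as the branch
#' lengths of a star network and `Z = bls_entropy(means) / 10`. Z attains
#' its maximum 0.1 exactly when all members correlate equally with the
#' rest of the group; heterogeneous correlation structure lowers it. The
#' 1/10 prefactor is the printed definition (group size 10); set
#' `prefactor = "size"` to use `1/G` for other group sizes.
#'
#' @param profiles list of >= 2 profiles of a common length.
#' @param prefactor `"ten"` (default; divide by 10) or `"size"` (divide by
#'   the group size).
#' @return Z in (0, 0.1] (or (0, 1/G] with `prefactor = "size"`).
#' @export
group_z <- function(profiles, prefactor = c("ten", "size")) {
  prefactor <- match.arg(prefactor)
  means <- group_mean_Q(profiles)
  bad <- which(means <= 0)
  if (length(bad))
    abort2(sprintf(
      "per-shape mean correlation of shape %d is not positive (%.4g); Z is undefined",
      bad[1L], means[bad[1L]]), "blse_nonpositive_mean")
  denom <- if (prefactor == "ten") 10 else length(means)
  bls_entropy(means) / denom
}

#' (Gamma, Z) feature table for shape groups
#'
#' For each group: the mean and standard deviation of the member shapes'
#' self-similarity `Gamma`, and the group statistic `Z`.
#'
#' @param groups named list; each element is a list of >= 2 profiles
#'   (closed, common length divisible by the window size). Contours are
#'   accepted too and are profiled at their current node count.
#' @param params a `gamma_params`.
#' @return data frame with columns `group_id`, `n`, `gamma_mean`,
#'   `gamma_sd`, `Z`.
#' @export
group_features <- function(groups, params = gamma_params()) {
  if (!is.list(groups) || length(groups) == 0L)
    abort2("groups must be a non-empty list", "blse_invalid_spec")
  ids <- names(groups)
  if (is.null(ids)) ids <- as.character(seq_along(groups))
  rows <- lapply(seq_along(groups), function(g) {
    profs <- lapply(groups[[g]], function(p)
      if (is_contour(p)) entropy_profile(p) else p)
    gam <- vapply(profs, function(p) self_similarity(p, params)$gamma,
                  numeric(1L))
    data.frame(group_id = ids[g], n = length(profs),
               gamma_mean = mean(gam), gamma_sd = stats::sd(gam),
               Z = group_z(profs), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Z of group g's member profiles with an extra profile appended, given the
# full pairwise-Q matrix `q`, member indices `members`, and index `x`
z_with_appended <- function(q, members, x) {
  idx <- c(members, x)
  sub <- q[idx, idx, drop = FALSE]
  diag(sub) <- NA_real_
  means <- rowMeans(sub, na.rm = TRUE)
  if (any(means <= 0))
    abort2("non-positive mean correlation; Z undefined", "blse_nonpositive_mean")
  bls_entropy(means) / 10
}

# shared core of classify / LOO: distance of shape x to each group centroid
# in standardized (Gamma-mean, Z) space. `q` is the pairwise-Q matrix over
# all profiles, `gammas` the per-profile Gamma values, `membership` a list
# of index vectors (training members per group, excluding x).
centroid_distances <- function(q, gammas, membership, x) {
  gm <- vapply(membership, function(m) mean(gammas[m]), numeric(1L))
  zs <- vapply(membership, function(m) {
    if (length(m) < 2L) return(NA_real_)  # singleton group: no Z centroid
    sub <- q[m, m, drop = FALSE]; diag(sub) <- NA_real_
    means <- rowMeans(sub, na.rm = TRUE)
    if (any(means <= 0))
      abort2("non-positive mean correlation; Z undefined", "blse_nonpositive_mean")
    bls_entropy(means) / 10
  }, numeric(1L))
  s_g <- stats::sd(gm); s_z <- stats::sd(zs, na.rm = TRUE)
  if (!is.finite(s_g) || s_g == 0) s_g <- 1
  if (!is.finite(s_z) || s_z == 0) s_z <- 1
  vapply(seq_along(membership), function(g) {
    dg2 <- ((gammas[x] - gm[g]) / s_g)^2
    if (is.na(zs[g])) return(sqrt(dg2))
    zx <- z_with_appended(q, membership[[g]], x)
    sqrt(dg2 + ((zx - zs[g]) / s_z)^2)
  }, numeric(1L))
}

#' Nearest-centroid classification in (Gamma, Z) space
#'
#' Assigns a shape to the group whose (Gamma-mean, Z) centroid is nearest
#' in standardized Euclidean distance. The shape's Gamma coordinate is its
#' own self-similarity; its Z coordinate relative to a candidate group is
#' the Z that group would have with the shape appended, so a shape that
#' correlates like a member leaves Z unchanged while a foreign shape drags
#' it down. Coordinates are standardized by the across-group standard
#' deviations of the training centroids. Ties are resolved toward the
#' earlier group in list order and flagged.
#'
#' @param groups_train named list of >= 2 groups of training profiles
#'   (common length).
#' @param profile the profile to classify (numeric vector or
#'   `bls_profile` of the same length).
#' @param params a `gamma_params`.
#' @return list with `group_id`, `distances` (named), `tie` (logical).
#' @export
nearest_centroid_classify <- function(groups_train, profile,
                                      params = gamma_params()) {
  if (!is.list(groups_train) || length(groups_train) < 2L)
    abort2("need at least 2 training groups", "blse_invalid_spec")
  ids <- names(groups_train)
  if (is.null(ids)) ids <- as.character(seq_along(groups_train))
  vs <- lapply(groups_train, check_group)
  flat <- c(unlist(vs, recursive = FALSE), list(as_profile_vector(profile)))
  if (length(unique(lengths(flat))) != 1L)
    abort2("profile length must match the training profiles", "blse_length")
  q <- pairwise_Q(flat)
  gammas <- vapply(flat, function(v) self_similarity(v, params)$gamma,
                   numeric(1L))
  sizes <- lengths(vs)
  bounds <- cumsum(c(0L, sizes))
  membership <- lapply(seq_along(vs), function(g)
    seq.int(bounds[g] + 1L, bounds[g + 1L]))
  x <- length(flat)
  d <- centroid_distances(q, gammas, membership, x)
  best <- which(d <= min(d) + 1e-12)
  list(group_id = ids[best[1L]], distances = stats::setNames(d, ids),
       tie = length(best) > 1L)
}

#' Leave-one-out evaluation of the (Gamma, Z) classifier
#'
#' Holds out each profile in turn, recomputes every group centroid without
#' it, classifies it with [nearest_centroid_classify]'s rule, and reports
#' the overall and per-group accuracy. Pairwise correlations and Gamma
#' values are computed once and reused across folds.
#'
#' @param groups named list of >= 2 groups of >= 2 profiles each (common
#'   length).
#' @param params a `gamma_params`.
#' @return list with `accuracy`, `per_group` (data frame), `predictions`
#'   (data frame with `group_id`, `member`, `predicted`, `tie`).
#' @export
nearest_centroid_loo <- function(groups, params = gamma_params()) {
  if (!is.list(groups) || length(groups) < 2L)
    abort2("need at least 2 groups", "blse_invalid_spec")
  ids <- names(groups)
  if (is.null(ids)) ids <- as.character(seq_along(groups))
  vs <- lapply(groups, check_group)
  flat <- unlist(vs, recursive = FALSE)
  if (length(unique(lengths(flat))) != 1L)
    abort2("all groups must share one profile length", "blse_length")
  q <- pairwise_Q(flat)
  gammas <- vapply(flat, function(v) self_similarity(v, params)$gamma,
                   numeric(1L))
  sizes <- lengths(vs)
  bounds <- cumsum(c(0L, sizes))
  membership <- lapply(seq_along(vs), function(g)
    seq.int(bounds[g] + 1L, bounds[g + 1L]))
  preds <- lapply(seq_along(flat), function(x) {
    truth <- which(vapply(membership, function(m) x %in% m, logical(1L)))
    mem <- membership
    mem[[truth]] <- setdiff(mem[[truth]], x)
    d <- centroid_distances(q, gammas, mem, x)
    best <- which(d <= min(d) + 1e-12)
    data.frame(group_id = ids[truth],
               member = x - bounds[truth],
               predicted = ids[best[1L]],
               tie = length(best) > 1L, stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, preds)
  hit <- preds$predicted == preds$group_id
  per_group <- stats::aggregate(hit, by = list(group_id = preds$group_id),
                                FUN = mean)
  names(per_group)[2L] <- "accuracy"
  list(accuracy = mean(hit), per_group = per_group, predictions = preds)
}
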