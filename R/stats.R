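#' Cluster-based permutation test for two groups
#'
#' Point-wise two-sample t-values (pooled variance) on a 1-D (time or
#' frequency) or 2-D (time x frequency) grid are thresholded at the
#' two-sided t quantile for `cluster_alpha`; contiguous supra-threshold
#' points of the same sign (orthogonal adjacency in 2-D) form clusters
#' whose mass is the sum of t-values. The null distribution of the
#' maximum absolute cluster mass is built by randomly relabelling group
#' membership; each observed cluster gets
#' p = (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param groupA,groupB numeric matrices `subjects x grid` (a 2-D grid is
#'   passed flattened, with `grid_dims` giving its shape).
#' @param n_perm number of permutations (default 5000). If the number of
#'   distinct relabellings is smaller, all of them are enumerated exactly.
#' @param cluster_alpha two-sided alpha defining the cluster-forming t
#'   threshold.
#' @param grid_dims integer vector of grid dimensions for 2-D grids
#'   (default: 1-D, `ncol(groupA)`).
#' @param seed integer seed for the permutation RNG.
#' @return a `cluster_stat` object: list with `clusters` (data.frame:
#'   id, mass, size, p_value; member indices in `members`), `t_obs`,
#'   `threshold`, `n_perm`.
#' @export
cluster_permutation_test <- function(groupA, groupB, n_perm = 5000,
                                     cluster_alpha = 0.05, grid_dims = NULL,
                                     seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  nA <- nrow(groupA); nB <- nrow(groupB)
  if (nA < 2 || nB < 2) stop("need >= 2 subjects per group")
  X <- rbind(groupA, groupB)
  G <- ncol(X)
  if (is.null(grid_dims)) grid_dims <- G
  stopifnot(prod(grid_dims) == G)
  n <- nA + nB
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 2)
  t_obs <- two_sample_t(X, seq_len(nA))
  obs <- cluster_masses(t_obs, thr, grid_dims)
  # permutation null of the max |cluster mass|
  combos <- choose(n, nA)
  exhaustive <- is.finite(combos) && combos <= n_perm
  set.seed(seed)
  labels_list <- if (exhaustive) {
    apply(utils::combn(n, nA), 2, identity, simplify = FALSE)
  } else {
    lapply(seq_len(n_perm), function(i) sample.int(n, nA))
  }
  null_max <- vapply(labels_list, function(idxA) {
    tt <- two_sample_t(X, idxA)
    cl <- cluster_masses(tt, thr, grid_dims)
    if (length(cl$mass) == 0) 0 else max(abs(cl$mass))
  }, numeric(1))
  B <- length(null_max)
  # random sampling adds the observed labelling ((1+b)/(1+B)); exhaustive
  # enumeration already contains it, so p = b/B
  p <- if (exhaustive)
    vapply(obs$mass, function(m) sum(null_max >= abs(m) - 1e-12) / B, numeric(1))
  else
    vapply(obs$mass, function(m) (1 + sum(null_max >= abs(m))) / (1 + B),
           numeric(1))
  clusters <- data.frame(id = seq_along(obs$mass), mass = obs$mass,
                         size = lengths(obs$members), p_value = p)
  structure(list(clusters = clusters, members = obs$members, t_obs = t_obs,
                 threshold = thr, n_perm = B, exhaustive = exhaustive,
                 grid_dims = grid_dims),
            class = "cluster_stat")
}

#' @export
print.cluster_stat <- function(x, ...) {
  cat(sprintf("<cluster_stat> %d cluster(s), %d permutations%s\n",
              nrow(x$clusters), x$n_perm,
              if (x$exhaustive) " (exhaustive)" else ""))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

# pooled-variance two-sample t per grid point; zero-variance points get 0
two_sample_t <- function(X, idxA) {
  A <- X[idxA, , drop = FALSE]
  B <- X[-idxA, , drop = FALSE]
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- (colSums(A^2) - nA * mA^2) / (nA - 1)
  vB <- (colSums(B^2) - nB * mB^2) / (nB - 1)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- numeric(length(se))
  ok <- se > 0
  t[ok] <- (mA[ok] - mB[ok]) / se[ok]
  t
}

# clusters of same-sign supra-threshold points; returns masses and members
cluster_masses <- function(t, thr, grid_dims) {
  mass <- numeric(0)
  members <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) t > thr else t < -thr
    if (!any(mask)) next
    labs <- label_components(mask, grid_dims)
    for (lab in seq_len(max(labs))) {
      idx <- which(labs == lab)
      mass <- c(mass, sum(t[idx]))
      members <- c(members, list(idx))
    }
  }
  list(mass = mass, members = members)
}

# connected components of a logical mask on a 1-D or 2-D grid
# (orthogonal adjacency); returns integer labels, 0 = background
label_components <- function(mask, grid_dims) {
  if (length(grid_dims) == 1) {
    labs <- integer(length(mask))
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    lab <- 0L
    for (i in which(r$values)) {
      lab <- lab + 1L
      labs[starts[i]:ends[i]] <- lab
    }
    return(labs)
  }
  nr <- grid_dims[1]; nc <- grid_dims[2]
  m <- matrix(mask, nr, nc)
  labs <- matrix(0L, nr, nc)
  lab <- 0L
  for (start in which(m & labs == 0L)) {
    if (labs[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labs[start] <- lab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        nb <- (jj - 1L) * nr + ii
        if (m[nb] && labs[nb] == 0L) {
          labs[nb] <- lab
          queue <- c(queue, nb)
        }
      }
    }
  }
  as.integer(labs)
}

#' Permutation GLM with maximum-t family-wise correction
#'
#' Fits an ordinary-least-squares GLM per outcome, forms the contrast of
#' parameter estimates (COPE = contrast . coefficients) and its t
#' statistic, and corrects across outcomes with the permutation
#' distribution of the maximum |t| under the Freedman-Lane scheme: the
#' confound-only model is fitted, its residuals are row-permuted, the full
#' model is refitted on the permuted residuals, and the maximum |t| across
#' outcomes is recorded per permutation. Corrected
#' p = (1 + #\{max-null >= |t_obs|\}) / (1 + n_perm). With <= `n_perm`
#' distinct row permutations the enumeration is exhaustive.
#'
#' @param outcomes numeric matrix `subjects x outcomes`.
#' @param design numeric design matrix `subjects x regressors`, full
#'   column rank (e.g. intercept, group indicator, age, sex, missing-MRI).
#' @param contrast numeric contrast vector, one weight per regressor; the
#'   permuted (tested) component is the set of columns with non-zero
#'   weight, the rest are treated as confounds.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @return a `glm_result` data.frame: outcome, cope, t, df, p_uncorrected,
#'   p_corrected.
#' @export
permutation_glm_maxt <- function(outcomes, design, contrast, n_perm = 5000,
                                 seed = 1) {
  outcomes <- as.matrix(outcomes)
  design <- as.matrix(design)
  n <- nrow(outcomes)
  stopifnot(nrow(design) == n, length(contrast) == ncol(design))
  if (qr(design)$rank < ncol(design))
    stop("design matrix is rank deficient; drop collinear regressors")
  X <- design
  XtXi <- solve(crossprod(X))
  cvar <- drop(t(contrast) %*% XtXi %*% contrast)
  df <- n - ncol(X)
  glm_t <- function(Y) {
    B <- XtXi %*% crossprod(X, Y)
    resid <- Y - X %*% B
    sigma2 <- colSums(resid^2) / df
    cope <- drop(contrast %*% B)
    se <- sqrt(sigma2 * cvar)
    t <- ifelse(se > 0, cope / se, 0)
    list(cope = cope, t = t)
  }
  obs <- glm_t(outcomes)
  # Freedman-Lane: residualize outcomes on the confound columns
  conf <- which(contrast == 0)
  Z <- design[, conf, drop = FALSE]
  Rz <- if (ncol(Z) > 0) {
    H <- Z %*% solve(crossprod(Z)) %*% t(Z)
    outcomes - H %*% outcomes
  } else outcomes
  exhaustive <- n <= 8 && factorial(n) <= n_perm
  set.seed(seed)
  perms <- if (exhaustive) all_permutations(n)
           else lapply(seq_len(n_perm), function(i) sample.int(n))
  m <- ncol(outcomes)
  null_t <- matrix(vapply(perms, function(p) abs(glm_t(Rz[p, , drop = FALSE])$t),
                          numeric(m)), nrow = m)   # outcomes x permutations
  null_max <- apply(null_t, 2, max)
  B <- length(null_max)
  if (exhaustive) {  # identity permutation is already in the enumeration
    p_corr <- vapply(obs$t, function(tt)
      sum(null_max >= abs(tt) - 1e-12) / B, numeric(1))
    p_unc <- vapply(seq_len(m), function(j)
      sum(null_t[j, ] >= abs(obs$t[j]) - 1e-12) / B, numeric(1))
  } else {
    p_corr <- vapply(obs$t, function(tt) (1 + sum(null_max >= abs(tt))) / (1 + B),
                     numeric(1))
    p_unc <- vapply(seq_len(m), function(j)
      (1 + sum(null_t[j, ] >= abs(obs$t[j]))) / (1 + B), numeric(1))
  }
  res <- data.frame(
    outcome = if (!is.null(colnames(outcomes))) colnames(outcomes)
              else paste0("y", seq_len(ncol(outcomes))),
    cope = obs$cope, t = obs$t, df = df,
    p_uncorrected = p_unc, p_corrected = pmax(p_corr, p_unc))
  class(res) <- c("glm_result", "data.frame")
  attr(res, "n_perm") <- B
  attr(res, "exhaustive") <- exhaustive
  res
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- list()
  for (p in sub) for (k in seq_len(n))
    out[[length(out) + 1]] <- append(p, n, after = k - 1)
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t with Satterthwaite degrees of freedom and two-sided
#' p. Accepts either summary statistics (mean, sd, n per group) or two raw
#' sample vectors.
#'
#' @param m1,s1,n1 mean, sd, n of group 1 — or `m1` a raw sample vector
#'   and `s1` the second sample vector.
#' @param m2,s2,n2 mean, sd, n of group 2 (summary form only).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(m1, s1, n1 = NULL, m2 = NULL, s2 = NULL, n2 = NULL) {
  if (is.null(n1)) {  # raw-sample form: welch_t(x, y)
    x <- m1; y <- s1
    return(welch_t(mean(x), stats::sd(x), length(x),
                   mean(y), stats::sd(y), length(y)))
  }
  stopifnot(n1 >= 2, n2 >= 2)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-squared test on a contingency table
#'
#' @param table integer matrix of counts; all marginals must be positive.
#' @param yates apply Yates continuity correction (default FALSE).
#' @return list with `chisq`, `df`, `p`.
#' @export
chi_squared <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  ct <- stats::chisq.test(table, correct = yates)
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Pearson correlation with two-sided t-based p
#'
#' @param x,y numeric vectors of length >= 3 with positive variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bonferroni adjustment
#'
#' @param pvalues numeric p-values in 0-1.
#' @param n_comparisons number of comparisons in the family.
#' @return `min(1, p * n_comparisons)` elementwise.
#' @export
bonferroni_adjust <- function(pvalues, n_comparisons) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  pmin(1, pvalues * n_comparisons)
}
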