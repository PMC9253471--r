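#' TFCE configuration
#'
#' Standard 3-D threshold-free cluster enhancement parameters: height
#' exponent `H = 2`, extent exponent `E = 0.5`, integration step
#' `dh = 0.1`, 26-connectivity.
#'
#' @param H,E Height and extent exponents (>= 0).
#' @param dh Threshold integration step (> 0).
#' @param connectivity 6, 18 or 26.
#' @return A `tfce_config` list.
#' @export
tfce_config <- function(H = 2, E = 0.5, dh = 0.1, connectivity = 26L) {
  if (H < 0 || E < 0) stop("`H` and `E` must be >= 0")
  if (dh <= 0) stop("`dh` must be > 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  structure(list(H = H, E = E, dh = dh,
                 connectivity = as.integer(connectivity)),
            class = "tfce_config")
}

#' Threshold-free cluster enhancement
#'
#' For every voxel, integrates `extent(h)^E * h^H * dh` over thresholds
#' `h = dh, 2dh, ...` up to the voxel's statistic value, where `extent(h)`
#' is the size of the connected component containing the voxel at
#' threshold `h`. Negative statistic values are enhanced on the negated
#' map and returned with negative sign, so the output preserves the
#' direction of effects.
#'
#' @param stat_map 3-D statistic array (finite inside the mask).
#' @param mask Binary 3-D analysis mask (nonempty), same dims.
#' @param cfg A [tfce_config()].
#' @return 3-D array of signed enhanced values.
#' @export
tfce <- function(stat_map, mask, cfg = tfce_config()) {
  d <- dim(stat_map)
  if (is.null(d) || length(d) != 3L) stop("`stat_map` must be 3-D")
  if (!all(dim(mask) == d)) stop("mask/stat dimension mismatch")
  mlog <- as.logical(mask != 0)
  if (!any(mlog)) stop("empty analysis mask")
  if (any(!is.finite(stat_map[mlog])))
    stop("`stat_map` must be finite inside the mask")
  pos <- tfce_cpp(pmax(as.numeric(stat_map), 0), as.integer(d), mlog,
                  cfg$H, cfg$E, cfg$dh, cfg$connectivity)
  neg <- tfce_cpp(pmax(-as.numeric(stat_map), 0), as.integer(d), mlog,
                  cfg$H, cfg$E, cfg$dh, cfg$connectivity)
  array(pos - neg, dim = d)
}

#' Build the voxel-wise GLM design matrix
#'
#' Intercept + z-scored serum NfL, with z-scored age and disease duration,
#' a sex indicator, and phenotype-by-treatment combinations expanded to
#' indicator columns as unique conditions (reference = first observed
#' combination); combinations absent from the sample are dropped by
#' construction since only observed levels generate columns. The design is
#' checked for full column rank.
#'
#' @param records Baseline records, one per subject, NfL outliers already
#'   removed upstream.
#' @return List with `X` (n x p matrix), `contrast` (+NfL contrast vector;
#'   negate for the negative contrast), `nfl_col`, `rank`, `combos`
#'   (observed phenotype x treatment combinations).
#' @export
build_design <- function(records) {
  df <- as.data.frame(records)
  cols <- list(`(Intercept)` = rep(1, nrow(df)),
               snfl_z = zscore(df$snfl))
  if ("age" %in% names(df) && stats::sd(df$age) > 0)
    cols$age_z <- zscore(df$age)
  if ("disease_duration" %in% names(df) &&
      stats::sd(df$disease_duration) > 0)
    cols$duration_z <- zscore(df$disease_duration)
  if ("sex" %in% names(df) && length(unique(df$sex)) > 1L)
    cols$sexM <- as.numeric(df$sex == "M")
  combos <- character(0)
  if (all(c("phenotype", "treatment") %in% names(df))) {
    combo <- interaction(df$phenotype, df$treatment, drop = TRUE, sep = ":")
    combos <- levels(combo)
    if (length(combos) > 1L)
      for (lv in combos[-1L])
        cols[[paste0("combo_", lv)]] <- as.numeric(combo == lv)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  contrast <- as.numeric(colnames(X) == "snfl_z")
  list(X = X, contrast = contrast, nfl_col = which(contrast == 1),
       rank = qx$rank, combos = combos)
}

#' Per-voxel GLM t-statistics
#'
#' Ordinary least squares at every voxel of `Y` for a single contrast:
#' `t(v) = c'beta(v) / sqrt(sigma2(v) c'(X'X)^-1 c)`. Voxels with zero
#' residual variance get `t = 0` and are reported in the `degenerate`
#' attribute.
#'
#' @param Y n x V response matrix (subjects x voxels), rows aligned to `X`.
#' @param X n x p design matrix of full column rank.
#' @param contrast Length-p contrast vector.
#' @return Numeric vector of V t-values with attribute `degenerate`
#'   (indices of zero-variance voxels).
#' @export
glm_tmap <- function(Y, X, contrast) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("rows of Y must align with X")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than design columns")
  XtXi <- solve(crossprod(X))
  A <- XtXi %*% t(X)
  B <- A %*% Y
  res <- Y - X %*% B
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  cvar <- drop(t(contrast) %*% XtXi %*% contrast)
  num <- drop(t(contrast) %*% B)
  denom <- sqrt(sigma2 * cvar)
  degenerate <- which(denom <= sqrt(.Machine$double.eps) * abs(num) |
                        sigma2 <= .Machine$double.eps)
  t <- num / denom
  t[degenerate] <- 0
  attr(t, "degenerate") <- degenerate
  t
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      row <- integer(n)
      row[pos] <- n
      row[-pos] <- sub[i, ]
      out[r, ] <- row
    }
  }
  out
}

#' Permutation inference with TFCE and FWER control
#'
#' Mass-univariate test of a single contrast over a stack of subject maps,
#' with Freedman-Lane permutation of reduced-model residuals, TFCE of each
#' permuted t-map, and max-statistic family-wise error correction. Both
#' the positive and the negative NfL contrast are tested, each at the
#' stated FWER level. When every distinct relabelling can be enumerated
#' (n! <= `n_perm`) the full permutation group is used instead of random
#' sampling (and a message is emitted).
#'
#' @param Y n x V matrix of subject responses at the V mask voxels
#'   (column v corresponds to the v-th TRUE voxel of `mask` in array
#'   order).
#' @param X Design matrix (see [build_design()]).
#' @param contrast Contrast vector for the positive association; its
#'   negation is tested as the second contrast.
#' @param mask Binary 3-D analysis mask with exactly V nonzero voxels
#'   (gives the geometry for TFCE connectivity).
#' @param n_perm Number of permutations (default 5000).
#' @param cfg A [tfce_config()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @param alpha FWER level for the significance masks (default 0.05).
#' @return A `voxelwise_result`: `t_map`, per-contrast `tfce_obs`,
#'   `null_max` (length `n_perm`), `fwer_p`, `significant` (p < alpha),
#'   all as vectors over the V mask voxels, plus `mask`, `n_perm`,
#'   `exhaustive`.
#' @export
permutation_fwer <- function(Y, X, contrast, mask, n_perm = 5000L,
                             cfg = tfce_config(), seed = 1L, alpha = 0.05) {
  if (n_perm < 1L) stop("`n_perm` must be >= 1")
  if (is.null(seed)) stop("`seed` must be set")
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(X)
  mlog <- as.logical(mask != 0)
  V <- sum(mlog)
  if (ncol(Y) != V)
    stop("ncol(Y) must equal the number of nonzero mask voxels")
  d <- dim(mask)

  if (sum(contrast != 0) != 1L)
    stop("`contrast` must select exactly one design column ",
         "(Freedman-Lane reduced model = the remaining columns)")
  # Freedman-Lane: reduced model = nuisance columns (contrast == 0)
  nuis <- which(contrast == 0)
  Z <- X[, nuis, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Ez <- Y - Hz %*% Y          # reduced-model residuals
  Fz <- Hz %*% Y              # reduced-model fitted values

  exhaustive <- FALSE
  nfact <- suppressWarnings(factorial(n))
  if (is.finite(nfact) && nfact <= n_perm) {
    perms <- all_permutations(n)
    n_perm <- nrow(perms)
    exhaustive <- TRUE
    message(sprintf(
      "all %d distinct relabelings enumerable: exhaustive permutation", n_perm))
  } else {
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(n)))
  }

  tfce_vec <- function(tvals) {
    vol <- array(0, dim = d)
    vol[mlog] <- tvals
    enh <- tfce_cpp(pmax(as.numeric(vol), 0), as.integer(d), mlog,
                    cfg$H, cfg$E, cfg$dh, cfg$connectivity)
    enh[mlog]
  }

  t_obs <- glm_tmap(Y, X, contrast)
  obs_pos <- tfce_vec(t_obs)
  obs_neg <- tfce_vec(-t_obs)

  null_pos <- numeric(n_perm)
  null_neg <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    Yb <- Fz + Ez[perms[b, ], , drop = FALSE]
    tb <- glm_tmap(Yb, X, contrast)
    null_pos[b] <- max(tfce_vec(tb))
    null_neg[b] <- max(tfce_vec(-tb))
  }
  p_pos <- vapply(obs_pos, function(o) (1 + sum(null_pos >= o)) /
                    (1 + n_perm), numeric(1))
  p_neg <- vapply(obs_neg, function(o) (1 + sum(null_neg >= o)) /
                    (1 + n_perm), numeric(1))
  structure(list(t_map = as.numeric(t_obs),
                 tfce_obs = list(positive = obs_pos, negative = obs_neg),
                 null_max = list(positive = null_pos, negative = null_neg),
                 fwer_p = list(positive = p_pos, negative = p_neg),
                 significant = list(positive = p_pos < alpha,
                                    negative = p_neg < alpha),
                 mask = mask, n_perm = n_perm, exhaustive = exhaustive,
                 alpha = alpha),
            class = "voxelwise_result")
}

#' @export
print.voxelwise_result <- function(x, ...) {
  cat(sprintf(
    "<voxelwise_result: %d mask voxels, %d permutations%s; sig+ %d, sig- %d at FWER %g>\n",
    length(x$t_map), x$n_perm, if (x$exhaustive) " (exhaustive)" else "",
    sum(x$significant$positive), sum(x$significant$negative), x$alpha))
  invisible(x)
}

#' Embed a mask-voxel vector back into a 3-D volume
#'
#' @param values Vector over the nonzero voxels of `mask` (array order).
#' @param mask Binary 3-D mask.
#' @param fill Background value.
#' @return 3-D array.
#' @export
unmask <- function(values, mask, fill = 0) {
  vol <- array(fill, dim = dim(mask))
  vol[mask != 0] <- values
  vol
}
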