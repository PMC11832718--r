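#' Response transforms for the cognition GLMs
#'
#' Maps raw cognition outcomes onto the model's linear-predictor scale:
#' the IQ index is z-scored (sample mean 0, variance 1, n-1 SD); SOC
#' mean moves is inverted (`y = 1 / SOCmove`); SOC problems solved in
#' minimum moves is reflected-log transformed
#' (`y = log(max(SOCprob) - SOCprob + offset)`, `max` taken over the
#' sample). A subject solving the sample maximum would hit `log(0)`;
#' with the default `offset = 0` such data trigger a warning and a
#' half-count offset of 0.5 is used instead (configurable).
#'
#' @param table cognition data frame with columns `IST60`,
#'   `SOC_moves_4`, `SOC_prob_min` as needed.
#' @param response_id `"IQ"`, `"SOCmove"` or `"SOCprob"`.
#' @param socprob_offset offset added inside the reflected log.
#' @param socprob_max reference maximum for the reflection; defaults to
#'   the sample maximum. Supplying the instrument maximum (12 problems)
#'   avoids the degenerate `log(0)` whenever no subject attains it.
#' @return numeric response vector; attributes carry what is needed to
#'   invert the transform (`center`/`scale` for IQ, `max_val`/`offset`
#'   for SOCprob).
#' @export
transform_response <- function(table, response_id = c("IQ", "SOCmove", "SOCprob"),
                               socprob_offset = 0, socprob_max = NULL) {
  response_id <- match.arg(response_id)
  switch(response_id,
    IQ = {
      x <- need_col(table, "IST60")
      m <- mean(x); s <- sd(x)
      if (s == 0) stop("IQ index has zero variance; cannot z-score")
      structure((x - m) / s, center = m, scale = s)
    },
    SOCmove = {
      x <- need_col(table, "SOC_moves_4")
      if (any(x <= 0)) stop("SOC mean moves must be positive")
      1 / x
    },
    SOCprob = {
      x <- need_col(table, "SOC_prob_min")
      mx <- if (is.null(socprob_max)) max(x) else socprob_max
      off <- socprob_offset
      if (off == 0 && any(x == mx)) {
        warning("some subjects solved the sample maximum; using a ",
                "half-count offset of 0.5 inside the reflected log")
        off <- 0.5
      }
      structure(log(mx - x + off), max_val = mx, offset = off)
    })
}

need_col <- function(table, col) {
  if (!col %in% names(table)) stop("cognition table lacks column '", col, "'")
  table[[col]]
}

#' Back-transforms of the GLM responses
#'
#' Inverts [transform_response()]: the expected IQ index is recovered
#' from its z-score via the stored centre/scale, SOC mean moves as the
#' reciprocal of the linear predictor, and SOC problems solved as
#' `max(SOCprob) - exp(X beta)` (plus the offset if one was used). These
#' are the interpretation rules for fitted coefficients: for SOCmove a
#' positive coefficient means fewer moves (better planning), for SOCprob
#' a positive coefficient means fewer problems solved (worse planning).
#'
#' @param y transformed response / linear predictor.
#' @param response_id `"IQ"`, `"SOCmove"` or `"SOCprob"`.
#' @param center,scale IQ z-score parameters (default: attributes of
#'   `y`).
#' @param max_val,offset SOCprob reflection parameters (default:
#'   attributes of `y`).
#' @return numeric vector on the raw outcome scale.
#' @export
back_transform_response <- function(y, response_id = c("IQ", "SOCmove", "SOCprob"),
                                    center = attr(y, "center"),
                                    scale = attr(y, "scale"),
                                    max_val = attr(y, "max_val"),
                                    offset = attr(y, "offset")) {
  response_id <- match.arg(response_id)
  switch(response_id,
    IQ = {
      if (is.null(center) || is.null(scale))
        stop("IQ back-transform needs 'center' and 'scale'")
      as.numeric(center + scale * y)
    },
    SOCmove = 1 / as.numeric(y),
    SOCprob = {
      if (is.null(max_val)) stop("SOCprob back-transform needs 'max_val'")
      if (is.null(offset)) offset <- 0
      max_val + offset - exp(as.numeric(y))
    })
}

#' Build the GLM design matrix
#'
#' Expands the entrainment-feature design shared by all three cognition
#' models: a global intercept; the main effects `alpha_am`,
#' `alpha_itpc`, `sigma_am`, `sigma_itpc`; and, within each group level
#' (Wilkinson `group * x = group + x + group:x`, expanded per level), a
#' group indicator plus group-specific slopes for `A_am`, `mu_am`,
#' `A_am:mu_am`, `A_itpc`, `mu_itpc`, `A_itpc:mu_itpc` and `power`.
#' Only the magnitude-by-latency interactions enter, mirroring the
#' model's focus on `A`, `mu` and their product. The two group
#' indicators sum to the intercept column; [fit_glm()] resolves that
#' rank deficiency by dropping one indicator, which reproduces the
#' conventional "global intercept + one group intercept" reporting.
#'
#' @param features feature table (see [simulate_feature_table()] for the
#'   column contract) with a two-level `group` factor.
#' @param formula_id `"IQ"`, `"SOCmove"` or `"SOCprob"` (the three
#'   models share the design; the argument documents intent and keeps
#'   the interface explicit).
#' @return list with `X` (model matrix) and `terms` (column names).
#' @export
build_design <- function(features, formula_id = c("IQ", "SOCmove", "SOCprob")) {
  formula_id <- match.arg(formula_id)
  g <- factor(features$group)
  if (nlevels(g) != 2) stop("'group' must have exactly two levels")
  need <- c("A_am", "mu_am", "sigma_am", "alpha_am",
            "A_itpc", "mu_itpc", "sigma_itpc", "alpha_itpc", "power")
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols))
    stop("feature table is missing predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(features)
  X <- cbind("(Intercept)" = rep(1, n),
             alpha_am = features$alpha_am, alpha_itpc = features$alpha_itpc,
             sigma_am = features$sigma_am, sigma_itpc = features$sigma_itpc)
  for (lev in levels(g)) {
    ind <- as.numeric(g == lev)
    blk <- cbind(ind,
                 ind * features$A_am, ind * features$mu_am,
                 ind * features$A_am * features$mu_am,
                 ind * features$A_itpc, ind * features$mu_itpc,
                 ind * features$A_itpc * features$mu_itpc,
                 ind * features$power)
    colnames(blk) <- paste0(c("group", "A_am:", "mu_am:", "A_am:mu_am:",
                              "A_itpc:", "mu_itpc:", "A_itpc:mu_itpc:",
                              "power:"), lev)
    X <- cbind(X, blk)
  }
  list(X = X, terms = colnames(X))
}

#' Fit a Gaussian GLM on a prepared design
#'
#' Ordinary least squares (Gaussian family, identity link on the
#' already-transformed response) with per-term standard errors,
#' t statistics and two-sided p values, plus the overall model tests
#' reported against the intercept-only model: the F statistic and, as
#' the deviance-based alternative, the likelihood-ratio chi-squared.
#' Exactly collinear columns are dropped with a warning naming them
#' (pivoted QR), and the design's condition number is reported.
#'
#' @param X design matrix (e.g. from [build_design()]).
#' @param y numeric response vector.
#' @return object of class `"assr_glm"`: list with `terms` (data frame:
#'   term, estimate, se, t, p), `r2`, `loglik`, `fstat`, `f_df`, `f_p`,
#'   `chi2`, `chi2_df`, `chi2_p`, `n`, `rank`, `dropped`, `condition`.
#' @export
fit_glm <- function(X, y) {
  if (is.list(X) && !is.null(X$X)) X <- X$X
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length of 'y' must match rows of 'X'")
  qrx <- qr(X)
  r <- qrx$rank
  dropped <- character(0)
  if (r < ncol(X)) {
    keep <- qrx$pivot[seq_len(r)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("rank-deficient design; dropped: ", paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
    qrx <- qr(X)
    r <- qrx$rank
  }
  if (n <= r) stop("need more observations than estimated terms")
  sv <- svd(X, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[length(sv)]
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  df_res <- n - r
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(qr.R(qrx)[seq_len(r), seq_len(r)])
  # undo pivoting of qr.R for SE lookup
  piv <- qrx$pivot[seq_len(r)]
  se <- sqrt(sigma2 * diag(XtXinv))[order(piv)]
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df_res)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  has_int <- any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))
  df_model <- r - as.integer(has_int)
  fstat <- f_p <- chi2 <- chi2_p <- NA_real_
  if (df_model > 0 && tss > rss) {
    fstat <- ((tss - rss) / df_model) / (rss / df_res)
    f_p <- pf(fstat, df_model, df_res, lower.tail = FALSE)
    chi2 <- n * log(tss / rss)          # LR statistic vs intercept-only
    chi2_p <- pchisq(chi2, df_model, lower.tail = FALSE)
  }
  structure(list(
    terms = data.frame(term = colnames(X), estimate = unname(beta),
                       se = unname(se), t = unname(tval), p = unname(pval)),
    r2 = r2, loglik = loglik,
    fstat = fstat, f_df = c(df_model, df_res), f_p = f_p,
    chi2 = chi2, chi2_df = df_model, chi2_p = chi2_p,
    n = n, rank = r, dropped = dropped, condition = cond,
    rss = rss, fitted = fitted),
    class = "assr_glm")
}

#' @export
print.assr_glm <- function(x, digits = 3, ...) {
  cat(sprintf("<assr_glm> n=%d, R2=%.3f, loglik=%.1f, F(%d,%d)=%.3g (p=%.3g), chi2=%.3g (p=%.3g)\n",
              x$n, x$r2, x$loglik, x$f_df[1], x$f_df[2], x$fstat, x$f_p,
              x$chi2, x$chi2_p))
  print(format(x$terms, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Two-sample location tests
#'
#' Classical two-sided two-sample tests used for the group comparisons:
#' the pooled-variance t test for normally distributed scores and the
#' Wilcoxon rank-sum test for skewed ones. The rank-sum test uses exact
#' enumeration when the smaller sample has at most 8 observations and
#' there are no ties, and the normal approximation with tie/continuity
#' correction otherwise. When both samples are constant and equal, the
#' t statistic is reported as 0 with p = 1 and a `degenerate` flag.
#'
#' @param x,y numeric samples.
#' @param kind `"t"` or `"ranksum"`.
#' @return list with `statistic`, `p`, `kind`, `degenerate`.
#' @export
two_sample_tests <- function(x, y, kind = c("t", "ranksum")) {
  kind <- match.arg(kind)
  if (kind == "t") {
    if (length(x) < 2 || length(y) < 2)
      stop("the t test needs at least 2 observations per sample")
    if (var(x) == 0 && var(y) == 0) {
      if (mean(x) == mean(y))
        return(list(statistic = 0, p = 1, kind = "t", degenerate = TRUE))
      return(list(statistic = sign(mean(x) - mean(y)) * Inf, p = 0,
                  kind = "t", degenerate = TRUE))
    }
    ht <- t.test(x, y, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p = ht$p.value, kind = "t",
         degenerate = FALSE)
  } else {
    if (length(x) < 1 || length(y) < 1)
      stop("the rank-sum test needs at least 1 observation per sample")
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- min(length(x), length(y)) <= 8 && !ties
    ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    list(statistic = unname(ht$statistic), p = ht$p.value, kind = "ranksum",
         degenerate = FALSE)
  }
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level.
#' @param m number of tests in the family (user supplied, >= 1).
#' @return per-test threshold `alpha / m`.
#' @examples
#' bonferroni(0.05, 16)  # 0.003125
#' @export
bonferroni <- function(alpha = 0.05, m = 1) {
  if (m < 1 || m != round(m)) stop("'m' must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  alpha / m
}

#' Channel-wise permutation test on topographies
#'
#' For each channel, the observed statistic is the difference of group
#' means of the per-subject topography values; its two-sided p value is
#' estimated by shuffling group labels, with the add-one estimator
#' `p = (1 + #(|perm| >= |obs|)) / (1 + n_perm)` so p is always in
#' `(0, 1]`. No multiplicity correction is applied: these maps are
#' exploratory and channels with raw p < 0.05 are highlighted.
#'
#' @param groupA,groupB numeric matrices, subjects x channels, with the
#'   same channel sets (columns).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed (reproducible for identical inputs).
#' @return named per-channel p-value vector, with the observed mean
#'   differences as attribute `"statistic"`.
#' @export
permutation_topography <- function(groupA, groupB, n_perm = 1000, seed = 1L) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) != ncol(groupB))
    stop("both groups must have the same channel set")
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop("each group needs at least 2 subjects")
  if (n_perm < 100) stop("'n_perm' must be at least 100")
  nA <- nrow(groupA)
  comb <- rbind(groupA, groupB)
  obs <- colMeans(groupA) - colMeans(groupB)
  with_seed(seed, {
    count <- numeric(ncol(comb))
    for (i in seq_len(n_perm)) {
      idx <- sample.int(nrow(comb), nA)
      stat <- colMeans(comb[idx, , drop = FALSE]) -
              colMeans(comb[-idx, , drop = FALSE])
      count <- count + (abs(stat) >= abs(obs))
    }
    p <- (1 + count) / (1 + n_perm)
    names(p) <- colnames(comb)
    attr(p, "statistic") <- obs
    p
  })
}
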