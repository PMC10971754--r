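#' Screen topology features for multicollinearity
#'
#' Keeps the study's candidate list — total nodes, total edges, positive to
#' negative edge ratio, average path length, modularity, average degree,
#' heterogeneity, clustering coefficient — in that fixed order (the sign-
#' specific edge counts are excluded a priori: together they determine total
#' edges and the ratio). Constant features are dropped, then for any pair
#' with `|Pearson r| > r_max` the later feature is dropped greedily.
#'
#' @param features data.frame/matrix of replicate-by-metric values (e.g.
#'   `ensemble_result$records`).
#' @param r_max collinearity cutoff (default 0.9).
#' @param candidates feature order to consider; defaults to the standard
#'   eight.
#' @return Character vector of retained feature names; dropped ones in
#'   `attr(, "dropped")`.
#' @export
multicollinearity_screen <- function(features, r_max = 0.9,
                                     candidates = c(
                                       "total_nodes", "total_edges",
                                       "pos_neg_ratio",
                                       "average_path_length", "modularity",
                                       "average_degree", "heterogeneity",
                                       "clustering_coefficient")) {
  features <- as.data.frame(features)
  cand <- intersect(candidates, colnames(features))
  if (length(cand) < 2) stop("need at least 2 candidate features")
  X <- features[, cand, drop = FALSE]
  dropped <- character(0)
  const <- vapply(X, function(v) sd(v, na.rm = TRUE) == 0 ||
                    all(is.na(v)), logical(1))
  dropped <- c(dropped, cand[const])
  cand <- cand[!const]
  keep <- character(0)
  for (f in cand) {
    coll <- FALSE
    for (g in keep) {
      r <- suppressWarnings(cor(features[[f]], features[[g]],
                                use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) > r_max) { coll <- TRUE; break }
    }
    if (coll) dropped <- c(dropped, f) else keep <- c(keep, f)
  }
  attr(keep, "dropped") <- dropped
  keep
}

# negative log-likelihood and gradient of the proportional-odds model,
# parameters par = c(beta (k), theta (J-1)), logit P(Y<=j|x) = theta_j - x b
polr_nll <- function(par, X, yi, J) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  theta <- par[k + seq_len(J - 1)]
  eta <- if (k) drop(X %*% beta) else numeric(nrow(X))
  th <- c(-Inf, theta, Inf)
  a_hi <- th[yi + 1] - eta
  a_lo <- th[yi] - eta
  li <- plogis(a_hi) - plogis(a_lo)
  if (any(li <= 0)) return(1e10)
  -sum(log(li))
}

polr_grad <- function(par, X, yi, J) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  theta <- par[k + seq_len(J - 1)]
  eta <- if (k) drop(X %*% beta) else numeric(nrow(X))
  th <- c(-Inf, theta, Inf)
  a_hi <- th[yi + 1] - eta
  a_lo <- th[yi] - eta
  li <- plogis(a_hi) - plogis(a_lo)
  li <- pmax(li, 1e-300)
  f_hi <- stats::dlogis(a_hi)
  f_lo <- stats::dlogis(a_lo)
  gbeta <- if (k) drop(crossprod(X, (f_hi - f_lo) / li)) else numeric(0)
  gtheta <- numeric(J - 1)
  for (j in seq_len(J - 1)) {
    gtheta[j] <- -sum(f_hi[yi == j] / li[yi == j]) +
      sum(f_lo[yi == j + 1] / li[yi == j + 1])
  }
  c(gbeta, gtheta)
}

#' Fit a proportional-odds logistic regression
#'
#' Maximizes the proportional-odds likelihood `logit P(Y <= j | x) =
#' theta_j - x beta` by BFGS with analytic gradients, starting from
#' `beta = 0` and cutpoints at the empirical cumulative logits. Features
#' are standardized internally for conditioning and estimates mapped back.
#' Standard errors come from the inverse observed information, p-values
#' from two-sided normal z. Rows with missing values are dropped and
#' counted.
#'
#' @param X replicate-by-feature matrix or data.frame (may have 0 columns).
#' @param y ordinal outcome (ordered factor, or coercible).
#' @return An `ordinal_fit`: coefficients, cutpoints (`theta`), `se`, `z`,
#'   `p`, `logLik`, `AIC`, odds ratios, `n_dropped`.
#' @export
polr_fit <- function(X, y) {
  X <- as.matrix(as.data.frame(X))
  if (!is.ordered(y)) y <- factor(y, ordered = TRUE)
  ok <- stats::complete.cases(X) & !is.na(y)
  n_dropped <- sum(!ok)
  X <- X[ok, , drop = FALSE]
  y <- droplevels(y[ok])
  J <- nlevels(y)
  if (J < 2) stop("need at least 2 observed categories")
  yi <- as.integer(y)
  n <- length(yi)
  k <- ncol(X)
  mu <- if (k) colMeans(X) else numeric(0)
  sdv <- if (k) apply(X, 2, sd) else numeric(0)
  if (k && any(sdv == 0)) stop("constant feature in design matrix")
  Xs <- if (k) sweep(sweep(X, 2, mu), 2, sdv, "/") else X
  cum <- cumsum(tabulate(yi, J))[seq_len(J - 1)] / n
  start <- c(rep(0, k), qlogis(cum))
  fit <- optim(start, polr_nll, polr_grad, X = Xs, yi = yi, J = J,
               method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("proportional-odds fit did not converge (code ",
         fit$convergence, ")")
  if (any(abs(fit$par[seq_len(k)]) > 30))
    stop("likely perfect separation: unbounded coefficient estimate")
  theta_s <- fit$par[k + seq_len(J - 1)]
  if (is.unsorted(theta_s, strictly = TRUE))
    stop("fitted cutpoints not strictly increasing")
  covm <- tryCatch(solve(fit$hessian), error = function(e)
    stop("observed information singular (possible separation)"))
  se_s <- sqrt(pmax(diag(covm), 0))
  beta <- if (k) fit$par[seq_len(k)] / sdv else numeric(0)
  se_beta <- if (k) se_s[seq_len(k)] / sdv else numeric(0)
  theta <- theta_s + if (k) sum(fit$par[seq_len(k)] * mu / sdv) else 0
  names(beta) <- colnames(X)
  names(se_beta) <- colnames(X)
  ll <- -fit$value
  npar <- k + (J - 1)
  z <- beta / se_beta
  structure(list(
    features = colnames(X), coefficients = beta, theta = theta,
    se = se_beta, z = z, p = 2 * pnorm(-abs(z)),
    logLik = ll, AIC = 2 * npar - 2 * ll,
    odds_ratio = exp(beta), n = n, n_dropped = n_dropped,
    levels = levels(y)), class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("ordinal_fit: %d obs, %d categories, AIC = %.2f\n",
              x$n, length(x$theta) + 1, x$AIC))
  if (length(x$coefficients)) {
    tab <- data.frame(beta = x$coefficients, se = x$se, p = x$p,
                      OR = x$odds_ratio)
    print(tab, digits = 4)
  } else cat("  (intercept-only model)\n")
  invisible(x)
}

#' Exhaustive best-subset selection by AIC
#'
#' Fits [polr_fit] for every subset of the candidate features (including the
#' intercept-only model) and returns the subset with minimal AIC; ties go to
#' the smaller subset. Subsets whose fit fails are skipped and logged.
#'
#' @param X candidate feature matrix/data.frame (at most 12 columns).
#' @param y ordinal outcome.
#' @param max_features optional cap on subset size.
#' @return Character vector of selected features (possibly empty), with the
#'   winning AIC in `attr(, "AIC")` and skipped subsets in
#'   `attr(, "skipped")`.
#' @export
best_subset <- function(X, y, max_features = NULL) {
  X <- as.data.frame(X)
  k <- ncol(X)
  if (k > 12) stop("more than 12 candidates: exhaustive search intractable")
  if (is.null(max_features)) max_features <- k
  best <- list(feats = character(0),
               aic = polr_fit(X[, 0, drop = FALSE], y)$AIC)
  skipped <- character(0)
  if (k > 0) {
    for (sz in seq_len(min(k, max_features))) {
      for (combo in as.list(as.data.frame(combn(colnames(X), sz),
                                          stringsAsFactors = FALSE))) {
        aic <- tryCatch(polr_fit(X[, combo, drop = FALSE], y)$AIC,
                        error = function(e) NA_real_)
        if (is.na(aic)) {
          skipped <- c(skipped, paste(combo, collapse = "+"))
        } else if (aic < best$aic - 1e-9) {
          best <- list(feats = combo, aic = aic)
        }
      }
    }
  }
  structure(best$feats, AIC = best$aic, skipped = skipped)
}

#' Bidirectional stepwise selection by AIC
#'
#' Starts from the full model and repeatedly applies the single add or drop
#' that most improves AIC, stopping at a local minimum. Deterministic given
#' the data.
#'
#' @inheritParams best_subset
#' @return Character vector of selected features with `attr(, "AIC")`.
#' @export
stepwise_aic <- function(X, y) {
  X <- as.data.frame(X)
  all_f <- colnames(X)
  fit_aic <- function(fs) tryCatch(
    polr_fit(X[, fs, drop = FALSE], y)$AIC, error = function(e) Inf)
  current <- all_f
  cur_aic <- fit_aic(current)
  if (!is.finite(cur_aic)) { current <- character(0); cur_aic <- fit_aic(current) }
  repeat {
    moves <- list()
    for (f in current)
      moves[[paste0("-", f)]] <- setdiff(current, f)
    for (f in setdiff(all_f, current))
      moves[[paste0("+", f)]] <- c(current, f)
    if (!length(moves)) break
    aics <- vapply(moves, fit_aic, numeric(1))
    if (min(aics) < cur_aic - 1e-9) {
      pick <- which.min(aics)
      current <- moves[[pick]]
      cur_aic <- aics[pick]
    } else break
  }
  structure(as.character(sort(current)), AIC = cur_aic)
}

#' Reconcile two selected feature sets
#'
#' Equal sets are returned as-is; otherwise the smaller (simpler) model
#' wins; on a size tie the set with the lower AIC is chosen.
#'
#' @param set_a,set_b feature sets from [best_subset] / [stepwise_aic].
#' @param X,y data used to break size ties by AIC (only needed then).
#' @return The reconciled feature set.
#' @export
reconcile <- function(set_a, set_b, X = NULL, y = NULL) {
  a <- as.character(set_a); b <- as.character(set_b)
  if (setequal(a, b)) return(sort(a))
  if (length(a) != length(b))
    return(sort(if (length(a) < length(b)) a else b))
  aic <- function(s, given) {
    g <- attr(given, "AIC")
    if (!is.null(g)) return(g)
    if (is.null(X)) stop("need X, y to break an AIC tie")
    polr_fit(as.data.frame(X)[, s, drop = FALSE], y)$AIC
  }
  if (aic(a, set_a) <= aic(b, set_b)) sort(a) else sort(b)
}

#' Interpret an odds ratio as a fold change
#'
#' Odds ratios below 1 are reported as their reciprocal "times less
#' likely"; at or above 1 as "times more likely". The fold is rounded to 3
#' significant figures.
#'
#' @param or_value positive odds ratio.
#' @return list `direction` ("more"/"less") and `fold`.
#' @export
interpret_odds_ratio <- function(or_value) {
  if (!is.finite(or_value) || or_value <= 0)
    stop("odds ratio must be a positive number")
  if (or_value >= 1) list(direction = "more", fold = signif(or_value, 3))
  else list(direction = "less", fold = signif(1 / or_value, 3))
}
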