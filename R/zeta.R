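# mean intersection size over a set of site combinations given as an
# i x m index matrix (columns = combinations)
zeta_over_combos <- function(presence, combos) {
  i <- nrow(combos); m <- ncol(combos)
  # indicator matrix (m x n_sites) times presence (n_sites x S) counts, per
  # combination, how many of its i sites hold each species
  S <- matrix(0, m, nrow(presence))
  S[cbind(rep(seq_len(m), each = i), as.vector(combos))] <- 1
  shared <- S %*% presence        # m x species
  cnt <- rowSums(shared == i)
  list(mean = mean(cnt), sd = if (m > 1) sd(cnt) else 0)
}

#' Exact zeta diversity of a given order
#'
#' Mean number of species present in every site of a combination, over all
#' `choose(n_sites, i)` combinations of `i` sites. Errors above the
#' enumeration cap; use [zeta_sampled] there.
#'
#' @param presence binary site-by-species matrix.
#' @param i zeta order (number of sites per combination).
#' @param cap largest number of combinations enumerated exactly
#'   (default 1e5).
#' @return numeric scalar `zeta_i`.
#' @export
zeta_exact <- function(presence, i, cap = 1e5) {
  presence <- (as.matrix(presence) > 0) * 1
  n <- nrow(presence)
  stopifnot(i >= 1, i <= n)
  if (choose(n, i) > cap)
    stop("too many combinations for exact enumeration; use zeta_sampled()")
  combos <- combn(n, i)
  zeta_over_combos(presence, combos)$mean
}

#' Monte-Carlo zeta diversity of a given order
#'
#' Mean intersection size over `n_combos` uniformly drawn `i`-site
#' combinations (sites distinct within a combination; combinations may
#' repeat across draws).
#'
#' @inheritParams zeta_exact
#' @param n_combos number of sampled combinations (default 1000).
#' @param seed integer seed.
#' @return list `zeta` (estimate) and `sd` (combination-level standard
#'   deviation).
#' @export
zeta_sampled <- function(presence, i, n_combos = 1000, seed = 1L) {
  presence <- (as.matrix(presence) > 0) * 1
  n <- nrow(presence)
  stopifnot(i >= 1, i <= n)
  combos <- with_seed(seed, vapply(seq_len(n_combos),
                                   function(z) sample.int(n, i), integer(i)))
  combos <- matrix(combos, nrow = i)
  zs <- zeta_over_combos(presence, combos)
  list(zeta = zs$mean, sd = zs$sd)
}

#' Zeta decline across orders 1..i_max
#'
#' Exact where the enumeration cap allows, sampled otherwise; also returns
#' the retention ratios `zeta_{i+1} / zeta_i` (NA where `zeta_i = 0`).
#'
#' @inheritParams zeta_sampled
#' @param i_max highest zeta order.
#' @return A `zeta_decline`: list with `order`, `zeta`, `sd` (0 for exact
#'   orders), `retention`, `sampled` (logical per order).
#' @export
zeta_decline <- function(presence, i_max, cap = 1e5, n_combos = 1000,
                         seed = 1L) {
  presence <- (as.matrix(presence) > 0) * 1
  n <- nrow(presence)
  stopifnot(i_max >= 1, i_max <= n)
  zeta <- sdv <- numeric(i_max)
  sampled <- logical(i_max)
  for (i in seq_len(i_max)) {
    if (choose(n, i) <= cap) {
      zeta[i] <- zeta_exact(presence, i, cap)
    } else {
      zs <- zeta_sampled(presence, i, n_combos, derive_seed(seed, "zeta", i))
      zeta[i] <- zs$zeta; sdv[i] <- zs$sd; sampled[i] <- TRUE
    }
  }
  retention <- c(zeta[-1] / head(zeta, -1), NA_real_)
  retention[head(zeta, -1) == 0] <- NA_real_
  structure(list(order = seq_len(i_max), zeta = zeta, sd = sdv,
                 retention = retention[seq_len(i_max)], sampled = sampled),
            class = "zeta_decline")
}

#' @export
print.zeta_decline <- function(x, ...) {
  cat(sprintf("zeta_decline: orders 1..%d, zeta_1 = %.3g, zeta_%d = %.3g\n",
              max(x$order), x$zeta[1], max(x$order), x$zeta[length(x$zeta)]))
  invisible(x)
}

#' Fit exponential and power-law models to a zeta decline
#'
#' Ordinary least squares of `log zeta_i` on `i` (exponential decline) and
#' on `log i` (power-law decline); Gaussian AIC on the log scale with three
#' parameters each. Orders with `zeta = 0` truncate the fit range. The
#' verdict maps the winning model to an assembly regime: exponential
#' decline - stochastic assembly, power-law decline - niche assembly.
#'
#' @param decline a `zeta_decline` (or a numeric vector of zeta values for
#'   orders `1..length`).
#' @return list with `exp_fit`, `pow_fit` (each: intercept, slope, AIC),
#'   `delta_aic` (exp minus pow), `verdict` ("stochastic" or "niche"),
#'   `orders_used`.
#' @export
fit_decline <- function(decline) {
  zeta <- if (inherits(decline, "zeta_decline")) decline$zeta else
    as.numeric(decline)
  ord <- seq_along(zeta)
  zero <- which(zeta <= 0)
  if (length(zero)) {
    last <- min(zero) - 1L
    ord <- ord[seq_len(last)]
    zeta <- zeta[seq_len(last)]
  }
  if (length(ord) < 3) stop("fewer than 3 usable zeta orders for the fit")
  lz <- log(zeta)
  f_exp <- lm(lz ~ ord)
  f_pow <- lm(lz ~ log(ord))
  aic_e <- AIC(f_exp)
  aic_p <- AIC(f_pow)
  list(exp_fit = list(intercept = unname(coef(f_exp)[1]),
                      slope = unname(coef(f_exp)[2]), AIC = aic_e),
       pow_fit = list(intercept = unname(coef(f_pow)[1]),
                      slope = unname(coef(f_pow)[2]), AIC = aic_p),
       delta_aic = aic_e - aic_p,
       verdict = if (aic_e < aic_p) "stochastic" else "niche",
       orders_used = ord)
}

#' Assembly verdicts per group, rank and order
#'
#' Runs [zeta_decline] + [fit_decline] on every combination of group, rank
#' and maximum order. Cells whose group has fewer sites than the order are
#' skipped with a reason.
#'
#' @param presence_tables nested list: `presence_tables[[rank]][[group]]` is
#'   a binary site-by-species matrix (see [to_presence_absence]).
#' @param orders maximum zeta orders (default `c(3, 5, 10, 20, 50)`).
#' @param seed integer seed for sampled orders.
#' @param cap,n_combos passed to [zeta_decline].
#' @return data.frame with columns `group`, `rank`, `i_max`, `aic_exp`,
#'   `aic_pow`, `delta_aic`, `verdict`, `skipped`, `reason`.
#' @export
assembly_report <- function(presence_tables, orders = c(3, 5, 10, 20, 50),
                            seed = 1L, cap = 1e5, n_combos = 1000) {
  rows <- list()
  for (rank in names(presence_tables)) {
    for (group in names(presence_tables[[rank]])) {
      pres <- presence_tables[[rank]][[group]]
      for (i_max in orders) {
        if (nrow(pres) < i_max) {
          rows[[length(rows) + 1L]] <- data.frame(
            group = group, rank = rank, i_max = i_max,
            aic_exp = NA_real_, aic_pow = NA_real_, delta_aic = NA_real_,
            verdict = NA_character_, skipped = TRUE,
            reason = sprintf("only %d sites < order %d", nrow(pres), i_max),
            stringsAsFactors = FALSE)
          next
        }
        dec <- zeta_decline(pres, i_max, cap = cap, n_combos = n_combos,
                            seed = derive_seed(seed, paste(rank, group), i_max))
        fd <- tryCatch(fit_decline(dec), error = function(e) NULL)
        rows[[length(rows) + 1L]] <- if (is.null(fd)) data.frame(
          group = group, rank = rank, i_max = i_max,
          aic_exp = NA_real_, aic_pow = NA_real_, delta_aic = NA_real_,
          verdict = NA_character_, skipped = TRUE,
          reason = "fewer than 3 usable orders", stringsAsFactors = FALSE)
        else data.frame(
          group = group, rank = rank, i_max = i_max,
          aic_exp = fd$exp_fit$AIC, aic_pow = fd$pow_fit$AIC,
          delta_aic = fd$delta_aic, verdict = fd$verdict, skipped = FALSE,
          reason = "", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
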