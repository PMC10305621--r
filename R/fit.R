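#' Fit redox rate constants to time-course observations
#'
#' Least-squares recovery of the four rate constants of the
#' reduction/oxidation network from observed (K, R, S) trajectories.
#' Observations may pool several incubation series, each with its own fixed
#' oxygen factor (anaerobic series have `oxygen_factor = 0`) and initial
#' state; aerobic and anaerobic series together are what make all four
#' rates identifiable. Optimisation uses bounded Levenberg-Marquardt
#' (rates >= 0).
#'
#' @param observations Data frame with columns `t`, `K`, `R`, `S`,
#'   `oxygen_factor`, and optionally `series` (defaults to one series per
#'   distinct oxygen factor).
#' @param y0 Initial state `c(K=,R=,S=)` shared by all series, or a named
#'   list of such vectors keyed by series.
#' @param start A `redox_params` initial guess (its `oxygen_factor` is
#'   ignored; the per-observation factors are used).
#' @return A `redox_fit` object with `coefficients`, `fitted.values`,
#'   `residuals`, `diagnostics` (residual norm, convergence message,
#'   per-parameter identifiability flags) and the data used. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`.
#' @examples
#' p <- redox_params(0.15, 0.3, 0.25, 0.02)
#' tr <- simulate_redox(p, times = seq(2, 24, length.out = 8))
#' obs <- data.frame(tr[c("t", "K", "R", "S")], oxygen_factor = 1)
#' fit <- fit_redox(obs, start = redox_params(0.1, 0.1, 0.1, 0.1))
#' coef(fit)
#' @export
fit_redox <- function(observations, y0 = c(K = 1, R = 0, S = 0),
                      start = redox_params(0.1, 0.1, 0.1, 0.1)) {
  need <- c("t", "K", "R", "S", "oxygen_factor")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  obs <- as.data.frame(observations)
  if (nrow(obs) == 0L || all(obs$t == 0)) {
    stop("degenerate input: need observations at t > 0", call. = FALSE)
  }
  if (is.null(obs$series)) {
    obs$series <- paste0("phi", obs$oxygen_factor)
  }
  y0_of <- function(s) {
    y <- if (is.list(y0)) y0[[s]] else y0
    y[c("K", "R", "S")]
  }

  pred_all <- function(k) {
    out <- obs
    for (s in unique(obs$series)) {
      ix <- which(obs$series == s)
      phi <- obs$oxygen_factor[ix[1L]]
      p <- redox_params(k[1L], k[2L], k[3L], k[4L], oxygen_factor = phi)
      tt <- obs$t[ix]
      o <- order(tt)
      tr <- simulate_redox(p, y0 = y0_of(s), times = tt[o])
      out[ix[o], c("K", "R", "S")] <- tr[, c("K", "R", "S")]
    }
    out
  }
  resid_fun <- function(k) {
    pr <- pred_all(k)
    c(obs$K - pr$K, obs$R - pr$R, obs$S - pr$S)
  }

  k0 <- pmax(unlist(start[c("k_red_R", "k_red_S", "k_ox_S", "k_ox_R")]),
             1e-6)
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit <- minpack.lm::nls.lm(par = k0, fn = resid_fun,
                            lower = rep(0, 4), control = ctl)
  k_hat <- pmax(unname(fit$par), 0)
  names(k_hat) <- c("k_red_R", "k_red_S", "k_ox_S", "k_ox_R")

  res <- resid_fun(k_hat)
  pr <- pred_all(k_hat)

  # identifiability: numeric Jacobian column norms + aerobic-data check
  J <- jacobian_fd(resid_fun, k_hat)
  colnorm <- sqrt(colSums(J^2))
  scale_ <- max(colnorm, 1e-12)
  unident <- colnorm < 1e-6 * scale_
  if (all(obs$oxygen_factor == 0)) {
    unident[c("k_ox_S", "k_ox_R")] <- TRUE
  }
  dof <- max(length(res) - sum(!unident), 1L)
  sigma2 <- sum(res^2) / dof
  vc <- tryCatch({
    Ji <- J[, !unident, drop = FALSE]
    v <- matrix(NA_real_, 4, 4, dimnames = list(names(k_hat), names(k_hat)))
    v[!unident, !unident] <- sigma2 * solve(crossprod(Ji))
    v
  }, error = function(e) matrix(NA_real_, 4, 4,
                                dimnames = list(names(k_hat), names(k_hat))))

  structure(
    list(coefficients = k_hat,
         fitted.values = pr[, c("K", "R", "S")],
         residuals = res,
         vcov = vc,
         diagnostics = list(
           residual_norm = sqrt(sum(res^2)),
           deviance = sum(res^2),
           convergence = fit$info,
           message = fit$message,
           unidentifiable = names(k_hat)[unident]),
         data = obs,
         y0 = y0,
         start = k0),
    class = "redox_fit")
}

jacobian_fd <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x),
              dimnames = list(NULL, names(x)))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1)
    xj <- x; xj[j] <- xj[j] + h
    J[, j] <- (f(xj) - f0) / h
  }
  J
}

#' @export
coef.redox_fit <- function(object, ...) object$coefficients

#' @export
vcov.redox_fit <- function(object, ...) object$vcov

#' @export
fitted.redox_fit <- function(object, ...) object$fitted.values

#' @export
residuals.redox_fit <- function(object, ...) object$residuals

#' @export
deviance.redox_fit <- function(object, ...) object$diagnostics$deviance

#' @export
print.redox_fit <- function(x, digits = 4, ...) {
  cat("Redox kinetics fit (bounded Levenberg-Marquardt)\n")
  print(round(x$coefficients, digits))
  cat("residual norm:", format(x$diagnostics$residual_norm, digits = digits),
      "on", nrow(x$data), "observations\n")
  if (length(x$diagnostics$unidentifiable)) {
    cat("WARNING: unidentifiable parameter(s):",
        paste(x$diagnostics$unidentifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.redox_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se)
  out <- list(coefficients = tab,
              residual_norm = object$diagnostics$residual_norm,
              n = nrow(object$data),
              unidentifiable = object$diagnostics$unidentifiable,
              message = object$diagnostics$message)
  class(out) <- "summary.redox_fit"
  out
}

#' @export
print.summary.redox_fit <- function(x, digits = 4, ...) {
  cat("Redox kinetics fit\n\nRate constants (1/h):\n")
  print(signif(x$coefficients, digits))
  cat("\nresidual norm:", format(x$residual_norm, digits = digits),
      "on", x$n, "observations\n")
  if (length(x$unidentifiable)) {
    cat("unidentifiable:", paste(x$unidentifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict species trajectories from a fitted redox model
#'
#' @param object A `redox_fit`.
#' @param times Sampling times (hours); default: times in the fitted data.
#' @param oxygen_factor Oxygen factor of the predicted incubation.
#' @param y0 Initial state; default the fit's shared initial state (or the
#'   first series' state when per-series states were supplied).
#' @param ... Unused.
#' @return A trajectory data frame as from [simulate_redox()].
#' @export
predict.redox_fit <- function(object, times = NULL, oxygen_factor = 1,
                              y0 = NULL, ...) {
  if (is.null(times)) times <- sort(unique(object$data$t))
  if (is.null(y0)) {
    y0 <- if (is.list(object$y0)) object$y0[[1L]] else object$y0
  }
  k <- object$coefficients
  p <- redox_params(k[1L], k[2L], k[3L], k[4L], oxygen_factor = oxygen_factor)
  simulate_redox(p, y0 = y0, times = times)
}

#' @export
plot.redox_fit <- function(x, n_grid = 101, ...) {
  obs <- x$data
  op <- graphics::par(mfrow = c(1, length(unique(obs$series))),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in unique(obs$series)) {
    d <- obs[obs$series == s, ]
    phi <- d$oxygen_factor[1L]
    tt <- seq(0, max(d$t), length.out = n_grid)
    y0 <- if (is.list(x$y0)) x$y0[[s]] else x$y0
    tr <- predict(x, times = tt, oxygen_factor = phi, y0 = y0)
    graphics::matplot(tr$t, tr[, c("K", "R", "S")], type = "l", lty = 1,
                      col = c("black", "forestgreen", "firebrick"),
                      xlab = "time (h)", ylab = "fraction", main = s, ...)
    graphics::matpoints(d$t, d[, c("K", "R", "S")], pch = 1,
                        col = c("black", "forestgreen", "firebrick"))
    graphics::legend("topright", c("K", "R", "S"), lty = 1, bty = "n",
                     col = c("black", "forestgreen", "firebrick"))
  }
  invisible(x)
}

#' Simulate replicate noisy observation tables from a fitted model
#'
#' Draws `nsim` datasets with the design (times, oxygen factors, series,
#' initial states) of the fitted data and multiplicative Gaussian noise on
#' each species.
#'
#' @param object A `redox_fit`.
#' @param nsim Number of replicate tables.
#' @param seed Optional integer seed.
#' @param noise_sd Multiplicative noise standard deviation.
#' @param ... Unused.
#' @return A list of `nsim` observation data frames.
#' @export
simulate.redox_fit <- function(object, nsim = 1, seed = NULL,
                               noise_sd = 0.05, ...) {
  k <- object$coefficients
  base <- object$data
  clean <- base
  for (s in unique(base$series)) {
    ix <- which(base$series == s)
    y0 <- if (is.list(object$y0)) object$y0[[s]] else object$y0
    tr <- predict(object, times = base$t[ix],
                  oxygen_factor = base$oxygen_factor[ix[1L]], y0 = y0)
    clean[ix, c("K", "R", "S")] <- tr[, c("K", "R", "S")]
  }
  with_seed(seed, {
    replicate(nsim, simplify = FALSE, {
      noisy <- clean
      for (col in c("K", "R", "S")) {
        noisy[[col]] <- pmax(noisy[[col]] *
                               (1 + stats::rnorm(nrow(noisy), 0, noise_sd)), 0)
      }
      noisy
    })
  })
}
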