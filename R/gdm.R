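#' Build a site-pair table with a scaled response
#'
#' Divides a dissimilarity matrix by its maximum so the response lies within
#' 0..1 (min-max with the floor at the natural zero), one row per
#' unordered basin pair with a defined value.
#'
#' @param D symmetric dissimilarity matrix (e.g. betaMPD); `NA` pairs are
#'   dropped.
#' @return data frame with `basin_i`, `basin_j`, `raw`, `response`.
#' @export
scale_response <- function(D) {
  D <- as.matrix(D)
  px <- .pair_index(nrow(D))
  raw <- D[cbind(px$i, px$j)]
  keep <- !is.na(raw)
  if (sum(keep) < 3) stop("fewer than 3 defined pairs: model unidentifiable")
  raw <- raw[keep]
  mx <- max(raw)
  if (mx == 0) {
    warning("all dissimilarities are zero; response is all-zero")
    resp <- raw
  } else {
    resp <- raw / mx
  }
  data.frame(basin_i = rownames(D)[px$i[keep]],
             basin_j = rownames(D)[px$j[keep]],
             raw = raw, response = resp, stringsAsFactors = FALSE)
}

#' Monotone I-spline basis (integrated M-splines, order 2)
#'
#' Order-2 M-splines are piecewise-linear hat functions, so their integrals
#' — the I-splines — are piecewise quadratic and have a closed form. Basis
#' function `i` lives on the knot triple `(a, b, c) =`
#' `(t[i], t[i+1], t[i+2])` of the boundary-augmented knot vector: it is 0
#' up to `a`, `(x-a)^2 / ((c-a)(b-a))` on `(a, b]`,
#' `1 - (c-x)^2 / ((c-a)(c-b))` on `(b, c]`, and 1 beyond `c` (degenerate
#' boundary triples collapse to a single quadratic arc). Each basis is 0 at
#' the smallest knot, 1 at the largest, and non-decreasing; together with
#' non-negative coefficients this yields monotone fitted curves. Default:
#' three splines with knots at the 0th, 50th and 100th percentiles of the
#' distances.
#'
#' @param x distances (finite).
#' @param n_splines number of basis functions.
#' @param knots strictly increasing knot vector of length `n_splines`
#'   (default: evenly spaced quantiles of `x`).
#' @return matrix `length(x) x n_splines` with values in `[0, 1]` and
#'   attribute `knots`.
#' @export
ispline_basis <- function(x, n_splines = 3, knots = NULL) {
  stopifnot(all(is.finite(x)), n_splines >= 2)
  if (is.null(knots)) {
    knots <- unname(quantile(x, seq(0, 1, length.out = n_splines)))
  }
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing (constant or tied distances)")
  }
  stopifnot(length(knots) == n_splines)
  t_aug <- c(knots[1], knots, knots[n_splines])
  x_clamp <- pmin(pmax(x, knots[1]), knots[n_splines])
  B <- matrix(0, length(x), n_splines)
  for (i in seq_len(n_splines)) {
    a <- t_aug[i]; b <- t_aug[i + 1]; cc <- t_aug[i + 2]
    v <- numeric(length(x))
    if (a < b) {
      lo <- x_clamp > a & x_clamp <= b
      v[lo] <- (x_clamp[lo] - a)^2 / ((cc - a) * (b - a))
    }
    if (b < cc) {
      hi <- x_clamp > b & x_clamp <= cc
      v[hi] <- 1 - (cc - x_clamp[hi])^2 / ((cc - a) * (cc - b))
    }
    v[x_clamp >= cc] <- 1
    B[, i] <- v
  }
  colnames(B) <- paste0("I", seq_len(n_splines))
  attr(B, "knots") <- knots
  B
}

#' Fit a generalized dissimilarity model (one predictor)
#'
#' Model: `d = 1 - exp(-eta)`, `eta = b0 + sum_j b_j I_j(distance)` with all
#' coefficients constrained non-negative, so predicted dissimilarity is
#' monotone non-decreasing in distance and bounded in [0, 1). Fitting
#' minimises squared error on the response scale: non-negative least
#' squares (Lawson–Hanson) on the linearised link provides the start, then
#' projected Gauss–Newton iterations polish the fit. Deterministic — no
#' random initialisation.
#'
#' @param table site-pair table from [scale_response()] with the predictor
#'   added, or any data frame with columns `response` and `distance`.
#' @param n_splines,knots passed to [ispline_basis()].
#' @param max_iter Gauss–Newton iteration cap.
#' @return object of class `gdm_fit`: `intercept`, `coefficients`, `knots`,
#'   `n_splines`, `percent_deviance_explained`, `fitted`, `converged`.
#' @export
fit_gdm <- function(table, n_splines = 3, knots = NULL, max_iter = 100) {
  stopifnot(all(c("response", "distance") %in% names(table)),
            nrow(table) >= 3)
  d <- table$response
  stopifnot(all(d >= 0), all(d <= 1))
  x <- table$distance
  B <- ispline_basis(x, n_splines, knots)
  knots <- attr(B, "knots")
  X <- cbind(`(Intercept)` = 1, B)
  rss_null <- sum((d - mean(d))^2)

  if (rss_null == 0) {
    # constant response: null model, all spline coefficients zero
    b0 <- -log(1 - min(mean(d), 1 - 1e-12))
    fit <- list(intercept = b0, coefficients = setNames(rep(0, ncol(B)),
                                                        colnames(B)),
                knots = knots, n_splines = ncol(B),
                percent_deviance_explained = 0,
                fitted = rep(1 - exp(-b0), length(d)), converged = TRUE,
                data = table)
    class(fit) <- "gdm_fit"
    return(fit)
  }

  # start: NNLS on the linearised link eta = -log(1 - d)
  eta_t <- -log(1 - pmin(d, 1 - 1e-8))
  beta <- pracma::lsqnonneg(X, eta_t)$x

  pred <- function(b) 1 - exp(-drop(X %*% b))
  rss <- function(b) sum((d - pred(b))^2)
  cur <- rss(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    J <- X * exp(-eta)           # d pred / d beta
    target <- d - pred(beta) + drop(J %*% beta)
    cand <- pracma::lsqnonneg(J, target)$x
    # damped step toward the NNLS solution of the linearised problem
    step <- 1
    repeat {
      trial <- beta + step * (cand - beta)
      if (rss(trial) <= cur + 1e-15 || step < 1e-6) break
      step <- step / 2
    }
    new <- rss(trial)
    if (new <= cur) { beta <- trial; improved <- cur - new; cur <- new }
    else improved <- 0
    if (improved < 1e-14 * max(cur, 1e-30)) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("GDM fit did not converge within ", max_iter, " iterations")
  }
  fit <- list(intercept = beta[1],
              coefficients = setNames(beta[-1], colnames(B)),
              knots = knots, n_splines = ncol(B),
              percent_deviance_explained = 100 * max(0, 1 - cur / rss_null),
              fitted = pred(beta), converged = converged, data = table)
  class(fit) <- "gdm_fit"
  fit
}

#' Predict from a GDM fit
#'
#' @param object a `gdm_fit`.
#' @param distances distances to predict at (values outside the knot range
#'   are flagged via the `extrapolated` attribute and predicted at the
#'   clamped boundary).
#' @param ... unused.
#' @return numeric predictions in [0, 1), non-decreasing in distance; the
#'   `curve` attribute holds a data frame of per-spline partial sums.
#' @export
predict.gdm_fit <- function(object, distances = object$data$distance, ...) {
  B <- ispline_basis(distances, object$n_splines, object$knots)
  eta <- object$intercept + drop(B %*% object$coefficients)
  out <- 1 - exp(-eta)
  curve <- data.frame(distance = distances,
                      sweep(B, 2, object$coefficients, "*"),
                      prediction = out)
  attr(out, "extrapolated") <- distances < min(object$knots) |
    distances > max(object$knots)
  attr(out, "curve") <- curve
  out
}

#' @export
print.gdm_fit <- function(x, ...) {
  cat("GDM fit:", x$n_splines, "I-splines, deviance explained",
      sprintf("%.2f%%", x$percent_deviance_explained), "\n")
  cat("  intercept:", signif(x$intercept, 5), " coefficients:",
      paste(signif(x$coefficients, 5), collapse = ", "), "\n")
  invisible(x)
}
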