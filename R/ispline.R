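#' Monotone I-spline basis for one predictor
#'
#' Builds a basis of K monotone non-decreasing I-splines (integrated
#' quadratic M-splines, order 2) over the observed range of a predictor.
#' Knots sit at evenly spaced quantiles of the observed values: for the
#' default K = 3 they are the minimum, median and maximum. Each basis
#' function satisfies I_k(min) = 0 and I_k(max) = 1, so monotone partial
#' responses are obtained with non-negative coefficients.
#'
#' @param values observed predictor values at the sites (>= 3 distinct).
#' @param n_basis number of basis functions K, default 3.
#' @param name predictor name carried in the object.
#' @return an `ispline_basis` object.
#' @export
build_ispline_basis <- function(values, n_basis = 3, name = "x") {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 3) {
    stop("constant or near-constant predictor: ", name)
  }
  if (n_basis == 1) {
    q <- range(values)
    knots <- c(q[1], q[1], q[2])
  } else {
    probs <- seq(0, 1, length.out = n_basis)
    q <- unname(stats::quantile(values, probs, type = 7))
    if (anyDuplicated(q)) {
      # fall back to evenly spaced knots over the range when quantiles tie
      q <- seq(min(values), max(values), length.out = n_basis)
    }
    # order-2 knot vector: boundary knots duplicated
    knots <- c(q[1], q, q[n_basis])
  }
  structure(list(name = name, n_basis = n_basis, knots = knots,
                 quantiles = q, range = range(values)),
            class = "ispline_basis")
}

#' Evaluate an I-spline basis
#'
#' Values outside the training range are clamped to the range; the number of
#' clamped points is returned as attribute `n_clamped`.
#'
#' @param basis an `ispline_basis`.
#' @param x numeric vector.
#' @return matrix `length(x) x n_basis`, attribute `n_clamped`.
#' @export
eval_ispline <- function(basis, x) {
  t <- basis$knots
  K <- basis$n_basis
  lo <- basis$range[1]
  hi <- basis$range[2]
  n_clamped <- sum(x < lo | x > hi, na.rm = TRUE)
  x <- pmin(pmax(x, lo), hi)
  out <- matrix(0, length(x), K)
  for (j in seq_len(K)) {
    t1 <- t[j]; t2 <- t[j + 1]; t3 <- t[j + 2]
    out[, j] <- ispline2_one(x, t1, t2, t3)
  }
  colnames(out) <- paste0(basis$name, "_I", seq_len(K))
  attr(out, "n_clamped") <- n_clamped
  out
}

# one order-2 I-spline on knot triple (t1, t2, t3); handles repeated
# boundary knots (t1 == t2 or t2 == t3) and missing inputs
ispline2_one <- function(x, t1, t2, t3) {
  y <- numeric(length(x))
  if (t1 < t2) {
    seg <- which(x >= t1 & x < t2)
    y[seg] <- (x[seg] - t1)^2 / ((t3 - t1) * (t2 - t1))
  }
  seg2 <- which(x >= t2 & x < t3)
  if (t2 < t3) {
    y[seg2] <- 1 - (t3 - x[seg2])^2 / ((t3 - t1) * (t3 - t2))
  } else {
    y[seg2] <- 1
  }
  y[which(x >= t3)] <- 1
  y[is.na(x)] <- NA_real_
  y
}

# the M-spline (density) corresponding to ispline2_one; used by tests as a
# quadrature oracle and by nothing else
mspline2_one <- function(x, t1, t2, t3) {
  y <- numeric(length(x))
  if (t1 < t2) {
    seg <- x >= t1 & x < t2
    y[seg] <- 2 * (x[seg] - t1) / ((t3 - t1) * (t2 - t1))
  }
  if (t2 < t3) {
    seg <- x >= t2 & x <= t3
    y[seg] <- 2 * (t3 - x[seg]) / ((t3 - t1) * (t3 - t2))
  }
  y
}

#' @export
print.ispline_basis <- function(x, ...) {
  cat(sprintf("ispline_basis '%s': K = %d, knots at %s\n", x$name,
              x$n_basis, paste(signif(x$quantiles, 4), collapse = ", ")))
  invisible(x)
}
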