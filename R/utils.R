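#' Deterministic sub-seed for a pipeline stage
#'
#' Derives a stage-specific seed from a master seed so that every stochastic
#' stage of a run is reproducible yet uses independent streams. The derivation
#' is a small multiplicative hash of the stage name folded into the master
#' seed, kept inside the 32-bit signed-integer range R requires.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729) %% 2147483629)
}

#' Construct a labelled symmetric pairwise matrix
#'
#' The common container for genomic, geographic and environmental distances
#' and for Fst matrices. Distance kinds must have a zero diagonal and be
#' non-negative; Fst entries may be slightly negative before unit-interval
#' scaling.
#'
#' @param m square numeric matrix.
#' @param labels character labels (defaults to rownames of `m`).
#' @param kind one of "genomic", "geographic", "fst", "scaled_fst",
#'   "environmental".
#' @param tol symmetry tolerance.
#' @return a `pairwise_matrix` object (a matrix with attributes).
#' @export
pairwise_matrix <- function(m, labels = rownames(m),
                            kind = c("genomic", "geographic", "fst",
                                     "scaled_fst", "environmental"),
                            tol = 1e-8) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("pairwise matrix must be square")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  if (length(labels) != nrow(m)) stop("labels length must match dimension")
  if (max(abs(m - t(m)), na.rm = TRUE) > tol) stop("matrix is not symmetric")
  m <- (m + t(m)) / 2
  dist_kind <- kind %in% c("genomic", "geographic", "environmental", "scaled_fst")
  if (dist_kind && any(m[!is.na(m)] < -tol)) {
    stop("negative entries not allowed for kind '", kind, "'")
  }
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  structure(m, kind = kind, class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise_matrix [%s] %d x %d\n", attr(x, "kind"),
              nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

# lower-triangle vector in a fixed (column-major) order
lower_tri <- function(m) m[lower.tri(m)]

#' Write a pairwise matrix as labelled CSV
#' @param pm a `pairwise_matrix`.
#' @param path output file.
#' @export
write_pairwise_csv <- function(pm, path) {
  df <- data.frame(id = rownames(pm), unclass(pm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise matrix from labelled CSV
#' @param path CSV written by [write_pairwise_csv()].
#' @param kind matrix kind tag.
#' @export
read_pairwise_csv <- function(path, kind = "genomic") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  pairwise_matrix(m, labels = df[[1]], kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
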