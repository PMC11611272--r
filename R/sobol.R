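# Native Sobol'-sequence / Saltelli sampling and variance-based sensitivity
# estimators. The generator uses the standard primitive-polynomial direction
# numbers (Joe & Kuo) for up to 16 dimensions; designs are randomized by a
# seeded digital shift, which preserves the digital-net structure.

# d >= 2: degree s, primitive-polynomial coefficients a, initial m's
joe_kuo_table <- list(
  list(s = 1, a = 0,  m = c(1)),
  list(s = 2, a = 1,  m = c(1, 3)),
  list(s = 3, a = 1,  m = c(1, 3, 1)),
  list(s = 3, a = 2,  m = c(1, 1, 1)),
  list(s = 4, a = 1,  m = c(1, 1, 3, 3)),
  list(s = 4, a = 4,  m = c(1, 3, 5, 13)),
  list(s = 5, a = 2,  m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4,  m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7,  m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31)),
  list(s = 6, a = 1,  m = c(1, 3, 3, 9, 7, 49)),
  list(s = 6, a = 13, m = c(1, 1, 1, 15, 21, 21)),
  list(s = 6, a = 16, m = c(1, 3, 1, 13, 27, 49))
)

#' Sobol' low-discrepancy sequence
#'
#' First `n` points of the Sobol' sequence in `d` dimensions (including the
#' origin), generated with Gray-code ordering from Joe-Kuo direction
#' numbers. With a `seed`, every dimension is randomized by an independent
#' digital shift (bitwise XOR with a random integer), which keeps the
#' equidistribution properties of the net while decorrelating designs across
#' seeds.
#'
#' @param n number of points.
#' @param d dimension, at most 16.
#' @param seed optional integer seed for the digital shift; `NULL` returns
#'   the plain (deterministic) sequence.
#' @return An `n x d` matrix of points in `[0, 1)`.
#' @export
sobol_sequence <- function(n, d, seed = NULL) {
  nbits <- 30L
  if (d < 1 || d > length(joe_kuo_table) + 1)
    stop("dimension 'd' must be in [1, ", length(joe_kuo_table) + 1, "]",
         call. = FALSE)
  if (n > 2^24) stop("'n' too large", call. = FALSE)
  V <- matrix(0L, nbits, d)
  V[, 1] <- bitwShiftL(1L, nbits - seq_len(nbits))
  for (j in seq_len(d - 1L)) {
    dn <- joe_kuo_table[[j]]
    s <- dn$s; a <- dn$a
    m <- integer(nbits)
    m[seq_len(min(s, nbits))] <- dn$m[seq_len(min(s, nbits))]
    if (nbits > s) {
      for (k in (s + 1L):nbits) {
        val <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
        if (s > 1L) for (i in 1:(s - 1L)) {
          if (bitwAnd(bitwShiftR(a, s - 1L - i), 1L) == 1L)
            val <- bitwXor(val, bitwShiftL(m[k - i], i))
        }
        m[k] <- val
      }
    }
    V[, j + 1L] <- bitwShiftL(m, nbits - seq_len(nbits))
  }
  X <- matrix(0L, n, d)
  x <- integer(d)
  if (n > 1L) for (k in 1:(n - 1L)) {
    # index of the lowest zero bit of k-1 selects the direction number
    c0 <- 0L; kk <- k - 1L
    while (bitwAnd(kk, 1L) == 1L) { kk <- bitwShiftR(kk, 1L); c0 <- c0 + 1L }
    x <- bitwXor(x, V[c0 + 1L, ])
    X[k + 1L, ] <- x
  }
  if (!is.null(seed)) {
    shift <- with_seed(seed, sample.int(2^nbits, d, replace = TRUE) - 1L)
    X <- matrix(bitwXor(X, rep(shift, each = n)), n, d)
  }
  X / 2^nbits
}

# evaluate expr with a locally set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Saltelli cross-sampling design
#'
#' Builds the `base_N * (2D + 2)` evaluation matrix needed for first-,
#' second- and total-order Sobol index estimation: two independent base
#' blocks A and B drawn from a `2D`-dimensional Sobol' sequence, plus the
#' radial blocks `AB_i` (A with column `i` from B) and `BA_i` (B with column
#' `i` from A). Columns are scaled into the requested uniform bounds. Rows
#' are stored in block order A, B, AB_1..AB_D, BA_1..BA_D; the layout is
#' carried on the object and consumed by [sobol_indices()].
#'
#' @param bounds a `2 x D` matrix (rows: lower, upper) or a named list of
#'   `c(lower, upper)` pairs defining the uniform marginals.
#' @param base_N base sample size, a power of two.
#' @param seed integer seed for the digital-shift randomization.
#' @return A `saltelli_design`: list with `samples` (the
#'   `base_N*(2D+2) x D` matrix), `base_N`, `D`, `names`, `bounds`, `seed`
#'   and the block `layout`.
#' @examples
#' d <- saltelli_sample(list(x1 = c(0, 1), x2 = c(0, 1)), base_N = 8, seed = 1)
#' nrow(d$samples)  # 8 * (2*2 + 2) = 48
#' @export
saltelli_sample <- function(bounds, base_N, seed = 1) {
  if (is.list(bounds)) {
    nm <- names(bounds)
    bounds <- matrix(unlist(bounds), nrow = 2,
                     dimnames = list(c("lower", "upper"), nm))
  }
  stopifnot(is.matrix(bounds), nrow(bounds) == 2)
  D <- ncol(bounds)
  nm <- colnames(bounds)
  if (is.null(nm)) nm <- paste0("x", seq_len(D))
  if (base_N < 2 || bitwAnd(base_N, base_N - 1L) != 0)
    stop("'base_N' must be a power of two", call. = FALSE)
  U <- sobol_sequence(base_N, 2L * D, seed = seed)
  A <- U[, 1:D, drop = FALSE]
  B <- U[, (D + 1):(2 * D), drop = FALSE]
  blocks <- vector("list", 2 * D + 2)
  blocks[[1]] <- A; blocks[[2]] <- B
  for (i in seq_len(D)) {
    AB <- A; AB[, i] <- B[, i]; blocks[[2 + i]] <- AB
    BA <- B; BA[, i] <- A[, i]; blocks[[2 + D + i]] <- BA
  }
  S <- do.call(rbind, blocks)
  S <- sweep(sweep(S, 2, bounds[2, ] - bounds[1, ], "*"), 2, bounds[1, ], "+")
  colnames(S) <- nm
  structure(list(samples = S, base_N = base_N, D = D, names = nm,
                 bounds = bounds, seed = seed,
                 layout = c("A", "B", paste0("AB", seq_len(D)),
                            paste0("BA", seq_len(D)))),
            class = "saltelli_design")
}

# split an output vector into the design's blocks
split_blocks <- function(Y, design) {
  n <- design$base_N
  k <- length(design$layout)
  stopifnot(length(Y) == n * k)
  blocks <- lapply(seq_len(k) - 1L, function(b) Y[b * n + 1:n])
  names(blocks) <- design$layout
  blocks
}

# Saltelli-family point estimators on pre-split, normalized blocks.
# ABm/BAm: base_N x D matrices of the radial blocks.
sobol_point_estimates <- function(A, B, ABm, BAm, pairs) {
  V <- stats::var(c(A, B)) * (length(c(A, B)) - 1) / length(c(A, B))
  D <- ncol(ABm)
  S1 <- vapply(seq_len(D), function(i) mean(B * (ABm[, i] - A)) / V,
               numeric(1))
  ST <- vapply(seq_len(D), function(i) 0.5 * mean((A - ABm[, i])^2) / V,
               numeric(1))
  S2 <- apply(pairs, 1, function(pr) {
    i <- pr[1]; j <- pr[2]
    mean(BAm[, i] * ABm[, j] - A * B) / V - S1[i] - S1[j]
  })
  list(S1 = S1, ST = ST, S2 = S2)
}

#' Sobol sensitivity indices with bootstrap confidence intervals
#'
#' Estimates first-order, total-order and second-order variance-based
#' sensitivity indices from model output evaluated on a [saltelli_sample()]
#' design, using the standard radial estimators
#' (`S1_i = mean(B*(AB_i - A))/V`, `ST_i = mean((A - AB_i)^2)/(2V)`,
#' `S2_ij = mean(BA_i*AB_j - A*B)/V - S1_i - S1_j`). Percentile bootstrap
#' confidence intervals are computed by resampling base-sample blocks;
#' an index is flagged significant when its interval excludes zero.
#' Negative point estimates (Monte Carlo noise around zero) are reported as
#' computed, never clipped.
#'
#' @param Y numeric output vector, one value per design row.
#' @param design the `saltelli_design` the outputs were evaluated on.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed seed for the bootstrap resampling.
#' @return A `sobol_result`: `first_order` data frame (`parameter`, `S1`,
#'   `S1_lo`, `S1_hi`, `S1_sig`, `ST`, `ST_lo`, `ST_hi`, `ST_sig`),
#'   `second_order` data frame (`pair`, `S2`, `S2_lo`, `S2_hi`, `S2_sig`),
#'   plus `base_N`, `n_samples`, `n_boot`, `conf`, `seed`.
#' @export
sobol_indices <- function(Y, design, n_boot = 1000, conf = 0.95, seed = 1) {
  stopifnot(inherits(design, "saltelli_design"))
  if (anyNA(Y)) stop("'Y' contains missing values", call. = FALSE)
  if (stats::sd(Y) < 1e-12 * (1 + abs(mean(Y))))
    stop("output variance is (near) zero: Sobol indices are undefined",
         call. = FALSE)
  D <- design$D
  Yn <- (Y - mean(Y)) / stats::sd(Y)
  bl <- split_blocks(Yn, design)
  A <- bl$A; B <- bl$B
  ABm <- do.call(cbind, bl[paste0("AB", seq_len(D))])
  BAm <- do.call(cbind, bl[paste0("BA", seq_len(D))])
  pairs <- t(utils::combn(D, 2))
  est <- sobol_point_estimates(A, B, ABm, BAm, pairs)

  boot <- with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(design$base_N, replace = TRUE)
      e <- sobol_point_estimates(A[idx], B[idx],
                                 ABm[idx, , drop = FALSE],
                                 BAm[idx, , drop = FALSE], pairs)
      c(e$S1, e$ST, e$S2)
    })
  })
  qs <- apply(boot, 1, stats::quantile,
              probs = c((1 - conf) / 2, 1 - (1 - conf) / 2))
  i1 <- seq_len(D); iT <- D + i1; i2 <- 2 * D + seq_len(nrow(pairs))
  sig <- function(lo, hi) lo > 0 | hi < 0

  first <- data.frame(
    parameter = design$names,
    S1 = est$S1, S1_lo = qs[1, i1], S1_hi = qs[2, i1],
    S1_sig = sig(qs[1, i1], qs[2, i1]),
    ST = est$ST, ST_lo = qs[1, iT], ST_hi = qs[2, iT],
    ST_sig = sig(qs[1, iT], qs[2, iT]),
    row.names = NULL)
  second <- data.frame(
    pair = paste(design$names[pairs[, 1]], design$names[pairs[, 2]],
                 sep = ":"),
    S2 = est$S2, S2_lo = qs[1, i2], S2_hi = qs[2, i2],
    S2_sig = sig(qs[1, i2], qs[2, i2]),
    row.names = NULL)
  structure(list(first_order = first, second_order = second,
                 base_N = design$base_N, n_samples = nrow(design$samples),
                 n_boot = n_boot, conf = conf, seed = design$seed),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, digits = 4, ...) {
  cat(sprintf("<sobol_result> base_N = %d (%d model evaluations), %d%% CIs from %d bootstrap resamples\n",
              x$base_N, x$n_samples, round(100 * x$conf), x$n_boot))
  fo <- x$first_order
  cat("first/total order:\n")
  print(data.frame(parameter = fo$parameter,
                   S1 = round(fo$S1, digits),
                   S1_ci = sprintf("[%.*f, %.*f]%s", digits, fo$S1_lo, digits,
                                   fo$S1_hi, ifelse(fo$S1_sig, " *", "")),
                   ST = round(fo$ST, digits),
                   ST_ci = sprintf("[%.*f, %.*f]%s", digits, fo$ST_lo, digits,
                                   fo$ST_hi, ifelse(fo$ST_sig, " *", ""))),
        row.names = FALSE)
  so <- x$second_order
  cat("second order:\n")
  print(data.frame(pair = so$pair, S2 = round(so$S2, digits),
                   S2_ci = sprintf("[%.*f, %.*f]%s", digits, so$S2_lo, digits,
                                   so$S2_hi, ifelse(so$S2_sig, " *", ""))),
        row.names = FALSE)
  invisible(x)
}
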