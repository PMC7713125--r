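## Genome-sampling pan/core size curves and the Tettelin exponential fits
## F(n) = kappa * exp(-n / tau) + offset, used to classify the pangenome as
## open (positive asymptotic new-genes-per-genome) or closed.

#' Pan, core and new-gene sampling curves
#'
#' For random orderings of the genomes, records after adding the k-th genome
#' the pan size (union of families), core size (intersection) and the number
#' of families new to the union.  When `n_permutations` covers all `G!`
#' orderings (and `G <= 8`) the full set of distinct orderings is enumerated
#' instead of sampled, so the means are exact.
#'
#' @param matrix A `pan_matrix`.
#' @param n_permutations Number of genome orderings (default 10).
#' @param seed Seed for the orderings.
#' @return A `sampling_curves` object: data.frames `pan`, `core`, `new_genes`
#'   with columns `kind`, `n`, `mean`, `sd`; per-ordering trajectories are
#'   kept in the `"per_permutation"` attribute.
#' @export
sample_size_curves <- function(matrix, n_permutations = 10L, seed = 1L) {
  if (is.null(dim(matrix)) || !nrow(matrix) || !ncol(matrix))
    halopan_error("empty pan matrix")
  if (n_permutations < 1L) halopan_error("n_permutations must be >= 1")
  G <- ncol(matrix)
  pres <- matrix > 0
  exhaustive <- G <= 8L && factorial(G) <= n_permutations
  if (exhaustive) {
    ords <- all_permutations(seq_len(G))
  } else {
    set.seed(stage_seed(seed, "curves"))
    ords <- replicate(n_permutations, sample.int(G), simplify = FALSE)
  }
  np <- length(ords)
  pan <- core <- new <- matrix(0, np, G)
  for (r in seq_len(np)) {
    o <- ords[[r]]
    un <- rep(FALSE, nrow(pres)); int <- rep(TRUE, nrow(pres))
    prev <- 0L
    for (k in seq_len(G)) {
      col <- pres[, o[k]]
      un <- un | col
      int <- int & col
      pan[r, k] <- sum(un)
      core[r, k] <- sum(int)
      new[r, k] <- pan[r, k] - prev
      prev <- pan[r, k]
    }
  }
  mk <- function(m, kind) {
    data.frame(kind = kind, n = seq_len(G), mean = colMeans(m),
               sd = if (np > 1) apply(m, 2L, sd) else rep(0, G))
  }
  structure(list(pan = mk(pan, "pan"), core = mk(core, "core"),
                 new_genes = mk(new, "new-genes"),
                 n_permutations = np, exhaustive = exhaustive),
            class = "sampling_curves",
            per_permutation = list(pan = pan, core = core, new_genes = new))
}

#' Fit the Tettelin exponential model to a sampling curve
#'
#' Least-squares fit of `F(n) = kappa * exp(-n / tau) + offset`.  For fixed
#' `tau` the model is linear in `(kappa, offset)`, so the fit profiles the
#' residual sum of squares over `tau` (log-spaced grid on `[0.1, 10 G]`
#' followed by a tight local optimisation) and solves the linear part
#' exactly; this is deterministic and immune to the poor conditioning of
#' generic 3-parameter exponential fits on near-flat curves.  A constant
#' curve returns `kappa = 0` with `offset` equal to the constant.
#'
#' @param curve A curve data.frame (`n`, `mean`) as produced by
#'   [sample_size_curves()] (at least 4 points).
#' @return A `tettelin_fit`: `kappa`, `tau`, `offset`, `rss`, `converged`,
#'   and `saturation_n` = smallest `n` with `|kappa| exp(-n/tau) <
#'   0.01 |kappa|` (the point at which the exponential term has decayed to
#'   1% of its scale; `NA` for flat fits).
#' @export
fit_tettelin <- function(curve) {
  if (is.list(curve) && !is.data.frame(curve) && !is.null(curve$pan))
    halopan_error("pass one curve (e.g. curves$core), not the curve set")
  n <- curve$n; y <- curve$mean
  if (length(n) < 4L)
    halopan_error("need at least 4 curve points to fit")
  kind <- if (length(curve$kind)) as.character(curve$kind[1]) else NA_character_
  if (diff(range(y)) < 1e-8) {
    return(structure(list(kappa = 0, tau = 1, offset = mean(y),
                          rss = sum((y - mean(y))^2), converged = TRUE,
                          saturation_n = NA_integer_, kind = kind),
                     class = "tettelin_fit"))
  }
  G <- max(n)
  lo <- 0.1; hi <- 10 * G
  solve_tau <- function(tau) {
    x <- exp(-n / tau)
    f <- lm.fit(cbind(offset = 1, kappa = x), y)
    list(rss = sum(f$residuals^2), kappa = unname(f$coefficients["kappa"]),
         offset = unname(f$coefficients["offset"]))
  }
  grid <- exp(seq(log(lo), log(hi), length.out = 80))
  rss_g <- vapply(grid, function(t) solve_tau(t)$rss, numeric(1))
  i <- which.min(rss_g)
  bl <- grid[max(1L, i - 1L)]; bu <- grid[min(length(grid), i + 1L)]
  opt <- optimize(function(t) solve_tau(t)$rss, lower = bl, upper = bu,
                  tol = 1e-10)
  tau <- opt$minimum
  sol <- solve_tau(tau)
  sat <- if (abs(sol$kappa) > 1e-8) as.integer(ceiling(tau * log(100)))
         else NA_integer_
  structure(list(kappa = sol$kappa, tau = tau, offset = sol$offset,
                 rss = sol$rss,
                 converged = is.finite(sol$rss) && is.finite(sol$kappa),
                 saturation_n = sat, kind = kind),
            class = "tettelin_fit")
}

#' @export
print.tettelin_fit <- function(x, ...) {
  cat(sprintf(
    "Tettelin fit%s: kappa = %.4g, tau = %.4g, offset = %.4g (rss %.4g)\n",
    if (is.na(x$kind)) "" else paste0(" [", x$kind, "]"),
    x$kappa, x$tau, x$offset, x$rss))
  if (!is.na(x$saturation_n))
    cat("  exponential term < 1% of scale from n =", x$saturation_n, "\n")
  invisible(x)
}

#' Classify a pangenome as open or closed
#'
#' Decided on the new-genes-per-genome curve fit: the pangenome is open iff
#' the fitted asymptote `offset` (the expected number of new families each
#' additional genome contributes, `tg(theta)` in Tettelin's notation) exceeds
#' `epsilon` (default 1 family).
#'
#' @param new_genes_fit A [fit_tettelin()] result for the new-genes curve.
#' @param epsilon Openness threshold in families per genome.
#' @return List with `status` (`"open"`/`"closed"`) and
#'   `new_genes_per_genome`.
#' @export
classify_openness <- function(new_genes_fit, epsilon = 1) {
  stopifnot(inherits(new_genes_fit, "tettelin_fit"))
  if (!isTRUE(new_genes_fit$converged))
    halopan_error("cannot classify openness from a non-converged fit",
                  "halopan_fit_error")
  list(status = if (new_genes_fit$offset > epsilon) "open" else "closed",
       new_genes_per_genome = new_genes_fit$offset, epsilon = epsilon)
}

#' Write sampling curves as TSV (kind, n, mean, sd)
#' @param curves A `sampling_curves` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  d <- rbind(curves$pan, curves$core, curves$new_genes)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
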