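#' Per-comparison significance level implied by an FDR target
#'
#' Converts a target false discovery rate `q` into the per-comparison
#' significance level `alpha = (1 - beta) * q / (1 + (1 - q) * m0/m1)`,
#' where `m0/m1` is the anticipated ratio of true nulls to true
#' alternatives. Always `alpha < q`.
#'
#' @param q target FDR in (0, 1).
#' @param beta average Type II error in (0, 1).
#' @param m0_over_m1 ratio of true nulls to true alternatives (> 0).
#' @return `alpha` in (0, q).
#' @export
fdr_to_alpha <- function(q, beta, m0_over_m1 = 1) {
  (1 - beta) * q / (1 + (1 - q) * m0_over_m1)
}

se2_adjusted <- function(var_ptm, var_protein, j_ptm, j_protein) {
  2 * var_ptm / j_ptm + 2 * var_protein / j_protein
}

#' Minimal number of biological replicates for a future PTM experiment
#'
#' Chooses the smallest `J` per condition (same number of enriched and
#' global profiling replicates) such that the variance of the adjusted log2
#' fold-change estimate, `2(var_ptm + var_protein)/J`, is bounded by
#' `(delta_adj / (z_{1-beta} + z_{1-alpha/2}))^2`, with `alpha` derived from
#' the FDR target via [fdr_to_alpha()]. Closed form:
#' `J = ceiling((2 var_ptm + 2 var_protein)(z_{1-beta} + z_{1-alpha/2})^2 /
#' delta_adj^2)`, floored at 2 (a variance is inestimable below that).
#'
#' @param q target FDR in (0, 1).
#' @param beta average Type II error in (0, 1); power is `1 - beta`.
#' @param delta_adj minimal adjusted log2 fold change of interest (> 0).
#' @param var_ptm,var_protein anticipated variances of the pairwise
#'   comparison for the modified and unmodified summaries (log2 scale),
#'   typically taken from a prior experiment.
#' @param m0_over_m1 ratio of true nulls to true alternatives.
#' @return a one-row tibble: `j` (replicates per condition), `alpha`,
#'   `j_exact` (the pre-ceiling value).
#' @export
sample_size <- function(q = 0.05, beta = 0.2, delta_adj, var_ptm,
                        var_protein, m0_over_m1 = 1) {
  stopifnot(q > 0, q < 1, beta > 0, beta < 1, var_ptm >= 0,
            var_protein >= 0)
  if (delta_adj <= 0) {
    abort("delta_adj must be > 0", class = "ptm_power_error")
  }
  alpha <- fdr_to_alpha(q, beta, m0_over_m1)
  z <- qnorm(1 - beta) + qnorm(1 - alpha / 2)
  j_exact <- (2 * var_ptm + 2 * var_protein) * z^2 / delta_adj^2
  tibble::tibble(j = max(2L, as.integer(ceiling(j_exact))), alpha = alpha,
                 j_exact = j_exact)
}

#' Power or achieved FDR at a fixed number of replicates
#'
#' With the number of replicates fixed, the design relation can be solved
#' either for the power `1 - beta` at a given FDR target `q`
#' (`solve = "power"`), or for the achieved FDR `q` at a given power
#' (`solve = "fdr"`). The relation couples `alpha` to `beta` through
#' [fdr_to_alpha()], so the solution is found by root finding (bisection via
#' [stats::uniroot()], tolerance 1e-10); at the root the design equation
#' holds with equality. Replicates may be allocated unequally to the
#' enriched (`j_ptm`) and global (`j_protein`) profiles, in which case the
#' adjusted-contrast variance is `2 var_ptm / j_ptm + 2 var_protein /
#' j_protein`.
#'
#' @param delta_adj adjusted log2 fold change (> 0).
#' @param var_ptm,var_protein anticipated comparison variances.
#' @param j_ptm replicates per condition for the enriched profiles (>= 2).
#' @param j_protein replicates for the global profiles; defaults to `j_ptm`.
#' @param q FDR target (used when solving for power).
#' @param beta Type II error (used when solving for FDR).
#' @param m0_over_m1 ratio of true nulls to true alternatives.
#' @param solve `"power"` or `"fdr"`.
#' @return a one-row tibble: `power`, `q`, `alpha`, `boundary` (`TRUE` when
#'   no interior root exists and the returned value is a boundary of the
#'   unit interval).
#' @export
solve_power <- function(delta_adj, var_ptm, var_protein, j_ptm,
                        j_protein = j_ptm, q = 0.05, beta = 0.2,
                        m0_over_m1 = 1, solve = c("power", "fdr")) {
  solve <- match.arg(solve)
  stopifnot(delta_adj > 0, j_ptm >= 2, j_protein >= 2)
  se2 <- se2_adjusted(var_ptm, var_protein, j_ptm, j_protein)
  ratio <- delta_adj / sqrt(se2)
  eps <- 1e-9
  if (solve == "power") {
    # f decreasing in beta; root where z_{1-b} + z_{1-a(b)/2} = ratio
    f <- function(b) {
      qnorm(1 - b) + qnorm(1 - fdr_to_alpha(q, b, m0_over_m1) / 2) - ratio
    }
    if (f(1 - eps) >= 0) {
      # even near-zero power cannot satisfy the design: no interior root
      return(tibble::tibble(power = eps, q = q,
                            alpha = fdr_to_alpha(q, 1 - eps, m0_over_m1),
                            boundary = TRUE))
    }
    if (f(eps) <= 0) {
      # the design holds with slack even at near-certain detection
      return(tibble::tibble(power = 1 - eps, q = q,
                            alpha = fdr_to_alpha(q, eps, m0_over_m1),
                            boundary = TRUE))
    }
    root <- uniroot(f, c(eps, 1 - eps), tol = 1e-10)$root
    tibble::tibble(power = 1 - root, q = q,
                   alpha = fdr_to_alpha(q, root, m0_over_m1),
                   boundary = FALSE)
  } else {
    g <- function(qq) {
      ratio - (qnorm(1 - beta) + qnorm(1 - fdr_to_alpha(qq, beta,
                                                        m0_over_m1) / 2))
    }
    lo <- g(eps); hi <- g(1 - eps)
    if (lo >= 0) {
      return(tibble::tibble(power = 1 - beta, q = eps,
                            alpha = fdr_to_alpha(eps, beta, m0_over_m1),
                            boundary = TRUE))
    }
    if (hi <= 0) {
      return(tibble::tibble(power = 1 - beta, q = 1 - eps,
                            alpha = fdr_to_alpha(1 - eps, beta, m0_over_m1),
                            boundary = TRUE))
    }
    root <- uniroot(g, c(eps, 1 - eps), tol = 1e-10)$root
    tibble::tibble(power = 1 - beta, q = root,
                   alpha = fdr_to_alpha(root, beta, m0_over_m1),
                   boundary = FALSE)
  }
}

#' Power surface over replicate allocations
#'
#' Evaluates the statistical power of the adjusted test over a grid of
#' enriched-profile and global-profile replicate counts (which need not be
#' equal) and adjusted fold changes. When the PTM summaries are noisier than
#' the protein summaries, replicates are better spent on the enriched
#' profiles; when the variances are equal the surface is symmetric.
#'
#' @param delta_adj vector of adjusted log2 fold changes.
#' @param var_ptm,var_protein anticipated comparison variances.
#' @param j_ptm,j_protein vectors of replicate counts (>= 2).
#' @param q FDR target.
#' @param m0_over_m1 ratio of true nulls to true alternatives.
#' @return a `ptm_power_surface` tibble over the full grid with columns
#'   `delta_adj`, `j_ptm`, `j_protein`, `power`.
#' @export
power_surface <- function(delta_adj, var_ptm, var_protein, j_ptm,
                          j_protein = j_ptm, q = 0.05, m0_over_m1 = 1) {
  grid <- tidyr::expand_grid(delta_adj = delta_adj, j_ptm = j_ptm,
                             j_protein = j_protein)
  grid$power <- purrr::pmap_dbl(grid, function(delta_adj, j_ptm, j_protein) {
    solve_power(delta_adj, var_ptm, var_protein, j_ptm, j_protein, q = q,
                m0_over_m1 = m0_over_m1, solve = "power")$power
  })
  class(grid) <- c("ptm_power_surface", class(grid))
  attr(grid, "params") <- list(var_ptm = var_ptm, var_protein = var_protein,
                               q = q, m0_over_m1 = m0_over_m1)
  grid
}
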