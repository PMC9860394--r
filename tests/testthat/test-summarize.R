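test_that("log-sum summarization sums on the raw scale", {
  expect_equal(summarize_log_sum(7.3), 7.3)            # single feature
  expect_equal(summarize_log_sum(c(3, 3)), 4)          # log2(8 + 8)
  expect_equal(summarize_log_sum(c(10, 12)), log2(2^10 + 2^12))
  expect_equal(summarize_log_sum(c(10, 12)), 12.3219280948874,
               tolerance = 1e-12)
  expect_equal(summarize_log_sum(c(5, NA)), 5)
  expect_true(is.na(summarize_log_sum(c(NA_real_, NA_real_))))
})

test_that("ratio summary is the difference of log-sums", {
  expect_equal(ratio_summarize(c(3, 3), 2), 2)
  expect_equal(ratio_summarize(5.5, 2.25), 5.5 - 2.25)   # K = L = 1
  expect_equal(ratio_summarize(c(1, 2), c(1, 2)), 0)     # identical sums
  expect_true(is.na(ratio_summarize(c(NA_real_), 3)))
  for (i in 1:20) {
    set.seed(i)
    m <- rnorm(4, 20); u <- rnorm(6, 20)
    expect_equal(ratio_summarize(m, u),
                 summarize_log_sum(m) - summarize_log_sum(u))
  }
})

# Independent median-polish oracle: plain alternating row/column median
# sweeps iterated to convergence.
oracle_polish <- function(x, iter = 200) {
  overall <- 0
  row_eff <- rep(0, nrow(x)); col_eff <- rep(0, ncol(x))
  r <- x
  for (it in seq_len(iter)) {
    rm <- apply(r, 1, median, na.rm = TRUE)
    r <- r - rm; row_eff <- row_eff + rm
    cm <- median(row_eff)
    overall <- overall + cm; row_eff <- row_eff - cm
    cm <- apply(r, 2, median, na.rm = TRUE)
    r <- sweep(r, 2, cm); col_eff <- col_eff + cm
    rm2 <- median(col_eff)
    overall <- overall + rm2; col_eff <- col_eff - rm2
  }
  overall + col_eff
}

test_that("median-polish run summaries match an independent oracle", {
  m <- matrix(c(10.0, 10.2, 25.0,
                11.0, 11.1, 11.3,
                 9.5,  9.6,  9.8), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("f", 1:3), paste0("r", 1:3)))
  got <- median_polish_summarize(m)
  expect_equal(unname(got), unname(oracle_polish(m)), tolerance = 1e-4)
})

test_that("median polish degenerates correctly on small matrices", {
  one_row <- matrix(c(1.5, 2.5, NA), nrow = 1,
                    dimnames = list("f1", c("r1", "r2", "r3")))
  expect_equal(median_polish_summarize(one_row), c(r1 = 1.5, r2 = 2.5))
  const <- matrix(7, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(median_polish_summarize(const), c(a = 7, b = 7, c = 7))
  # single-feature targets agree with log-sum exactly
  expect_equal(unname(median_polish_summarize(one_row)),
               c(summarize_log_sum(1.5), summarize_log_sum(2.5)))
})

test_that("summaries are location-equivariant", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rnorm(24, 20), 4, 6,
                dimnames = list(NULL, paste0("r", 1:6)))
    m[sample(24, 4)] <- NA
    shift <- runif(1, -3, 3)
    expect_equal(median_polish_summarize(m + shift),
                 median_polish_summarize(m) + shift)
    expect_equal(apply(m + shift, 2, summarize_log_sum),
                 apply(m, 2, summarize_log_sum) + shift)
    # the run-level ratio is invariant to a joint shift
    u <- rnorm(3, 18)
    expect_equal(ratio_summarize(m[, 1] + shift, u + shift),
                 ratio_summarize(m[, 1], u))
  }
})

test_that("targets are grouped per site, composite sites kept apart", {
  tab <- make_ft(
    protein = c("P1", "P1", "P1", "P2"),
    peptide = c("AS*K", "AS*DT*K", "LLK", "MMK"),
    run = "R1", condition = "C1", log2inty = 1:4,
    site = c("S70", "S70+T81", NA, NA)
  )
  g <- group_targets(tab)
  expect_equal(nrow(g), 4)
  expect_setequal(g$site, c("S70", "S70+T81", NA))
  expect_equal(sum(g$target_type == "protein"), 2)
  expect_equal(nrow(group_targets(tab[0, ])), 0)
})

test_that("run summaries skip runs without observations", {
  tab <- make_ft(
    protein = "P1", peptide = c("AS*K", "AS*K", "AS*K"),
    run = c("R1", "R2", "R3"), condition = c("C1", "C1", "C2"),
    log2inty = c(5, NA, 6), site = "S2"
  )
  s <- summarize_runs(tab)
  expect_equal(sort(s$run), c("R1", "R3"))
  expect_equal(s$n_features, c(1L, 1L))
})

test_that("ratio summaries join sides and account for losses", {
  ptm <- make_summaries(c(10, 11, NA, 12), c("C1", "C1", "C2", "C2"))
  ptm <- ptm[!is.na(ptm$log2inty), ]
  prot <- make_summaries(c(8, 8.5, 9), c("C1", "C1", "C2"),
                         target_type = "protein", protein = "P1")
  prot$run <- c("R01", "R02", "R03")  # R04 missing on protein side
  u <- ratio_summaries(ptm, prot)
  expect_equal(nrow(u), 2)  # R01, R02 shared; R03 no ptm; R04 no protein
  expect_equal(u$log2inty, c(10 - 8, 11 - 8.5))
  loss <- attr(u, "loss")
  expect_equal(loss$n_protein_total, 3)
  expect_equal(loss$n_protein_discarded, 1)   # R03
  expect_equal(loss$n_ptm_total, 3)
  expect_equal(loss$n_ptm_discarded, 1)       # R04
})

test_that("AFT imputation honors its no-op contracts", {
  m <- matrix(rnorm(12, 20), 3, 4)
  expect_identical(impute_aft(m), m)                 # nothing missing
  m[1, 2] <- NA
  expect_identical(impute_aft(m, enabled = FALSE), m)
})

test_that("AFT imputation beats constant-minimum imputation when
           missingness is censoring", {
  set.seed(7)
  n_f <- 10; n_r <- 6
  feat <- rnorm(n_f, 20, 2); run_eff <- rnorm(n_r, 0, 0.5)
  truth <- outer(feat, run_eff, "+") + rnorm(n_f * n_r, 0, 0.4)
  thresh <- quantile(truth, 0.25)
  obs <- truth
  obs[obs < thresh] <- NA          # left-censored missingness
  stopifnot(anyNA(obs))
  imp <- impute_aft(obs)
  miss <- is.na(obs) & !is.na(imp)
  expect_true(any(miss))
  feat_min <- apply(obs, 1, min, na.rm = TRUE)
  bound <- matrix(feat_min, n_f, n_r)[miss]
  expect_true(all(imp[miss] <= bound + 1e-8))  # capped at censoring bound
  mae_aft <- mean(abs(imp[miss] - truth[miss]))
  mae_min <- mean(abs(bound - truth[miss]))
  expect_lt(mae_aft, mae_min)
})

test_that("grouped log-sum summaries match the per-target definition", {
  sim <- simulate_ptm(sim_config("sim2", n_proteins = 15, n_replicates = 3,
                                 seed = 12))
  s <- summarize_runs(sim$global, method = "log_sum")
  # oracle: per-target, per-run log2(sum(2^y)) over observed features
  g <- dplyr::group_by(sim$global, protein, run)
  oracle <- dplyr::summarise(
    g, value = log2(sum(2^log2inty[!is.na(log2inty)])), .groups = "drop"
  )
  oracle <- oracle[is.finite(oracle$value), ]
  joined <- dplyr::inner_join(s, oracle, by = c("protein", "run"))
  expect_equal(nrow(joined), nrow(s))
  expect_equal(nrow(joined), nrow(oracle))
  expect_equal(joined$log2inty, joined$value)
  expect_true(all(joined$n_features == 10))
})
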