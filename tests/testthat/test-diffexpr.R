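# Helper: matrix with given per-gene group log2 means and noise sd
make_expr <- function(log2_ctrl, log2_exp, m = 3, noise = 0, seed = 1) {
  set.seed(seed)
  n <- length(log2_ctrl)
  samples <- c(sprintf("c%d", 1:m), sprintf("e%d", 1:m))
  mat <- cbind(matrix(rep(log2_ctrl, m), n), matrix(rep(log2_exp, m), n)) +
    matrix(rnorm(n * 2 * m, 0, noise), n)
  expr <- tibble::as_tibble(as.data.frame(2^mat)) |> setNames(samples)
  expr <- dplyr::mutate(expr, gene_id = sprintf("g%03d", seq_len(n)),
                        .before = 1)
  groups <- tibble::tibble(sample_id = samples,
                           group = rep(c("control", "experimental"), each = m))
  list(expr = expr, groups = groups)
}

test_that("geometric mean matches closed forms and rejects bad input", {
  expect_equal(geometric_mean(c(4, 4, 4)), 4)
  expect_equal(geometric_mean(c(2, 8)), 4)
  expect_equal(geometric_mean(56.08), 56.08)
  expect_error(geometric_mean(c(1, 0)), class = "hubgene_domain_error")
  expect_error(geometric_mean(c(1, -2)), class = "hubgene_domain_error")
})

test_that("fold change reproduces printed intensity-pair examples", {
  up <- fold_change(2650.31, 56.08)
  expect_equal(round(up$fold_change, 2), 47.26)
  expect_equal(up$trend, "up")
  down <- fold_change(341.48, 785.22)
  expect_equal(round(down$fold_change, 2), 0.43)
  expect_equal(down$trend, "down")
  flat <- fold_change(100, 100)
  expect_equal(flat$fold_change, 1)
  expect_equal(flat$trend, "flat")
  expect_error(fold_change(0, 1), class = "hubgene_domain_error")
})

test_that("every printed top-table row's fold change is the geometric-mean ratio", {
  tab <- top_differential_table()
  fc <- fold_change(tab$geom_mean_exp, tab$geom_mean_ctrl)
  expect_equal(round(fc$fold_change, 2), tab$fold_change)
  expect_equal(fc$trend, tab$trend)
})

test_that("RVM fit recovers known hyperparameters from simulated variances", {
  set.seed(3)
  a <- 2; b <- 1; dfree <- 4
  s2 <- rf(5000, dfree, 2 * a) / (a * b)
  fit <- fit_rvm(s2, dfree)
  expect_false(fit$fallback)
  expect_gt(fit$a, 1.6)
  expect_lt(fit$a, 2.4)
})

test_that("RVM fit is a local likelihood optimum", {
  set.seed(4)
  s2 <- rf(2000, 4, 6) / 3
  fit <- fit_rvm(s2, 4)
  loglik <- function(a, b) {
    sum(df(s2 * a * b, df1 = 4, df2 = 2 * a, log = TRUE) + log(a * b))
  }
  at_fit <- loglik(fit$a, fit$b)
  set.seed(5)
  for (i in 1:20) {
    pert <- loglik(fit$a * exp(rnorm(1, 0, 0.2)),
                   fit$b * exp(rnorm(1, 0, 0.2)))
    expect_lte(pert, at_fit + 1e-6)
  }
})

test_that("degenerate variance inputs take the ordinary-t fallback", {
  expect_warning(fit1 <- fit_rvm(rep(0.5, 200), 4), "fell back")
  expect_true(fit1$fallback)
  expect_warning(fit2 <- fit_rvm(runif(10), 4), "fell back")
  expect_true(fit2$fallback)
  # fallback encodes the unmoderated test: a = 0, prior term 0
  expect_equal(fit1$a, 0)
  expect_equal(1 / fit1$b, 0)
})

test_that("zero-variance identical-mean genes get statistic 0 and p 1", {
  d <- make_expr(log2_ctrl = c(5, 5), log2_exp = c(5, 7), noise = 0)
  tt <- suppressWarnings(rvm_t_test(d$expr, d$groups))
  expect_equal(tt$statistic[1], 0)
  expect_equal(tt$p_value[1], 1)
  # shifted gene with zero variance is infinitely significant
  expect_equal(tt$p_value[2], 0)
})

test_that("in the flat-prior limit the RVM test equals the pooled t-test", {
  d <- make_expr(log2_ctrl = rnorm(500, 7, 1.5),
                 log2_exp = rnorm(500, 7, 1.5), noise = 0.4, seed = 11)
  flat <- structure(list(a = 1e-9, b = 1e12, df_residual = 4,
                         fallback = FALSE, converged = TRUE,
                         log_lik = NA_real_, n_genes = 500),
                    class = "rvm_model")
  tt <- rvm_t_test(d$expr, d$groups, model = flat)
  mat <- log2(as.matrix(d$expr[-1]))
  oracle_p <- oracle_pooled_t(mat, 4:6, 1:3)
  expect_lt(max(abs(tt$p_value - oracle_p)), 1e-3)
})

test_that("null simulation p-values are calibrated at the 5% level", {
  cfg <- sim_config(n_genes = 10000L, de_fraction = 0, hub_spec = list(),
                    n_random_edges = 0L, seed = 11L)
  sim <- simulate_expression(cfg)
  tt <- rvm_t_test(sim$expr, sim$groups)
  frac <- mean(tt$p_value < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("BH adjustment matches hand computation and edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.73), 0.73)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, NA)), class = "hubgene_domain_error")
  expect_error(bh_fdr(c(0.1, 1.2)), class = "hubgene_domain_error")
})

test_that("selection is strict on both cutoffs and sorts deterministically", {
  rec <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    statistic = 1, p_value = c(0.05, 0.01, 0.01, 0.2),
    fdr = c(0.01, 0.04, 0.04, 0.3),
    geom_mean_exp = c(2, 8, 2, 2), geom_mean_ctrl = 1,
    fold_change = c(2, 8, 2, 2), trend = "up")
  sel <- select_differential(rec)
  expect_equal(sel$gene_id, c("b", "c"))  # p tie broken by |log2 FC|
  expect_equal(nrow(select_differential(rec[0, ])), 0)
})

test_that("group-label symmetry: swapping groups inverts fold changes, keeps p", {
  d <- make_expr(log2_ctrl = rnorm(50, 7), log2_exp = rnorm(50, 7),
                 noise = 0.3, seed = 21)
  fwd <- diff_expression(d$expr, d$groups)
  swapped <- d$groups
  swapped$group <- ifelse(swapped$group == "control", "experimental",
                          "control")
  rev <- diff_expression(d$expr, swapped)
  expect_equal(rev$fold_change, 1 / fwd$fold_change, tolerance = 1e-12)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-9)
  flips <- fwd$trend != "flat"
  expect_true(all(rev$trend[flips] != fwd$trend[flips]))
})

test_that("permuting sample columns leaves all statistics unchanged", {
  d <- make_expr(log2_ctrl = rnorm(80, 7), log2_exp = rnorm(80, 7),
                 noise = 0.3, seed = 22)
  base <- diff_expression(d$expr, d$groups)
  perm <- sample(2:7)
  expr2 <- d$expr[, c(1, perm)]
  out <- diff_expression(expr2, d$groups)
  expect_equal(out$p_value, base$p_value, tolerance = 1e-12)
  expect_equal(out$fold_change, base$fold_change, tolerance = 1e-12)
})

test_that("volcano coordinates are finite closed forms", {
  rec <- tibble::tibble(gene_id = c("a", "b", "c"),
                        fold_change = c(1, 47.26, 2),
                        p_value = c(0.5, 1e-320, 1))
  v <- volcano_coordinates(rec)
  expect_equal(v$log2_fold_change[1], 0)
  expect_equal(v$log2_fold_change[2], log2(47.26))
  expect_equal(v$neg_log10_p[3], 0)
  expect_true(all(is.finite(v$neg_log10_p)))
})
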