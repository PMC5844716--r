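#' Geometric mean of positive intensities
#'
#' Fold changes between groups are ratios of per-group geometric means of
#' raw-scale intensities, the natural summary for log-normally distributed
#' microarray signal.
#'
#' @param values Numeric vector of positive intensities.
#' @return The geometric mean, `exp(mean(log(values)))`.
#' @export
#' @examples
#' geometric_mean(c(2, 8)) # 4
geometric_mean <- function(values) {
  check_positive(values, "values")
  exp(mean(log(values)))
}

#' Fold change and regulation trend from two geometric means
#'
#' @param geom_exp,geom_ctrl Geometric mean intensity in the experimental and
#'   control group.
#' @return A one-row tibble with `fold_change` (experimental / control) and
#'   `trend` ("up" if ratio > 1, "down" if < 1, "flat" at exactly 1).
#' @export
#' @examples
#' fold_change(2650.31, 56.08) # 47.26, up
fold_change <- function(geom_exp, geom_ctrl) {
  check_positive(geom_exp, "geom_exp")
  check_positive(geom_ctrl, "geom_ctrl")
  ratio <- geom_exp / geom_ctrl
  trend <- dplyr::case_when(ratio > 1 ~ "up", ratio < 1 ~ "down", TRUE ~ "flat")
  tibble::tibble(fold_change = ratio, trend = trend)
}

#' Fit the random-variance-model variance prior
#'
#' Pools information across genes by fitting an inverse-gamma prior on the
#' per-gene variance: with precision `1/sigma^2 ~ Gamma(a, scale = b)`, the
#' observed residual variances satisfy `s^2 * a * b ~ F(df, 2a)`. The
#' hyperparameters are estimated by maximum likelihood over the per-gene
#' pooled variances; the fitted prior adds `2a` degrees of freedom to every
#' gene's t-test, which is what makes the test usable with 3 replicates per
#' group.
#'
#' If fewer than 50 genes have positive variance, or the optimizer fails or
#' reaches a degenerate solution, the fit falls back (with a warning) to the
#' ordinary pooled t-test, encoded as `a = 0`, `1/b = 0`.
#'
#' @param sample_variances Per-gene pooled within-group variances.
#' @param df Residual degrees of freedom each variance was computed with
#'   (n1 + n2 - 2 for a two-group design).
#' @return An object of class `rvm_model` with elements `a`, `b`,
#'   `df_residual`, `fallback`, `converged`, `log_lik`, `n_genes`.
#' @export
fit_rvm <- function(sample_variances, df) {
  check_count(df, "df", min = 1L)
  s2 <- sample_variances[is.finite(sample_variances) & sample_variances > 0]

  fallback <- function(reason) {
    warn(paste0("RVM fit fell back to the ordinary pooled t-test: ", reason))
    structure(
      list(a = 0, b = Inf, df_residual = df, fallback = TRUE,
           converged = FALSE, log_lik = NA_real_,
           n_genes = length(sample_variances)),
      class = "rvm_model"
    )
  }

  if (length(s2) < 50L) {
    return(fallback(sprintf("only %d genes with positive variance (< 50)",
                            length(s2))))
  }
  if (sd(log(s2)) < 1e-10) {
    return(fallback("variances are (numerically) constant; prior not identifiable"))
  }

  # negative log-likelihood of s^2 under s^2 * a * b ~ F(df, 2a),
  # parameterized on the log scale to keep a, b > 0
  nll <- function(par) {
    a <- exp(par[1])
    b <- exp(par[2])
    ll <- suppressWarnings(
      sum(stats::df(s2 * a * b, df1 = df, df2 = 2 * a, log = TRUE) +
            log(a * b)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  init <- c(log(2), log(1 / mean(s2)))
  fit <- tryCatch(
    optim(init, nll, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$value)) {
    return(fallback("optimizer error"))
  }
  a <- exp(fit$par[1])
  b <- exp(fit$par[2])
  if (!is.finite(a) || !is.finite(b) || a > 1e6 || a < 1e-6) {
    return(fallback("degenerate hyperparameter estimate"))
  }
  structure(
    list(a = a, b = b, df_residual = df, fallback = FALSE,
         converged = fit$convergence == 0, log_lik = -fit$value,
         n_genes = length(s2)),
    class = "rvm_model"
  )
}

#' @export
print.rvm_model <- function(x, ...) {
  cat("Random variance model (inverse-gamma variance prior)\n")
  if (x$fallback) {
    cat("  degenerate fit: ordinary pooled t-test fallback\n")
  } else {
    cat(sprintf("  a = %.4f, b = %.4g (prior df added: %.2f)\n",
                x$a, x$b, 2 * x$a))
  }
  cat(sprintf("  residual df = %d, genes = %d\n", x$df_residual, x$n_genes))
  invisible(x)
}

#' @method tidy rvm_model
#' @export
tidy.rvm_model <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b)
  )
}

#' @method glance rvm_model
#' @export
glance.rvm_model <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b, df_prior = 2 * x$a, df_residual = x$df_residual,
    log_lik = x$log_lik, fallback = x$fallback, n_genes = x$n_genes
  )
}

# Moderated two-sample t-test on a log2 matrix. Returns statistic and
# two-sided p per row. Degenerate rows (zero moderated variance) get
# statistic 0 / p 1 when the mean difference is also zero, +-Inf / p 0
# otherwise.
rvm_t_core <- function(log2_mat, idx_exp, idx_ctrl, model) {
  n1 <- length(idx_exp)
  n2 <- length(idx_ctrl)
  m1 <- rowMeans(log2_mat[, idx_exp, drop = FALSE])
  m2 <- rowMeans(log2_mat[, idx_ctrl, drop = FALSE])
  v1 <- apply(log2_mat[, idx_exp, drop = FALSE], 1, var)
  v2 <- apply(log2_mat[, idx_ctrl, drop = FALSE], 1, var)
  df_res <- n1 + n2 - 2L
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_res
  prior_term <- if (is.finite(model$b)) 2 / model$b else 0
  s2_mod <- (df_res * s2 + prior_term) / (df_res + 2 * model$a)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  stat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- 2 * pt(-abs(stat), df = df_res + 2 * model$a)
  list(statistic = stat, p_value = p, mean_exp = m1, mean_ctrl = m2, s2 = s2)
}

#' RVM-moderated t-test per gene
#'
#' Log2-transforms the intensities, pools the two within-group variances,
#' shrinks them toward the fitted inverse-gamma prior
#' (`s2_mod = (df * s2 + 2/b) / (df + 2a)`) and refers the moderated
#' statistic to a t distribution with `df + 2a` degrees of freedom.
#'
#' @param expr Expression tibble (`gene_id` + sample columns, positive raw
#'   intensities).
#' @param groups Tibble with `sample_id`, `group`.
#' @param model An `rvm_model` from [fit_rvm()]; if `NULL`, fitted here.
#' @param exp_group,ctrl_group Group labels.
#' @return Tibble with `gene_id`, `statistic`, `p_value`.
#' @export
rvm_t_test <- function(expr, groups, model = NULL,
                       exp_group = "experimental", ctrl_group = "control") {
  check_expression(expr, groups, exp_group, ctrl_group)
  se <- group_samples(groups, exp_group)
  sc <- group_samples(groups, ctrl_group)
  if (length(se) < 2L || length(sc) < 2L) {
    abort("each group needs >= 2 samples (within-group variance undefined).",
          class = "hubgene_domain_error")
  }
  mat <- log2(as.matrix(expr[-1]))
  idx_exp <- match(se, colnames(mat))
  idx_ctrl <- match(sc, colnames(mat))
  if (is.null(model)) {
    n1 <- length(idx_exp); n2 <- length(idx_ctrl)
    v1 <- apply(mat[, idx_exp, drop = FALSE], 1, var)
    v2 <- apply(mat[, idx_ctrl, drop = FALSE], 1, var)
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    model <- fit_rvm(s2, df = n1 + n2 - 2L)
  }
  res <- rvm_t_core(mat, idx_exp, idx_ctrl, model)
  out <- tibble::tibble(gene_id = expr$gene_id,
                        statistic = res$statistic,
                        p_value = res$p_value)
  attr(out, "rvm") <- model
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()].
#'
#' @param p_values Numeric p-values in \[0, 1\], no missing values.
#' @return Adjusted values in \[0, 1\].
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values)) {
    abort("missing p-values are not allowed.", class = "hubgene_domain_error")
  }
  if (length(p_values) && (any(p_values < 0) || any(p_values > 1))) {
    abort("p-values must lie in [0, 1].", class = "hubgene_domain_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Differential screening of a two-group expression matrix
#'
#' Runs the full screen: RVM prior fit, moderated t-test on log2 intensities,
#' BH FDR, and raw-scale geometric-mean fold changes with up/down trends.
#'
#' @inheritParams rvm_t_test
#' @return Tibble with one row per gene: `gene_id`, `statistic`, `p_value`,
#'   `fdr`, `geom_mean_exp`, `geom_mean_ctrl`, `fold_change`, `trend`. The
#'   fitted `rvm_model` is attached as attribute `"rvm"`.
#' @export
diff_expression <- function(expr, groups, model = NULL,
                            exp_group = "experimental",
                            ctrl_group = "control") {
  check_expression(expr, groups, exp_group, ctrl_group)
  se <- group_samples(groups, exp_group)
  sc <- group_samples(groups, ctrl_group)
  tt <- rvm_t_test(expr, groups, model = model,
                   exp_group = exp_group, ctrl_group = ctrl_group)
  raw <- as.matrix(expr[-1])
  gexp <- exp(rowMeans(log(raw[, se, drop = FALSE])))
  gctl <- exp(rowMeans(log(raw[, sc, drop = FALSE])))
  ratio <- gexp / gctl
  out <- tt |>
    dplyr::mutate(
      fdr = bh_fdr(.data$p_value),
      geom_mean_exp = gexp,
      geom_mean_ctrl = gctl,
      fold_change = ratio,
      trend = dplyr::case_when(ratio > 1 ~ "up", ratio < 1 ~ "down",
                               TRUE ~ "flat")
    )
  attr(out, "rvm") <- attr(tt, "rvm")
  out
}

#' Select significant differential genes
#'
#' Applies the strict double cutoff `p < p_cut` AND `fdr < fdr_cut` and
#' orders the survivors by p-value, breaking ties by descending absolute
#' log2 fold change, then gene id.
#'
#' @param records Output of [diff_expression()].
#' @param p_cut,fdr_cut Strict upper cutoffs (defaults 0.05 / 0.05).
#' @return Filtered, ordered tibble.
#' @export
select_differential <- function(records, p_cut = 0.05, fdr_cut = 0.05) {
  check_proportion(p_cut, "p_cut")
  check_proportion(fdr_cut, "fdr_cut")
  records |>
    dplyr::filter(.data$p_value < p_cut, .data$fdr < fdr_cut) |>
    dplyr::arrange(.data$p_value, dplyr::desc(abs(log2(.data$fold_change))),
                   .data$gene_id)
}

#' Volcano-plot coordinates
#'
#' @param records Output of [diff_expression()].
#' @param p_floor p-values are floored here before taking -log10 so the
#'   coordinates stay finite.
#' @return Tibble with `gene_id`, `log2_fold_change`, `neg_log10_p`.
#' @export
volcano_coordinates <- function(records, p_floor = 1e-300) {
  records |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      log2_fold_change = log2(.data$fold_change),
      neg_log10_p = -log10(pmax(.data$p_value, p_floor))
    )
}
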