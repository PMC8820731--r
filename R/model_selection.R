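#' BIC comparison of two fits
#'
#' Difference in Bayesian information criterion between two fits of the same
#' data, with the conventional evidence threshold: a model is called the
#' better explanation only when the absolute BIC difference reaches 2;
#' smaller differences are inconclusive.
#'
#' @param fit_a,fit_b `joa_fit` objects fitted to the same trials.
#' @return A one-row tibble with `delta_bic` (`BIC_a - BIC_b`) and `verdict`
#'   (`"a_better"`, `"b_better"`, or `"inconclusive"`).
#' @export
compare_bic <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "joa_fit"), inherits(fit_b, "joa_fit"))
  if (fit_a$n != fit_b$n)
    stop("Fits are based on different numbers of trials.", call. = FALSE)
  delta <- fit_a$bic - fit_b$bic
  verdict <- if (abs(delta) < 2) "inconclusive"
             else if (delta < 0) "a_better" else "b_better"
  tibble::tibble(delta_bic = delta, verdict = verdict)
}

#' Akaike weights
#'
#' Normalised relative likelihoods `exp(-(AIC_i - min AIC) / 2)`, summing to
#' 1 across models. Invariant to adding a constant to every AIC.
#'
#' @param aic Numeric vector of AIC values (>= 2 models).
#' @return Numeric vector of weights summing to 1.
#' @examples
#' akaike_weights(c(100, 102))
#' @export
akaike_weights <- function(aic) {
  if (length(aic) < 2) stop("Need at least two models.", call. = FALSE)
  w <- exp(-(aic - min(aic)) / 2)
  w / sum(w)
}

#' Random-effects Bayesian model selection
#'
#' Group-level model comparison treating the identity of the best model as a
#' random effect across subjects (the hierarchical Dirichlet-multinomial
#' scheme standard in model-based cognitive neuroscience). The posterior
#' over population model frequencies is obtained by the usual variational
#' fixed-point iteration from per-subject log model evidence (here,
#' `-AIC / 2` by convention); exceedance probabilities (EP, the posterior
#' probability that each model is the most frequent) are then estimated from
#' `n_samples` Dirichlet posterior draws. The Bayes omnibus risk (BOR) is
#' the posterior probability of the null that all models are equally
#' frequent, computed from the variational free energy of the random-effects
#' model against the exact evidence of the null; protected exceedance
#' probabilities shrink the EPs toward chance accordingly:
#' `PEP = EP * (1 - BOR) + BOR / K`.
#'
#' @param log_evidence Numeric matrix, subjects x models, of log model
#'   evidence per subject (columns may be named).
#' @param n_samples Number of Dirichlet posterior draws for the EPs.
#' @param seed Optional integer seed for the draws.
#' @param alpha0 Dirichlet prior count per model (default 1, uninformative).
#' @param tol,max_iter Convergence control of the fixed-point iteration.
#' @return A `joa_bms` object with fields `alpha` (posterior Dirichlet
#'   counts), `expected_freq`, `ep`, `bor`, `pep`, `n_samples`. [tidy()] and
#'   [glance()] methods are provided.
#' @examples
#' le <- cbind(second = rep(0, 10), first = rep(2, 10))
#' rfx_bms(le, n_samples = 1e5, seed = 1)
#' @export
rfx_bms <- function(log_evidence, n_samples = 1e6, seed = NULL, alpha0 = 1,
                    tol = 1e-8, max_iter = 500) {
  log_evidence <- as.matrix(log_evidence)
  n <- nrow(log_evidence)
  K <- ncol(log_evidence)
  if (n < 2 || K < 2)
    stop("Need at least two subjects and two models.", call. = FALSE)
  models <- colnames(log_evidence)
  if (is.null(models)) models <- paste0("model", seq_len(K))
  a0 <- rep(alpha0, K)

  # variational fixed point for the Dirichlet posterior over frequencies
  alpha <- a0 + n / K
  z <- matrix(1 / K, n, K)
  for (iter in seq_len(max_iter)) {
    lw <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    z <- exp(lw) / rowSums(exp(lw))
    alpha_new <- a0 + colSums(z)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  # free energy of the random-effects model (variational bound)
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  z_safe <- pmax(z, 1e-300)
  f1 <- sum(z * log_evidence) + sum(z %*% elog_r) - sum(z_safe * log(z_safe)) +
    lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * elog_r) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * elog_r))
  # exact evidence of the null: every subject's data explained by an
  # equal-frequency mixture of the models
  lmax <- apply(log_evidence, 1, max)
  f0 <- sum(lmax + log(rowMeans(exp(log_evidence - lmax))))
  bor <- 1 / (1 + exp(f1 - f0))

  # exceedance probabilities from Dirichlet posterior draws
  draw_ep <- function() {
    win <- integer(K)
    chunk <- 1e5
    left <- n_samples
    while (left > 0) {
      m <- min(chunk, left)
      g <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
      idx <- max.col(g)
      win <- win + tabulate(idx, K)
      left <- left - m
    }
    win / n_samples
  }
  ep <- if (is.null(seed)) draw_ep() else withr::with_seed(seed, draw_ep())
  pep <- ep * (1 - bor) + bor / K

  structure(
    list(models = models, alpha = stats::setNames(alpha, models),
         expected_freq = stats::setNames(alpha / sum(alpha), models),
         ep = stats::setNames(ep, models),
         bor = bor, pep = stats::setNames(pep, models),
         n_samples = n_samples, attribution = z, f1 = f1, f0 = f0,
         n_subjects = n),
    class = "joa_bms"
  )
}

#' @export
print.joa_bms <- function(x, ...) {
  cat("<joa_bms> ", x$n_subjects, " subjects, ", length(x$models),
      " models\n", sep = "")
  print(tidy(x))
  cat(sprintf("BOR = %.4f (%s posterior draws)\n", x$bor,
              format(x$n_samples, big.mark = ",")))
  invisible(x)
}

#' @rdname rfx_bms
#' @param x A `joa_bms` object.
#' @param ... Unused.
#' @method tidy joa_bms
#' @export
tidy.joa_bms <- function(x, ...) {
  tibble::tibble(model = x$models, alpha = unname(x$alpha),
                 expected_freq = unname(x$expected_freq),
                 ep = unname(x$ep), pep = unname(x$pep))
}

#' @rdname rfx_bms
#' @method glance joa_bms
#' @export
glance.joa_bms <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_models = length(x$models),
                 bor = x$bor, n_samples = x$n_samples)
}
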