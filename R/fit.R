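# Sequential (Type I) least-squares decomposition over ordered column blocks.
#
# Each block is orthogonalized against everything before it (twice, for
# numerical stability); its sum of squares is the squared projection of the
# response onto the new directions, i.e. the reduction in residual SS when
# the block enters after all preceding blocks. Columns that lose essentially
# all their norm in the orthogonalization are aliased with earlier terms and
# are dropped, reducing the block's degrees of freedom.
seq_anova_engine <- function(blocks, y, tol = 1e-8) {
  n <- length(y)
  Q <- matrix(0, n, 0)
  res <- vector("list", length(blocks))
  names(res) <- names(blocks)
  for (b in names(blocks)) {
    Xb <- blocks[[b]]
    ref <- pmax(sqrt(colSums(Xb^2)), 1)
    C <- Xb
    if (ncol(Q) > 0) {
      C <- C - Q %*% crossprod(Q, C)
      C <- C - Q %*% crossprod(Q, C)
    }
    keep <- sqrt(colSums(C^2)) > tol * ref
    dropped <- colnames(Xb)[!keep]
    C <- C[, keep, drop = FALSE]
    cnorm <- if (ncol(C) == 1) sqrt(sum(C^2)) else NA_real_
    beta <- if (ncol(C) == 1) sum(C * y) / cnorm^2 else NA_real_
    rank <- 0L
    SS <- 0
    if (ncol(C) > 0) {
      qrC <- qr(C)
      rank <- qrC$rank
      Qn <- qr.Q(qrC)[, seq_len(rank), drop = FALSE]
      g <- crossprod(Qn, y)
      SS <- sum(g^2)
      Q <- cbind(Q, Qn)
    }
    res[[b]] <- list(term = b, df = rank, ss = SS, beta = beta, cnorm = cnorm,
                     dropped = dropped)
  }
  rss <- sum(y^2) - sum(vapply(res, `[[`, numeric(1), "ss"))
  rss <- max(rss, 0)
  list(terms = res, rss = rss, df_res = n - ncol(Q), n = n)
}

#' Fit a sequential ANOVA over an SA design
#'
#' Least-squares fit with sums of squares attributed sequentially (Type I)
#' in the design's term order: each term's SS is the reduction in residual
#' SS when its block enters after all preceding blocks. Aliased columns
#' (norm below tolerance after orthogonalization) are dropped and the
#' block's degrees of freedom reduced accordingly.
#'
#' @param design An `sa_design` from [build_dual_design()] or
#'   [build_single_design()].
#' @param response Numeric response vector aligned with the design rows.
#' @param coefficients Also solve for the full least-squares coefficient
#'   vector (one extra QR); the block-level statistics never need it.
#' @return A list of class `sa_anova_fit` with elements `table` (tibble:
#'   term, df, ss, ms, one row per non-intercept term), `residual`
#'   (df, ss, ms), `coefficients` (full least-squares coefficients, `NA`
#'   for aliased columns), and internal per-block details.
#' @export
fit_sequential_anova <- function(design, response, coefficients = TRUE) {
  stopifnot(inherits(design, "sa_design"))
  if (length(response) != design$n) {
    sa_abort_precondition("response length does not match design rows")
  }
  if (anyNA(response)) {
    sa_abort_value("response contains missing values")
  }
  eng <- seq_anova_engine(design$blocks, response)
  model_df <- sum(vapply(eng$terms, `[[`, integer(1), "df"))
  if (eng$df_res < 0 || model_df >= eng$n) {
    sa_abort_precondition("model degrees of freedom exceed the sample size")
  }
  terms <- eng$terms[setdiff(names(eng$terms), "intercept")]
  tab <- tibble::tibble(
    term = unname(vapply(terms, `[[`, character(1), "term")),
    df = unname(vapply(terms, `[[`, integer(1), "df")),
    ss = unname(vapply(terms, `[[`, numeric(1), "ss"))
  )
  tab$ms <- ifelse(tab$df > 0, tab$ss / tab$df, NA_real_)
  coefs <- NULL
  if (coefficients) {
    X <- design_matrix(design)
    coefs <- qr.coef(qr(X), response)
  }
  structure(
    list(
      table = tab,
      residual = list(df = eng$df_res, ss = eng$rss,
                      ms = if (eng$df_res > 0) eng$rss / eng$df_res else NA_real_),
      coefficients = coefs,
      engine = eng,
      design_meta = design$meta
    ),
    class = "sa_anova_fit"
  )
}

#' @export
print.sa_anova_fit <- function(x, ...) {
  cat("Sequential ANOVA (", x$design_meta$model, " SA model)\n", sep = "")
  print(x$table)
  cat(sprintf("Residual: df = %d, SS = %.6g, MS = %.6g\n",
              x$residual$df, x$residual$ss, x$residual$ms))
  invisible(x)
}

#' Fraction of interaction mean square explained by an SA term
#'
#' `phi = (ms_constrained - ms_free) / ms_constrained`, where
#' `ms_constrained` is the origin x test interaction mean square from the
#' model with the SA term constrained to zero (the interaction block then
#' carries its full `(J-1)(K-1)` degrees of freedom) and `ms_free` is the
#' interaction-remainder mean square with the SA term estimated. The value
#' can be negative because the two mean squares use different degrees of
#' freedom.
#'
#' @param ms_constrained Interaction MS under the SA-free (constrained)
#'   model; must be positive.
#' @param ms_free Interaction-remainder MS under the full model.
#' @return A single number `<= 1`.
#' @examples
#' phi(10, 10) # 0
#' phi(10, 0)  # 1
#' phi(4.0, 4.2) # -0.05
#' @export
phi <- function(ms_constrained, ms_free) {
  if (!is.finite(ms_constrained) || ms_constrained < 0 ||
      !is.finite(ms_free) || ms_free < 0) {
    sa_abort_value("phi() requires finite non-negative mean squares")
  }
  if (ms_constrained == 0) {
    rlang::warn("phi undefined: constrained interaction mean square is zero")
    return(NaN)
  }
  (ms_constrained - ms_free) / ms_constrained
}
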