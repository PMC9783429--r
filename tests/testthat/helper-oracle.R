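# Brute-force nested-model oracle for sequential sums of squares: refit the
# cumulative column sets with lm.fit and take residual-SS differences.
# Independent of the package's Gram-Schmidt engine.
oracle_sequential <- function(design, y) {
  blocks <- design$blocks
  rss <- numeric(length(blocks) + 1)
  dfs <- integer(length(blocks) + 1)
  rss[1] <- sum(y^2)
  dfs[1] <- 0L
  X <- NULL
  for (i in seq_along(blocks)) {
    X <- cbind(X, blocks[[i]])
    fit <- lm.fit(X, y)
    rss[i + 1] <- sum(fit$residuals^2)
    dfs[i + 1] <- qr(X)$rank
  }
  tibble::tibble(
    term = names(blocks),
    df = diff(dfs),
    ss = pmax(-diff(rss), 0)
  )
}

# Independent phi: interaction MS from constrained (SA column removed) and
# free models, both refit from scratch with lm.fit.
oracle_phi <- function(design, y, sa_block, int_block) {
  seq_free <- oracle_sequential(design, y)
  constrained <- design
  constrained$blocks <- constrained$blocks[setdiff(names(constrained$blocks), sa_block)]
  seq_con <- oracle_sequential(constrained, y)
  ms <- function(tab, term) {
    i <- match(term, tab$term)
    tab$ss[i] / tab$df[i]
  }
  (ms(seq_con, int_block) - ms(seq_free, int_block)) / ms(seq_con, int_block)
}

# Small fast study-like configs for tests.
tiny_config <- function(...) {
  sim_config(pops_per_env = c(2, 2, 2), units_per_pop_phase = 2, ...)
}
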