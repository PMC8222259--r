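# Nonparametric statistical battery: exact/approximate Mann-Whitney,
# Freeman-Halton (r x c Fisher) exact tests, Kruskal-Wallis with Dunn's
# post hoc, Spearman correlation and inter-rater agreement. All routines
# are authored here (base R supplies only distribution functions and the
# Patefield sampler for the Monte Carlo fallback) so that they can be
# validated against independent enumeration oracles, and so that the
# two-sided conventions match those of the published tables: Fisher-type
# tests sum the probabilities of all fixed-margin tables no more probable
# than the observed one.

#' Contingency table with validation
#'
#' @param counts r x c matrix of nonnegative integer counts (r, c >= 2,
#'   grand total >= 1).
#' @param row_labels,col_labels optional dimension labels.
#' @return a validated `contingency_table` (an integer matrix subclass).
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  m <- as.matrix(counts)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stopf("contingency table must be at least 2 x 2")
  if (any(m < 0) || any(m != round(m)))
    stopf("contingency table cells must be nonnegative integers")
  if (sum(m) < 1) stopf("contingency table must have a positive total")
  storage.mode(m) <- "integer"
  if (!is.null(row_labels)) rownames(m) <- row_labels
  if (!is.null(col_labels)) colnames(m) <- col_labels
  structure(m, class = c("contingency_table", class(m)))
}

#' Read a contingency table from a CSV matrix
#'
#' @param path CSV file: first column row labels, remaining columns counts.
#' @export
read_contingency_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(is.na(m))) stopf("contingency CSV '%s' contains missing cells",
                           path)
  if (any(m < 0)) stopf("contingency CSV '%s' contains negative cells", path)
  contingency_table(m)
}

new_test_result <- function(method, statistic, p_value, n = NULL,
                            exact = NA, adjustment = "none", note = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(list(method = method, statistic = statistic,
                 p_value = min(p_value, 1), n = n, exact = exact,
                 adjustment = adjustment, note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, p = %s%s\n", x$method, x$statistic,
              format_p(x$p_value),
              if (isTRUE(x$exact)) " (exact)"
              else if (isFALSE(x$exact)) " (approximate)" else ""))
  invisible(x)
}

# table-style p formatting: 4 decimals, "< 0.0001" under 0.00005
format_p <- function(p) {
  ifelse(is.na(p), "-",
         ifelse(p < 0.00005, "< 0.0001",
                ifelse(p > 0.99, "> 0.99", sprintf("%.4f", p))))
}

# ---- Mann-Whitney -----------------------------------------------------

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided. The exact null distribution of U (by dynamic-programming
#' count of rank-sum configurations) is used when `nx * ny <= exact_max`
#' and the data have no ties; otherwise a tie-corrected normal
#' approximation with continuity correction is used, and the result flags
#' which branch ran.
#'
#' @param x,y numeric samples (each nonempty).
#' @param exact_max largest `nx * ny` for which the exact distribution is
#'   enumerated.
#' @return a `test_result` with the U statistic (for `x`).
#' @export
mann_whitney <- function(x, y, exact_max = 400) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stopf("both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && nx * ny <= exact_max) {
    cnt <- wilcox_count(nx, ny)          # counts of U = 0..nx*ny
    tot <- sum(cnt)
    lo <- sum(cnt[seq_len(U + 1)])       # P(U <= u) * total
    hi <- sum(cnt[(U + 1):(nx * ny + 1)])
    p <- min(1, 2 * min(lo, hi) / tot)
    return(new_test_result("Mann-Whitney (exact)", U, p,
                           n = c(nx = nx, ny = ny), exact = TRUE))
  }
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  N <- nx + ny
  sig2 <- nx * ny / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sig2 <= 0) {
    return(new_test_result("Mann-Whitney (normal approx.)", U, 1,
                           n = c(nx = nx, ny = ny), exact = FALSE,
                           note = "all values tied"))
  }
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sig2)   # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_test_result("Mann-Whitney (normal approx.)", U, p,
                  n = c(nx = nx, ny = ny), exact = FALSE)
}

# Null distribution of U for sample sizes m, n without ties: the number
# of rank configurations with U = u equals the number of partitions of u
# into at most m parts each <= n, i.e. the coefficients of the Gaussian
# binomial [m + n choose m]_q, built by alternating exact polynomial
# multiplication by (1 - q^(n+k)) and division by (1 - q^k).
wilcox_count <- function(m, n) {
  maxu <- m * n
  co <- numeric(maxu + 1)
  co[1] <- 1
  for (k in seq_len(m)) {
    s <- n + k
    if (s <= maxu) for (u in maxu:s) co[u + 1] <- co[u + 1] - co[u + 1 - s]
    for (u in k:maxu) co[u + 1] <- co[u + 1] + co[u + 1 - k]
  }
  co
}

# ---- Freeman-Halton / Fisher exact r x c ------------------------------

#' Fisher's exact test for r x c tables (Freeman-Halton)
#'
#' Exact two-sided p: the sum of multivariate hypergeometric probabilities
#' (row and column margins fixed) over all tables whose probability does
#' not exceed that of the observed table (relative tie tolerance
#' `tie_tol`). This sum-of-smaller-probabilities convention reproduces the
#' classic two-sided 2 x 2 Fisher test. Tables whose fixed-margin
#' enumeration would exceed `max_tables` fall back to a seeded Monte Carlo
#' estimate (Patefield sampler) flagged as approximate.
#'
#' @param table a [contingency_table()] (or matrix of counts).
#' @param tie_tol relative tolerance for probability ties.
#' @param max_tables enumeration cap.
#' @param mc_draws Monte Carlo draws for the fallback.
#' @param mc_seed seed for the fallback.
#' @return a `test_result`; the statistic is the observed table
#'   probability.
#' @export
fisher_exact_rxc <- function(table, tie_tol = 1e-12, max_tables = 1e7,
                             mc_draws = 1e6, mc_seed = 1L) {
  tb <- if (inherits(table, "contingency_table")) table
        else contingency_table(table)
  rs <- rowSums(tb); cs <- colSums(tb)
  if (any(rs == 0) || any(cs == 0))
    stopf("all row and column margins must be positive")
  logp_obs <- log_table_prob(tb, rs, cs)
  n_est <- count_margin_tables(rs, cs, max_tables)
  if (is.na(n_est)) {
    p <- fisher_rxc_montecarlo(tb, rs, cs, logp_obs, tie_tol, mc_draws,
                               mc_seed)
    return(new_test_result("Fisher exact r x c (Monte Carlo)",
                           exp(logp_obs), p, n = sum(tb), exact = FALSE,
                           note = sprintf("%g draws, seed %d", mc_draws,
                                          mc_seed)))
  }
  acc <- new.env()
  acc$p <- 0
  enumerate_tables(rs, cs, function(logp) {
    if (logp <= logp_obs + log1p(tie_tol)) acc$p <- acc$p + exp(logp)
  })
  new_test_result("Fisher exact r x c (Freeman-Halton)", exp(logp_obs),
                  min(1, acc$p), n = sum(tb), exact = TRUE)
}

log_table_prob <- function(tb, rs = rowSums(tb), cs = colSums(tb)) {
  sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(sum(tb)) -
    sum(lfactorial(tb))
}

# number of fixed-margin tables, or NA when it exceeds `cap`
count_margin_tables <- function(rs, cs, cap) {
  n <- 0
  done <- tryCatch({
    enumerate_tables(rs, cs, function(logp) {
      n <<- n + 1
      if (n > cap) stop("cap")
    })
    TRUE
  }, error = function(e) FALSE)
  if (done) n else NA
}

# depth-first enumeration of all nonnegative integer tables with the given
# margins; calls visit(log probability) for each complete table
enumerate_tables <- function(rs, cs, visit) {
  r <- length(rs); cN <- length(cs)
  const <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(sum(rs))
  cell_rec <- function(i, j, row_left, col_left, logfact_acc) {
    if (i == r) {
      # last row forced by column margins
      if (any(col_left < 0)) return()
      visit(const - logfact_acc - sum(lfactorial(col_left)))
      return()
    }
    if (j == cN) {
      # last cell of the row absorbs the remainder
      v <- row_left
      if (v < 0 || v > col_left[cN]) return()
      cl <- col_left
      cl[cN] <- cl[cN] - v
      cell_rec(i + 1L, 1L, rs[min(i + 1L, r)], cl,
               logfact_acc + lfactorial(v))
      return()
    }
    hi <- min(row_left, col_left[j])
    # feasibility: remaining cells in this row must absorb row_left - v
    rest <- sum(col_left[-seq_len(j)])
    lo <- max(0L, row_left - rest)
    if (hi < lo) return()
    for (v in lo:hi) {
      cl <- col_left
      cl[j] <- cl[j] - v
      cell_rec(i, j + 1L, row_left - v, cl, logfact_acc + lfactorial(v))
    }
  }
  cell_rec(1L, 1L, rs[1L], cs, 0)
  invisible(NULL)
}

fisher_rxc_montecarlo <- function(tb, rs, cs, logp_obs, tie_tol, draws,
                                  seed) {
  with_seed(seed, {
    hits <- 0L
    block <- 10000L
    left <- draws
    while (left > 0) {
      b <- min(block, left)
      sims <- stats::r2dtable(b, rs, cs)
      lp <- vapply(sims, function(s) log_table_prob(s, rs, cs), 0)
      hits <- hits + sum(lp <= logp_obs + log1p(tie_tol))
      left <- left - b
    }
    (hits + 1) / (draws + 1)
  })
}

# ---- Kruskal-Wallis + Dunn --------------------------------------------

#' Kruskal-Wallis test with Dunn's multiple comparisons
#'
#' Omnibus H with tie correction, chi-squared p on k - 1 df; Dunn's
#' pairwise z tests with tie-corrected variance, two-sided p multiplied by
#' the number of comparisons m = k(k-1)/2 (Bonferroni), capped at 1.
#'
#' @param groups list of numeric samples (>= 2 groups, each nonempty).
#' @param dunn_alpha omnibus threshold below which the post hoc is run
#'   (set to 1 to always run it).
#' @return list with `omnibus` (a `test_result`) and `pairwise` (a
#'   data.frame of Dunn comparisons, or NULL when the omnibus is not
#'   rejected).
#' @export
kruskal_wallis_dunn <- function(groups, dunn_alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stopf("need at least 2 groups")
  if (any(!lengths(groups))) stopf("every group must be nonempty")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  Rbar <- tapply(r, factor(g, levels = names(groups)), mean)
  ni <- lengths(groups)
  H0 <- 12 / (N * (N + 1)) * sum(ni * (Rbar - (N + 1) / 2)^2)
  tie_tab <- table(x)
  Tsum <- sum(tie_tab^3 - tie_tab)
  corr <- 1 - Tsum / (N^3 - N)
  if (corr <= 0) {
    omnibus <- new_test_result("Kruskal-Wallis", 0, 1, n = ni, exact = FALSE,
                               note = "all values identical")
    return(list(omnibus = omnibus, pairwise = NULL))
  }
  H <- H0 / corr
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  omnibus <- new_test_result("Kruskal-Wallis", H, p, n = ni, exact = FALSE)
  pairwise <- NULL
  if (p < dunn_alpha && k >= 2L) {
    m <- k * (k - 1) / 2
    sig2_base <- (N * (N + 1) / 12) - Tsum / (12 * (N - 1))
    rows <- list()
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      se <- sqrt(sig2_base * (1 / ni[i] + 1 / ni[j]))
      z <- (Rbar[i] - Rbar[j]) / se
      p_raw <- 2 * stats::pnorm(-abs(z))
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = names(groups)[i], group2 = names(groups)[j], z = z,
        p_unadjusted = p_raw, p_adjusted = min(1, m * p_raw))
    }
    pairwise <- do.call(rbind, rows)
    rownames(pairwise) <- NULL
    attr(pairwise, "adjustment") <- "dunn-bonferroni"
  }
  list(omnibus = omnibus, pairwise = pairwise)
}

# ---- Spearman ---------------------------------------------------------

#' Spearman rank correlation
#'
#' Tie-aware rho (Pearson correlation of mid-ranks); two-sided p from the
#' t approximation on n - 2 df.
#'
#' @param x,y paired numeric vectors, n >= 3 (pairs with missing values
#'   are dropped).
#' @return a `test_result` with statistic rho (NA, flagged, when either
#'   variable has zero rank variance).
#' @export
spearman <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x)[keep]; y <- as.numeric(y)[keep]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(new_test_result("Spearman", NA_real_, NA_real_, n = n,
                           note = "zero variance; rho undefined"))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new_test_result("Spearman", rho, p, n = n, exact = FALSE)
}

#' Spearman correlation matrix over variables
#'
#' Applies [spearman()] to every variable pair (pairwise-complete).
#'
#' @param data data.frame of numeric variables.
#' @return a `correlation_matrix`: list with `rho` and `p` matrices.
#' @export
correlation_matrix <- function(data) {
  data <- as.data.frame(data)
  v <- names(data)
  k <- length(v)
  rho <- matrix(NA_real_, k, k, dimnames = list(v, v))
  pm <- rho
  diag(rho) <- 1
  diag(pm) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    res <- tryCatch(spearman(data[[i]], data[[j]]),
                    error = function(e) NULL)
    if (!is.null(res)) {
      rho[i, j] <- rho[j, i] <- res$statistic
      pm[i, j] <- pm[j, i] <- res$p_value
    }
  }
  structure(list(variables = v, rho = rho, p = pm),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d variables\n", length(x$variables)))
  print(round(x$rho, 3))
  invisible(x)
}

#' Inter-rater agreement for ordinal scores
#'
#' Spearman's rho for every rater pair (the scores are ordinal, so rank
#' correlation is the agreement measure). A rater with constant scores
#' yields NA for their pairs, flagged in the result.
#'
#' @param scores subjects x raters matrix or data.frame of ordinal scores.
#' @return data.frame with `rater1`, `rater2`, `rho`, `p_value`, `note`.
#' @export
interrater_agreement <- function(scores) {
  m <- as.matrix(scores)
  if (ncol(m) < 2L) stopf("need at least 2 raters")
  if (nrow(m) < 3L) stopf("need at least 3 subjects")
  if (is.null(colnames(m))) colnames(m) <- paste0("rater", seq_len(ncol(m)))
  rows <- list()
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    res <- spearman(m[, i], m[, j])
    rows[[length(rows) + 1L]] <- data.frame(
      rater1 = colnames(m)[i], rater2 = colnames(m)[j],
      rho = res$statistic, p_value = res$p_value,
      note = res$note %||% "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
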