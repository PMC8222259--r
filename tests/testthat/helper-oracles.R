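# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (full enumeration, per-pixel loops) and share no code
# with the implementation paths they check.

# two-sided Mann-Whitney p by complete enumeration of all group splits
oracle_mw_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(length(pooled), nx)
  U <- apply(splits, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(U <= obs), mean(U >= obs)))
}

# Freeman-Halton p by brute-force table enumeration: expand a grid over
# the free (r-1) x (c-1) cells and keep margin-consistent tables
oracle_fisher_p <- function(tb) {
  rs <- rowSums(tb); cs <- colSums(tb)
  r <- nrow(tb); cc <- ncol(tb)
  free_r <- seq_len(r - 1); free_c <- seq_len(cc - 1)
  ranges <- lapply(seq_len((r - 1) * (cc - 1)), function(k) {
    i <- free_r[((k - 1) %% (r - 1)) + 1]
    j <- free_c[((k - 1) %/% (r - 1)) + 1]
    0:min(rs[i], cs[j])
  })
  grid <- do.call(expand.grid, ranges)
  prob_of <- function(cells) {
    m <- matrix(0, r, cc)
    m[free_r, free_c] <- matrix(unlist(cells), r - 1, cc - 1)
    m[r, free_c] <- cs[free_c] - colSums(m[free_r, free_c, drop = FALSE])
    m[, cc] <- rs - rowSums(m[, free_c, drop = FALSE])
    if (any(m < 0)) return(NA_real_)
    exp(sum(lfactorial(rs)) + sum(lfactorial(cs)) -
          lfactorial(sum(rs)) - sum(lfactorial(m)))
  }
  probs <- apply(grid, 1, prob_of)
  probs <- probs[!is.na(probs)]
  p_obs <- exp(sum(lfactorial(rs)) + sum(lfactorial(cs)) -
                 lfactorial(sum(tb)) - sum(lfactorial(tb)))
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# naive per-column run count (no bridging, any run length counts)
oracle_run_count <- function(col) {
  col <- as.integer(col != 0)
  sum(diff(c(0L, col)) == 1L)
}

# per-pixel nearest-prototype classification by explicit loops
oracle_classify <- function(image, palette) {
  d <- dim(image$pixels)
  out <- matrix(0L, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    lab <- grDevices::convertColor(matrix(image$pixels[i, j, ] / 255, 1),
                                   from = "sRGB", to = "Lab")
    dd <- sqrt(rowSums(sweep(palette$lab, 2, as.numeric(lab))^2))
    best <- which.min(dd)
    out[i, j] <- if (dd[best] <= palette$max_distance) best else 0L
    if (lab[1] > palette$white_L) {
      bg <- match("background", palette$classes$role)
      if (!is.na(bg)) out[i, j] <- bg
    }
  }
  out
}

# numeric root-finding oracle for the area-conservation thinning map
oracle_thinned_b <- function(a, b, a_new) {
  target <- pi * ((a + b)^2 - a^2)
  stats::uniroot(function(bn) pi * ((a_new + bn)^2 - a_new^2) - target,
                 c(1e-12, a + b + 10), tol = 1e-12)$root
}

# elastin mask (role-matched) from a classified label mask
elastin_mask_of <- function(mask) {
  pal <- attr(mask, "palette")
  idx <- which(pal$classes$role == "elastin")
  matrix(as.vector(mask) %in% idx, nrow(mask), ncol(mask))
}
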