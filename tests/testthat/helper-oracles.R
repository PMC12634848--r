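# Independent statistical oracles, coded from closed forms (never the same
# library calls the package uses).

# Two-sample t test p value from the textbook formulas.
oracle_t_p <- function(x, y, equal_var = TRUE) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  if (equal_var) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2 <- vx / nx + vy / ny
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  2 * stats::pt(-abs(tstat), df)
}

# Pearson r and two-sided p from the sum formulas + t transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - mean(x); sy <- y - mean(y)
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# Brute-force matrix deconvolution: a candidate is nominated iff both of
# its pool memberships are in the positive set.
brute_decode <- function(design, positive_pools) {
  lay <- design$layout
  ids <- character()
  for (i in seq_len(nrow(lay))) {
    if (lay$row_pool[i] %in% positive_pools &&
        lay$col_pool[i] %in% positive_pools) {
      ids <- c(ids, lay$candidate_id[i])
    }
  }
  ids[order(lay$rank_index[match(ids, lay$candidate_id)])]
}

# Tukey-adjusted pairwise route p values within each stimulus, from cell
# means, the pooled within-cell variance and the studentized range.
oracle_tukey_routes <- function(d) {
  cells <- split(d$freq_ifng, interaction(d$stimulus, d$route, drop = TRUE))
  sse <- sum(vapply(cells, function(v) sum((v - mean(v))^2), numeric(1)))
  df <- nrow(d) - length(cells)
  mse <- sse / df
  routes <- sort(unique(d$route))
  out <- list()
  for (s in unique(d$stimulus)) {
    for (i in seq_len(length(routes) - 1)) {
      for (j in seq(i + 1, length(routes))) {
        yi <- d$freq_ifng[d$stimulus == s & d$route == routes[i]]
        yj <- d$freq_ifng[d$stimulus == s & d$route == routes[j]]
        se <- sqrt(mse * (1 / length(yi) + 1 / length(yj)))
        q <- abs(mean(yi) - mean(yj)) / (se / sqrt(2))
        out[[length(out) + 1L]] <- data.frame(
          stimulus = s, a = routes[i], b = routes[j],
          p = stats::ptukey(q, nmeans = length(routes), df = df,
                            lower.tail = FALSE)
        )
      }
    }
  }
  do.call(rbind, out)
}
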