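# Independent brute-force oracles used across the suite.

# Offspring call distribution for a mating, by direct enumeration of all
# 2^4 x 2^4 = 256 equally likely homolog choices. Deliberately indexes the
# raw configuration strings and never calls the package's gamete machinery.
oracle_segregation <- function(maternal, paternal = maternal) {
  m <- strsplit(maternal, "")[[1L]]
  p <- strsplit(paternal, "")[[1L]]
  out <- c(AA = 0, AB = 0, BB = 0, null = 0)
  for (cm in 0:15) {
    mch <- bitwAnd(bitwShiftR(cm, 0:3), 1L)          # homolog choice per subgenome
    gam_m <- m[2L * (1:4) - 1L + mch]
    for (cp in 0:15) {
      pch <- bitwAnd(bitwShiftR(cp, 0:3), 1L)
      gam_p <- p[2L * (1:4) - 1L + pch]
      sym <- c(gam_m, gam_p)
      call <- if (any(sym == "A") && any(sym == "B")) "AB"
              else if (any(sym == "A")) "AA"
              else if (any(sym == "B")) "BB" else "null"
      out[call] <- out[call] + 1 / 256
    }
  }
  out
}

# All valid configurations with every present subgenome drawn from the given
# per-subgenome pair alphabet.
oracle_all_configs <- function(pair_choices = c("AB", "AA", "BB", "OO")) {
  grid <- expand.grid(s1 = pair_choices, s2 = pair_choices,
                      s3 = pair_choices, s4 = pair_choices,
                      stringsAsFactors = FALSE)
  cfg <- apply(grid, 1L, paste, collapse = "")
  cfg[cfg != "OOOOOOOO"]
}

# Exact multinomial log-likelihood grid search for the two-point F2
# recombination fraction; independent of the EM implementation. `n9` is the
# 3x3 joint count table (rows locus a = AA/AB/BB, cols locus b), `step` the
# grid resolution. Both phases are searched; returns the global optimum.
oracle_grid_r <- function(n9, step = 1e-4) {
  grid <- seq(0, 0.5, by = step)
  gam <- expand.grid(m1 = 0:1, m2 = 0:1, p1 = 0:1, p2 = 0:1)
  k <- (gam$m1 != gam$m2) + (gam$p1 != gam$p2)   # recombinant gametes, coupling
  g1 <- gam$m1 + gam$p1
  g2 <- gam$m2 + gam$p2
  best <- list(ll = -Inf, r = NA_real_, phase = NA_character_)
  for (phase in c("coupling", "repulsion")) {
    # cell probabilities over the whole grid at once: accumulate each of the
    # 16 equally structured gamete-pair combos into its observed cell
    p_cell <- vector("list", 9L)
    for (i in seq_len(16L)) {
      cell <- g1[i] * 3L + (if (phase == "repulsion") 2L - g2[i] else g2[i]) + 1L
      w <- ((1 - grid) / 2)^(2 - k[i]) * (grid / 2)^k[i]
      p_cell[[cell]] <- if (is.null(p_cell[[cell]])) w else p_cell[[cell]] + w
    }
    ll <- numeric(length(grid))
    for (cell in 1:9) {
      n <- n9[(cell - 1L) %/% 3L + 1L, (cell - 1L) %% 3L + 1L]
      if (n == 0) next
      p <- p_cell[[cell]]
      ll <- ll + ifelse(p > 0, n * log(p), -Inf)
    }
    i <- which.max(ll)
    if (ll[i] > best$ll) best <- list(ll = ll[i], r = grid[i], phase = phase)
  }
  best
}

# Random two-locus F2 joint count tables: drawn from the true model at a
# random r and phase (sometimes with label swaps), plus occasional fully
# random tables. Returns a 3x3 count matrix.
oracle_random_table <- function(n_max = 30) {
  n <- sample(4:n_max, 1L)
  if (stats::runif(1) < 0.2) {
    tab <- matrix(stats::rmultinom(1, n, rep(1 / 9, 9)), 3, 3)
  } else {
    r <- stats::runif(1, 0, 0.5)
    gam <- expand.grid(m1 = 0:1, m2 = 0:1, p1 = 0:1, p2 = 0:1)
    k <- (gam$m1 != gam$m2) + (gam$p1 != gam$p2)
    swap <- sample(c(TRUE, FALSE), 1L)
    p <- matrix(0, 3, 3)
    for (i in seq_len(16L)) {
      gg2 <- if (swap) 2L - gam$g2 else NULL
      c1 <- gam$m1[i] + gam$p1[i] + 1L
      c2 <- gam$m2[i] + gam$p2[i]
      if (swap) c2 <- 2L - c2
      p[c1, c2 + 1L] <- p[c1, c2 + 1L] +
        ((1 - r) / 2)^(2 - k[i]) * (r / 2)^k[i]
    }
    tab <- matrix(stats::rmultinom(1, n, as.vector(p)), 3, 3)
  }
  tab
}
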