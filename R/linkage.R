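#' @name linkage
#' @title Two-point linkage machinery for S1 (F2-design) populations
#' @description An S1 of a heterozygous parent is, for linkage purposes, an
#'   F2 design: each offspring receives two independent parental gametes and
#'   each gamete is a recombinant between two loci with probability r. The
#'   functions here estimate r per locus pair by EM over the 16 latent
#'   gamete-pair combinations, which cleanly accommodates dominant loci
#'   (where the observed call collapses two underlying genotypes) and both
#'   linkage phases.
NULL

# ---- latent gamete-pair machinery ------------------------------------------
# Combos: maternal/paternal gamete alleles at locus 1 and 2 (0 = A, 1 = B).
# Under coupling the parental haplotypes are (A,A) and (B,B), so a gamete is
# recombinant iff its two alleles differ; repulsion swaps parental and
# recombinant roles.
.combos <- local({
  g <- expand.grid(m1 = 0:1, m2 = 0:1, p1 = 0:1, p2 = 0:1)
  g$k <- (g$m1 != g$m2) + (g$p1 != g$p2)  # recombinant gametes, coupling
  g$g1 <- g$m1 + g$p1                     # genotype code at locus 1 (0/1/2)
  g$g2 <- g$m2 + g$p2
  g
})

# Observed-category index (1..3) of an underlying genotype code 0/1/2 for a
# locus type; the masked homozygote of a dominant locus collapses into the
# heterozygote category.
.collapse_map <- function(type) {
  switch(type,
         codominant        = c(1L, 2L, 3L),
         dominant_AB_BB    = c(2L, 2L, 3L),   # AA masked into AB
         dominant_AB_AA    = c(1L, 2L, 2L),   # BB masked into AB
         stop("unknown locus type: ", type))
}

# Observed category (1..3) of a call string for a locus type; calls that are
# impossible for the type (e.g. AA at a dominant AB:BB locus) return NA and
# are dropped as presumed miscalls.
.call_category <- function(calls, type) {
  idx <- match(calls, c("AA", "AB", "BB"))
  out <- .collapse_map(type)[idx]
  if (type == "dominant_AB_BB") out[calls == "AA"] <- NA_integer_
  if (type == "dominant_AB_AA") out[calls == "BB"] <- NA_integer_
  out
}

# Per observed 3x3 cell: number of combos with k = 0, 1, 2 recombinant
# gametes (coupling). Cell index = (cat1 - 1) * 3 + cat2. Everything EM or
# likelihood needs reduces to these 9 x 3 integer counts.
.cell_k_counts <- function(type_a, type_b, phase = c("coupling", "repulsion")) {
  phase <- match.arg(phase)
  ca <- .collapse_map(type_a)[.combos$g1 + 1L]
  cb <- .collapse_map(type_b)[.combos$g2 + 1L]
  cell <- (ca - 1L) * 3L + cb
  k <- if (phase == "coupling") .combos$k else 2L - .combos$k
  A <- matrix(0L, nrow = 9L, ncol = 3L)
  for (i in seq_along(cell)) {
    A[cell[i], k[i] + 1L] <- A[cell[i], k[i] + 1L] + 1L
  }
  A
}

# Vectorised EM on 9-cell count rows. `n9` is an m x 9 matrix of joint
# counts; `A` the 9 x 3 cell/k table for the phase. Returns list(r, loglik).
.em_cells <- function(n9, A, starts = c(0.05, 0.25, 0.45),
                      tol = 1e-9, max_iter = 500) {
  m <- nrow(n9)
  N <- rowSums(n9)
  ll_of <- function(r) {
    w0 <- ((1 - r) / 2)^2; w1 <- (1 - r) * r / 4; w2 <- (r / 2)^2
    ll <- numeric(m)
    for (c in 1:9) {
      nc <- n9[, c]
      use <- nc > 0
      if (!any(use)) next
      den <- A[c, 1] * w0[use] + A[c, 2] * w1[use] + A[c, 3] * w2[use]
      ll[use] <- ll[use] + ifelse(den > 0, nc[use] * log(den), -Inf)
    }
    ll
  }
  best_r <- rep(NA_real_, m)
  best_ll <- rep(-Inf, m)
  for (r0 in starts) {
    r <- rep(r0, m)
    for (it in seq_len(max_iter)) {
      w0 <- ((1 - r) / 2)^2; w1 <- (1 - r) * r / 4; w2 <- (r / 2)^2
      num_tot <- numeric(m)
      for (c in 1:9) {
        nc <- n9[, c]
        use <- nc > 0
        if (!any(use)) next
        den <- A[c, 1] * w0[use] + A[c, 2] * w1[use] + A[c, 3] * w2[use]
        num <- A[c, 2] * w1[use] + 2 * A[c, 3] * w2[use]
        num_tot[use] <- num_tot[use] + nc[use] * ifelse(den > 0, num / den, 0)
      }
      r_new <- pmin(pmax(num_tot / (2 * N), 0), 0.5)
      r_new[N == 0] <- NA_real_
      delta <- max(abs(r_new - r), na.rm = TRUE)
      r <- r_new
      if (!is.finite(delta) || delta < tol) break
    }
    ll <- ll_of(r)
    upd <- !is.na(r) & ll > best_ll
    best_r[upd] <- r[upd]
    best_ll[upd] <- ll[upd]
  }
  list(r = best_r, loglik = best_ll)
}

#' Estimate the two-point recombination fraction for a locus pair
#'
#' Maximum-likelihood r via EM over the latent gamete-pair combinations of
#' the F2 design, evaluating both coupling and repulsion phase (the better
#' likelihood wins and sets the phase). Handles codominant and dominant loci
#' in any combination; calls that are impossible for a locus's type (stray
#' miscalls) and jointly missing individuals are dropped.
#'
#' LOD is the base-10 log likelihood ratio of linkage at the estimate versus
#' independence (r = 0.5), floored at 0.
#'
#' @param a,b Call vectors (`"AA"/"AB"/"BB"`/NA) of the two loci over the
#'   same individuals.
#' @param type_a,type_b Locus types: `"codominant"`, `"dominant_AB_BB"`
#'   (no AA cluster) or `"dominant_AB_AA"` (no BB cluster).
#' @param starts EM starting values for r.
#' @param tol,max_iter EM convergence controls.
#' @return List of class `pair_stats`: `r_hat`, `lod`, `phase`,
#'   `n_informative`, `loglik`. With fewer than 2 informative individuals
#'   the pair is undefined (`r_hat = NA`).
#' @examples
#' a <- rep(c("AA", "AB", "BB"), c(41, 82, 41))
#' estimate_r(a, a)  # co-segregating pair: r = 0, coupling
#' @export
estimate_r <- function(a, b, type_a = "codominant", type_b = "codominant",
                       starts = c(0.05, 0.25, 0.45), tol = 1e-9,
                       max_iter = 1000) {
  stopifnot(length(a) == length(b))
  ca <- .call_category(a, type_a)
  cb <- .call_category(b, type_b)
  keep <- !is.na(ca) & !is.na(cb)
  n_inf <- sum(keep)
  if (n_inf < 2L) {
    return(structure(list(r_hat = NA_real_, lod = NA_real_,
                          phase = NA_character_, n_informative = n_inf,
                          loglik = NA_real_), class = "pair_stats"))
  }
  n9 <- matrix(0, nrow = 1L, ncol = 9L)
  tab <- table(factor((ca[keep] - 1L) * 3L + cb[keep], levels = 1:9))
  n9[1L, ] <- as.numeric(tab)

  fits <- lapply(c("coupling", "repulsion"), function(ph) {
    A <- .cell_k_counts(type_a, type_b, ph)
    fit <- .em_cells(n9, A, starts = starts, tol = tol, max_iter = max_iter)
    list(phase = ph, r = fit$r[1L], ll = fit$loglik[1L],
         ll0 = sum(n9[1L, ] * ifelse(n9[1L, ] > 0, log(rowSums(A) / 16), 0)))
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1L), "ll"))]]
  # no real improvement over independence: the ML is (numerically) at 0.5
  if (best$ll <= best$ll0 + 1e-7) {
    best$r <- 0.5
    best$ll <- best$ll0
    best$phase <- "coupling"
  }
  structure(list(r_hat = best$r,
                 lod = max(0, (best$ll - best$ll0) / log(10)),
                 phase = best$phase, n_informative = n_inf,
                 loglik = best$ll),
            class = "pair_stats")
}

#' @export
print.pair_stats <- function(x, ...) {
  cat(sprintf("<pair_stats> r = %.4f, LOD = %.2f, phase = %s (n = %d)\n",
              x$r_hat, x$lod, x$phase, x$n_informative))
  invisible(x)
}

#' All pairwise two-point statistics among codominant loci
#'
#' Vectorised EM over every locus pair of a codominant call matrix: joint
#' 3 x 3 count tables for all pairs are built by indicator cross-products,
#' then EM runs simultaneously on all pairs under both phases (repulsion is
#' coupling on the table with one locus's homozygotes swapped).
#'
#' @param genotypes Character call matrix (loci x individuals).
#' @inheritParams estimate_r
#' @return data.frame: `a`, `b` (locus ids, a < b), `r_hat`, `lod`, `phase`,
#'   `n_informative`.
#' @export
estimate_r_matrix <- function(genotypes, starts = c(0.05, 0.25, 0.45),
                              tol = 1e-9, max_iter = 500) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 2L)
  loci <- rownames(genotypes) %||% sprintf("locus%d", seq_len(nrow(genotypes)))
  ind <- function(v) {
    m <- genotypes == v
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  }
  I1 <- ind("AA"); I2 <- ind("AB"); I3 <- ind("BB")
  Is <- list(I1, I2, I3)
  k <- nrow(genotypes)
  ut <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)  # a < b pairs
  m <- nrow(ut)
  n9 <- matrix(0, nrow = m, ncol = 9L)
  for (ga in 1:3) {
    for (gb in 1:3) {
      cross <- Is[[ga]] %*% t(Is[[gb]])
      n9[, (ga - 1L) * 3L + gb] <- cross[ut]
    }
  }
  # repulsion = coupling with locus b's homozygote categories swapped
  swap <- c(3L, 2L, 1L, 6L, 5L, 4L, 9L, 8L, 7L)
  A <- .cell_k_counts("codominant", "codominant", "coupling")
  fit_c <- .em_cells(n9, A, starts, tol, max_iter)
  fit_r <- .em_cells(n9[, swap, drop = FALSE], A, starts, tol, max_iter)
  take_r <- fit_r$loglik > fit_c$loglik
  ll0 <- as.vector(n9 %*% ifelse(rowSums(A) > 0, log(rowSums(A) / 16), 0))
  r_hat <- ifelse(take_r, fit_r$r, fit_c$r)
  ll <- pmax(fit_c$loglik, fit_r$loglik)
  phase <- ifelse(take_r, "repulsion", "coupling")
  flat <- !is.na(ll) & ll <= ll0 + 1e-7   # no improvement over independence
  r_hat[flat] <- 0.5
  ll[flat] <- ll0[flat]
  phase[flat] <- "coupling"

  data.frame(a = loci[ut[, 1L]], b = loci[ut[, 2L]],
             r_hat = r_hat,
             lod = pmax(0, (ll - ll0) / log(10)),
             phase = phase,
             n_informative = rowSums(n9),
             stringsAsFactors = FALSE)
}

#' Haldane's mapping function and its inverse
#'
#' Under no crossover interference, map distance in centimorgans is
#' `d = -50 * log(1 - 2r)`; the inverse is `r = (1 - exp(-d/50)) / 2`.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in cM, `>= 0`.
#' @param cap If `TRUE`, fractions at or beyond 0.4999 are capped there
#'   instead of raising an error.
#' @return `haldane_cm`: distance in cM; `haldane_r`: recombination fraction.
#' @examples
#' haldane_cm(0.2)          # -50 log(0.6) = 25.54 cM
#' haldane_r(haldane_cm(0.3))
#' @export
haldane_cm <- function(r, cap = FALSE) {
  stopifnot(all(r >= 0, na.rm = TRUE))
  if (any(r >= 0.4999, na.rm = TRUE)) {
    if (cap) r <- pmin(r, 0.4999)
    else if (any(r >= 0.5, na.rm = TRUE)) {
      stop("recombination fraction must be < 0.5 (use cap = TRUE to cap)",
           call. = FALSE)
    }
  }
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cm
#' @export
haldane_r <- function(d) {
  stopifnot(all(d >= 0, na.rm = TRUE))
  (1 - exp(-d / 50)) / 2
}

#' Convert repulsion-phase loci to coupling
#'
#' Loci whose phase relative to their group's seed locus is repulsion get
#' their homozygote calls swapped (`AA` <-> `BB`); heterozygous and missing
#' calls are unchanged. The operation is an involution and leaves two-point
#' r and LOD invariant (pure relabelling).
#'
#' @param genotypes Character call matrix (loci x individuals).
#' @param phases Named character vector (`"coupling"`/`"repulsion"`) for the
#'   loci to consider; loci absent from `phases` are untouched.
#' @return The converted matrix.
#' @export
convert_to_coupling <- function(genotypes, phases) {
  stopifnot(is.matrix(genotypes), !is.null(names(phases)))
  flip <- names(phases)[phases == "repulsion"]
  flip <- intersect(flip, rownames(genotypes))
  for (l in flip) {
    x <- genotypes[l, ]
    genotypes[l, ] <- ifelse(is.na(x), NA_character_,
                             ifelse(x == "AA", "BB",
                                    ifelse(x == "BB", "AA", x)))
  }
  genotypes
}

#' Partition loci into linkage groups
#'
#' Single-linkage (transitive-closure) grouping: loci are joined by an edge
#' when their pair has `lod >= lod_threshold` and `r_hat <= max_r`;
#' connected components are the linkage groups. Group ids are assigned
#' deterministically in order of each group's smallest member locus id.
#'
#' Defaults follow the mapping workflow's confirmation thresholds (LOD 2.0,
#' r < 0.4). For de novo grouping over many loci see the multiplicity note
#' in [build_map], which uses a stricter default.
#'
#' @param pairs Pair-statistics data.frame (`a`, `b`, `r_hat`, `lod`, and
#'   optionally `phase`, `type_a`, `type_b`), e.g. from [estimate_r_matrix].
#' @param loci Character vector of all locus ids to partition (singletons
#'   are preserved).
#' @param lod_threshold Minimum LOD for an edge (default 2).
#' @param max_r Maximum recombination fraction for an edge (default 0.4).
#' @param exclude_dd_repulsion Drop edges from dominant x dominant pairs in
#'   repulsion, which carry almost no linkage information in an F2 design
#'   (needs `type_a`/`type_b` columns; default `TRUE`).
#' @return Named list of character vectors (members per group), names
#'   `LG01`, `LG02`, ... ordered by smallest member id.
#' @export
group_loci <- function(pairs, loci, lod_threshold = 2, max_r = 0.4,
                       exclude_dd_repulsion = TRUE) {
  stopifnot(all(c("a", "b", "r_hat", "lod") %in% names(pairs)))
  loci <- sort(unique(loci))
  parent <- stats::setNames(seq_along(loci), loci)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ok <- !is.na(pairs$r_hat) & !is.na(pairs$lod) &
    pairs$lod >= lod_threshold & pairs$r_hat <= max_r
  if (exclude_dd_repulsion &&
      all(c("type_a", "type_b", "phase") %in% names(pairs))) {
    dd <- grepl("^dominant", pairs$type_a) & grepl("^dominant", pairs$type_b) &
      pairs$phase == "repulsion"
    ok <- ok & !dd
  }
  for (e in which(ok)) {
    ia <- match(pairs$a[e], loci)
    ib <- match(pairs$b[e], loci)
    if (is.na(ia) || is.na(ib)) next
    ra <- find(ia); rb <- find(ib)
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(loci), find, integer(1L))
  groups <- split(loci, roots)
  groups <- groups[order(vapply(groups, min, character(1L)))]
  names(groups) <- sprintf("LG%02d", seq_along(groups))
  groups
}

# Sum of adjacent recombination fractions of an order (SARF criterion).
.sarf <- function(order, rmat) {
  if (length(order) < 2L) return(0)
  sum(rmat[cbind(order[-length(order)], order[-1L])])
}

#' Order the loci of a linkage group
#'
#' Seriation by greedy insertion minimising the sum of adjacent
#' recombination fractions (SARF), followed by sliding window-3 ripple
#' passes (all permutations of each window) until no improvement. Insertion
#' order and ties are broken by locus id, and the returned orientation puts
#' the smaller terminal locus id first, so the result is deterministic.
#' Uninformative pairs (NA r) are treated as r = 0.5.
#'
#' @param members Character vector of locus ids.
#' @param pairs Pair statistics covering the members (data.frame as from
#'   [estimate_r_matrix]).
#' @return Character vector: the ordered locus ids.
#' @export
order_group <- function(members, pairs) {
  members <- sort(members)
  k <- length(members)
  if (k <= 2L) return(members)
  rmat <- matrix(0.5, k, k, dimnames = list(members, members))
  diag(rmat) <- 0
  sel <- pairs$a %in% members & pairs$b %in% members & !is.na(pairs$r_hat)
  rmat[cbind(pairs$a[sel], pairs$b[sel])] <- pairs$r_hat[sel]
  rmat[cbind(pairs$b[sel], pairs$a[sel])] <- pairs$r_hat[sel]

  ord <- members[1:2]
  for (l in members[-(1:2)]) {
    best <- NULL
    best_s <- Inf
    for (pos in 0:length(ord)) {
      cand <- append(ord, l, after = pos)
      s <- .sarf(cand, rmat)
      if (s < best_s - 1e-12) {
        best_s <- s
        best <- cand
      }
    }
    ord <- best
  }

  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ripple <- function(ord) {
    improved <- FALSE
    for (i in seq_len(length(ord) - 2L)) {
      win <- ord[i:(i + 2L)]
      cur <- .sarf(ord, rmat)
      for (p in perms3[-1L]) {
        cand <- ord
        cand[i:(i + 2L)] <- win[p]
        if (.sarf(cand, rmat) < cur - 1e-12) {
          ord <- cand
          cur <- .sarf(ord, rmat)
          improved <- TRUE
        }
      }
    }
    list(ord = ord, improved = improved)
  }
  # 2-opt segment reversals (constant-time SARF delta at the two boundaries)
  # repair reversed blocks that a width-3 window cannot reach
  two_opt <- function(ord) {
    improved <- FALSE
    n <- length(ord)
    repeat {
      done <- TRUE
      for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
          old <- (if (i > 1L) rmat[ord[i - 1L], ord[i]] else 0) +
            (if (j < n) rmat[ord[j], ord[j + 1L]] else 0)
          new <- (if (i > 1L) rmat[ord[i - 1L], ord[j]] else 0) +
            (if (j < n) rmat[ord[i], ord[j + 1L]] else 0)
          if (new < old - 1e-12) {
            ord[i:j] <- rev(ord[i:j])
            improved <- TRUE
            done <- FALSE
          }
        }
      }
      if (done) break
    }
    list(ord = ord, improved = improved)
  }
  repeat {
    s1 <- ripple(ord)
    s2 <- two_opt(s1$ord)
    ord <- s2$ord
    if (!s1$improved && !s2$improved) break
  }
  if (ord[1L] > ord[length(ord)]) ord <- rev(ord)
  ord
}

#' Impute solitary missing calls from flanking genotypes
#'
#' Within each individual and ordered linkage group, a missing call is
#' filled only when the nearest non-missing calls on both sides agree, with
#' that shared genotype; terminal loci (no flank on one side) are never
#' imputed and non-missing calls are never altered. Decisions are taken
#' against a snapshot of the input, which makes the operation idempotent.
#'
#' @param genotypes Character call matrix (loci x individuals).
#' @param orders List of ordered locus-id vectors (one per linkage group),
#'   e.g. the `orders` element of a [build_map] result.
#' @return The matrix with imputable cells filled.
#' @export
impute_solitary_missing <- function(genotypes, orders) {
  stopifnot(is.matrix(genotypes))
  if (!is.list(orders)) orders <- list(orders)
  out <- genotypes
  for (ord in orders) {
    ord <- intersect(ord, rownames(genotypes))
    if (length(ord) < 3L) next
    sub <- genotypes[ord, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      x <- sub[, j]
      miss <- which(is.na(x))
      if (!length(miss)) next
      obs <- which(!is.na(x))
      for (i in miss) {
        lo <- obs[obs < i]
        hi <- obs[obs > i]
        if (!length(lo) || !length(hi)) next  # terminal: never imputed
        left <- x[[max(lo)]]
        right <- x[[min(hi)]]
        if (left == right) out[ord[i], j] <- left
      }
    }
  }
  out
}

#' Assign co-segregating loci to bins
#'
#' Loci whose (coupling-converted) genotype vectors are identical on all
#' jointly scored individuals show zero recombinants and share a map
#' position. Loci are scanned in id order and attached to the first bin
#' whose representative (the lexicographically smallest member) they match;
#' a locus with no overlap or any mismatch opens a new bin.
#'
#' @param genotypes Character call matrix (loci x individuals).
#' @param members Locus ids to bin (default: all rows).
#' @return data.frame: `locus`, `bin` (representative locus id).
#' @export
bin_loci <- function(genotypes, members = rownames(genotypes)) {
  members <- sort(intersect(members, rownames(genotypes)))
  reps <- character(0L)
  bin_of <- character(length(members))
  names(bin_of) <- members
  for (l in members) {
    x <- genotypes[l, ]
    hit <- NA_character_
    for (r in reps) {
      y <- genotypes[r, ]
      both <- !is.na(x) & !is.na(y)
      if (any(both) && all(x[both] == y[both])) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, l)
      bin_of[l] <- l
    } else {
      bin_of[l] <- hit
    }
  }
  data.frame(locus = members, bin = unname(bin_of), stringsAsFactors = FALSE)
}

#' Attach dominant loci to a map by orthologous position
#'
#' A dominant locus with a reference anchor inherits the cM position (and
#' linkage group) of the mapped bin whose anchor on the same reference
#' chromosome is nearest in physical distance; ties go to the smaller
#' physical position. Loci without an anchor, or whose anchor chromosome has
#' no mapped anchored loci, are reported as unplaced.
#'
#' @param map Map data.frame (columns `locus`, `LG`, `position_cM`, `bin`).
#' @param dominant data.frame of loci to place (columns `locus`, `class`).
#' @param anchors Anchor table: `locus`, `ref_chrom`, `ref_pos` (1-based).
#' @return List: `placed` (map-format rows for the placed loci) and
#'   `unplaced` (data.frame locus + reason).
#' @export
attach_dominant_loci <- function(map, dominant, anchors) {
  stopifnot(all(c("locus", "LG", "position_cM", "bin") %in% names(map)),
            all(c("locus", "ref_chrom", "ref_pos") %in% names(anchors)))
  manchor <- merge(map, anchors, by = "locus")
  placed <- list()
  unplaced <- list()
  for (i in seq_len(nrow(dominant))) {
    l <- dominant$locus[i]
    ai <- match(l, anchors$locus)
    if (is.na(ai)) {
      unplaced[[l]] <- "no anchor"
      next
    }
    cand <- manchor[manchor$ref_chrom == anchors$ref_chrom[ai], , drop = FALSE]
    if (!nrow(cand)) {
      unplaced[[l]] <- "no mapped loci on anchor chromosome"
      next
    }
    dist <- abs(cand$ref_pos - anchors$ref_pos[ai])
    near <- cand[order(dist, cand$ref_pos), , drop = FALSE][1L, ]
    placed[[l]] <- data.frame(locus = l, LG = near$LG,
                              position_cM = near$position_cM,
                              bin = near$bin,
                              class = dominant$class[i] %||% NA_character_,
                              phase = NA_character_,
                              stringsAsFactors = FALSE)
  }
  list(placed = if (length(placed)) do.call(rbind, placed) else NULL,
       unplaced = if (length(unplaced)) {
         data.frame(locus = names(unplaced),
                    reason = unlist(unplaced),
                    stringsAsFactors = FALSE)
       } else NULL)
}
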