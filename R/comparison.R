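#' Collinearity of a genetic map with reference physical positions
#'
#' Joins mapped loci to their reference anchors and reports, per linkage
#' group with at least 3 anchored loci: the majority-vote reference
#' chromosome, the signed Spearman correlation of genetic position (cM)
#' versus physical position (bp) - its sign is the LG's orientation relative
#' to the reference - and putative local inversions. After normalising
#' orientation (so positions ascend overall), an inversion segment is a
#' maximal run of at least 3 loci whose physical positions are strictly
#' decreasing along the map.
#'
#' @param map Map data.frame (`locus`, `LG`, `position_cM`) or a
#'   `genetic_map`.
#' @param anchors Anchor table: `locus`, `ref_chrom`, `ref_pos`.
#' @return List: `per_lg` (LG, n_anchored, ref_chrom, rho, n_inversions,
#'   defined flag) and `inversions` (LG, start_locus, end_locus, n_loci).
#' @export
collinearity_stats <- function(map, anchors) {
  if (inherits(map, "genetic_map")) map <- map$map
  stopifnot(all(c("locus", "LG", "position_cM") %in% names(map)),
            all(c("locus", "ref_chrom", "ref_pos") %in% names(anchors)))
  per_lg <- list()
  inv <- list()
  for (lg in unique(map$LG)) {
    m <- map[map$LG == lg, , drop = FALSE]
    m <- m[order(m$position_cM, m$locus), , drop = FALSE]
    ai <- match(m$locus, anchors$locus)
    ok <- !is.na(ai)
    if (sum(ok) < 3L) {
      per_lg[[lg]] <- data.frame(LG = lg, n_anchored = sum(ok),
                                 ref_chrom = NA_character_, rho = NA_real_,
                                 n_inversions = NA_integer_, defined = FALSE,
                                 stringsAsFactors = FALSE)
      next
    }
    mm <- m[ok, , drop = FALSE]
    bp <- anchors$ref_pos[ai[ok]]
    rc <- anchors$ref_chrom[ai[ok]]
    ref_chrom <- names(sort(table(rc), decreasing = TRUE))[1L]
    on_ref <- rc == ref_chrom
    mm <- mm[on_ref, , drop = FALSE]
    bp <- bp[on_ref]
    rho <- suppressWarnings(stats::cor(mm$position_cM, bp,
                                       method = "spearman"))
    if (!is.na(rho) && rho < 0) bp <- rev(bp)  # normalise orientation
    # maximal strictly-decreasing runs of >= 3 loci
    n_seg <- 0L
    if (length(bp) >= 3L) {
      dec <- diff(bp) < 0
      runs <- rle(dec)
      pos0 <- cumsum(c(1L, runs$lengths))
      for (ri in seq_along(runs$lengths)) {
        if (runs$values[ri] && runs$lengths[ri] >= 2L) {
          n_seg <- n_seg + 1L
          i0 <- pos0[ri]
          i1 <- i0 + runs$lengths[ri]
          inv[[length(inv) + 1L]] <-
            data.frame(LG = lg, start_locus = mm$locus[i0],
                       end_locus = mm$locus[i1],
                       n_loci = runs$lengths[ri] + 1L,
                       stringsAsFactors = FALSE)
        }
      }
    }
    per_lg[[lg]] <- data.frame(LG = lg, n_anchored = nrow(mm),
                               ref_chrom = ref_chrom, rho = rho,
                               n_inversions = n_seg, defined = TRUE,
                               stringsAsFactors = FALSE)
  }
  list(per_lg = do.call(rbind, c(per_lg, list(make.row.names = FALSE))),
       inversions = if (length(inv)) {
         do.call(rbind, c(inv, list(make.row.names = FALSE)))
       } else NULL)
}

#' Physical coverage of reference chromosomes by a genetic map
#'
#' Coverage of a reference chromosome by a linkage group is defined as the
#' anchored physical span (max - min anchored bp among the LG's mapped loci
#' on its majority reference chromosome) divided by the chromosome length,
#' as a percentage clamped to \[0, 100\]. An LG with fewer than 2 anchored
#' loci gets 0% and is flagged undefined. Coverage is monotone
#' non-decreasing as anchors are added.
#'
#' @inheritParams collinearity_stats
#' @param chromosome_lengths Named numeric vector (or data.frame
#'   `ref_chrom`, `length_bp`) of reference chromosome lengths in bp.
#' @return data.frame: LG, ref_chrom, span_bp, coverage_pct, defined.
#' @export
coverage_ratio <- function(map, anchors, chromosome_lengths) {
  if (inherits(map, "genetic_map")) map <- map$map
  if (is.data.frame(chromosome_lengths)) {
    chromosome_lengths <- stats::setNames(chromosome_lengths$length_bp,
                                          chromosome_lengths$ref_chrom)
  }
  out <- list()
  for (lg in unique(map$LG)) {
    m <- map[map$LG == lg, , drop = FALSE]
    ai <- match(m$locus, anchors$locus)
    ok <- !is.na(ai)
    if (sum(ok) < 2L) {
      out[[lg]] <- data.frame(LG = lg, ref_chrom = NA_character_,
                              span_bp = 0, coverage_pct = 0, defined = FALSE,
                              stringsAsFactors = FALSE)
      next
    }
    rc <- anchors$ref_chrom[ai[ok]]
    ref_chrom <- names(sort(table(rc), decreasing = TRUE))[1L]
    bp <- anchors$ref_pos[ai[ok]][rc == ref_chrom]
    if (length(bp) < 2L) {
      out[[lg]] <- data.frame(LG = lg, ref_chrom = ref_chrom, span_bp = 0,
                              coverage_pct = 0, defined = FALSE,
                              stringsAsFactors = FALSE)
      next
    }
    if (!ref_chrom %in% names(chromosome_lengths)) {
      stop(sprintf("unknown chromosome length for '%s'", ref_chrom),
           call. = FALSE)
    }
    span <- max(bp) - min(bp)
    pct <- min(100, max(0, 100 * span / chromosome_lengths[[ref_chrom]]))
    out[[lg]] <- data.frame(LG = lg, ref_chrom = ref_chrom, span_bp = span,
                            coverage_pct = pct, defined = TRUE,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Tally ancestor-haplotype flags per linkage group
#'
#' Each flagged SNP records whether its haplotype-defining allele matches
#' the two candidate diploid ancestors (e.g. F. vesca and F. iinumae):
#' Y-N (first matched only), Y-Y, N-Y, N-N. Flags are tallied per LG over
#' mapped loci; within each homoeologous group the LG(s) with the maximum
#' Y-N count are labelled `"A"` (the most first-ancestor-like copy; ties are
#' all reported), and the remaining LGs are labelled `B_I`, `B_II`, ... by
#' descending mapped-locus count.
#'
#' @param map Map data.frame (`locus`, `LG`, and `HG` for the "A"
#'   assignment) or a `genetic_map`.
#' @param flags data.frame: `locus`, `vesca_match`, `iinumae_match`
#'   (logicals).
#' @return data.frame: LG, HG, n_flagged, YN, YY, NY, NN, label.
#' @export
tally_haplosnps <- function(map, flags) {
  if (inherits(map, "genetic_map")) map <- map$map
  stopifnot(all(c("locus", "LG") %in% names(map)),
            all(c("locus", "vesca_match", "iinumae_match") %in% names(flags)))
  tallies <- do.call(rbind, lapply(split(map, map$LG), function(m) {
    f <- flags[flags$locus %in% m$locus, , drop = FALSE]
    data.frame(LG = m$LG[1L],
               HG = if ("HG" %in% names(m)) m$HG[1L] else NA_character_,
               n_loci = nrow(m),
               n_flagged = nrow(f),
               YN = sum(f$vesca_match & !f$iinumae_match),
               YY = sum(f$vesca_match & f$iinumae_match),
               NY = sum(!f$vesca_match & f$iinumae_match),
               NN = sum(!f$vesca_match & !f$iinumae_match),
               stringsAsFactors = FALSE)
  }))
  rownames(tallies) <- NULL
  tallies$label <- NA_character_
  for (hg in unique(tallies$HG)) {
    if (is.na(hg)) next
    i <- which(tallies$HG == hg)
    a <- i[tallies$YN[i] == max(tallies$YN[i])]
    tallies$label[a] <- "A"
    rest <- setdiff(i, a)
    rest <- rest[order(-tallies$n_loci[rest], tallies$LG[rest])]
    if (length(rest)) {
      tallies$label[rest] <- paste0("B_", utils::as.roman(seq_along(rest)))
    }
  }
  tallies
}

#' Shared-locus counts across several maps
#'
#' Exact set-intersection cardinalities for two or more maps: every pairwise
#' intersection, the full intersection, and per-map specific counts (loci
#' mapped in exactly one map). Satisfies inclusion-exclusion by
#' construction.
#'
#' @param ... Two or more character vectors of mapped locus ids (or a single
#'   named list of them).
#' @return List: `n` (per-map sizes), `pairwise` (data.frame map_a, map_b,
#'   n_shared), `common_all`, `specific` (per-map exclusive counts).
#' @export
map_commonality <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]])) sets <- sets[[1L]]
  stopifnot(length(sets) >= 2L)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- sprintf("map%d", seq_along(sets))
  }
  sets <- lapply(sets, unique)
  nm <- names(sets)
  pw <- expand.grid(a = seq_along(sets), b = seq_along(sets))
  pw <- pw[pw$a < pw$b, , drop = FALSE]
  pairwise <- data.frame(
    map_a = nm[pw$a], map_b = nm[pw$b],
    n_shared = mapply(function(i, j) length(intersect(sets[[i]], sets[[j]])),
                      pw$a, pw$b),
    stringsAsFactors = FALSE)
  all_ids <- unlist(sets, use.names = FALSE)
  membership <- table(all_ids)
  specific <- vapply(seq_along(sets), function(i) {
    sum(sets[[i]] %in% names(membership)[membership == 1L])
  }, numeric(1L))
  list(n = vapply(sets, length, numeric(1L)),
       pairwise = pairwise,
       common_all = length(Reduce(intersect, sets)),
       specific = stats::setNames(specific, nm))
}

#' Compare probe read depths between codominant and dominant SNP classes
#'
#' A probe present in several subgenomes recruits reads from all of them, so
#' homoeologous (NMH-like) probes are expected to show higher mapped-read
#' depth than subgenome-specific (PHR-like) probes - and a multi-modal depth
#' distribution (one mode per copy number). Performs the classical
#' equal-variance two-sample t-test between the two classes and returns a
#' fixed-width histogram of per-probe depth normalised by each class's modal
#' depth.
#'
#' @param depths data.frame: `locus`, `depth`, `class` (two class labels,
#'   e.g. `PHR`/`NMH`).
#' @param bin_width Histogram bin width on the depth/mode ratio scale
#'   (default 0.1).
#' @return List: `means` (named per-class), `t`, `df`, `p_value`,
#'   `histograms` (per-class data.frame mid/count), `modes` (modal depth per
#'   class), `defined`.
#' @export
depth_comparison <- function(depths, bin_width = 0.1) {
  stopifnot(all(c("depth", "class") %in% names(depths)),
            all(depths$depth >= 0))
  cls <- sort(unique(depths$class))
  if (length(cls) != 2L ||
      any(vapply(cls, function(cl) sum(depths$class == cl), numeric(1L)) < 2)) {
    return(list(means = NA, t = NA_real_, df = NA_real_, p_value = NA_real_,
                histograms = NULL, modes = NA, defined = FALSE))
  }
  x <- depths$depth[depths$class == cls[1L]]
  y <- depths$depth[depths$class == cls[2L]]
  tt <- stats::t.test(x, y, var.equal = TRUE)
  mode_of <- function(v) {
    d <- stats::density(v)
    d$x[which.max(d$y)]
  }
  modes <- stats::setNames(c(mode_of(x), mode_of(y)), cls)
  hists <- lapply(stats::setNames(cls, cls), function(cl) {
    ratio <- depths$depth[depths$class == cl] / modes[[cl]]
    breaks <- seq(0, max(ratio) + bin_width, by = bin_width)
    h <- graphics::hist(ratio, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  })
  list(means = stats::setNames(c(mean(x), mean(y)), cls),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, histograms = hists, modes = modes,
       defined = TRUE)
}

#' Count density modes of a depth distribution
#'
#' Local maxima of the kernel density estimate exceeding `min_height` of the
#' tallest mode; used to contrast the single-peaked depth profile of
#' subgenome-specific probes with the multi-peaked profile of homoeologous
#' probes.
#'
#' @param x Numeric vector (depths or depth ratios).
#' @param min_height Minimum relative peak height (default 0.1).
#' @param adjust Bandwidth adjustment passed to [stats::density].
#' @return Integer: number of modes.
#' @export
count_depth_modes <- function(x, min_height = 0.1, adjust = 1) {
  d <- stats::density(x, adjust = adjust)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2L) + 1L
  sum(y[peaks] >= min_height * max(y))
}

#' Expected annual point mutations across a genome
#'
#' The back-of-envelope rate used when discussing marker specificity across
#' cultivars: a per-site per-year mutation rate multiplied by genome size
#' gives the expected number of new point mutations per year.
#'
#' @param genome_size_bp Genome size in base pairs (e.g. `708e6`).
#' @param rate Per-site per-year mutation rate (default `1.5e-8`).
#' @return Expected mutations per year.
#' @examples
#' annual_mutation_estimate(708e6)  # 10.62
#' @export
annual_mutation_estimate <- function(genome_size_bp, rate = 1.5e-8) {
  stopifnot(genome_size_bp > 0, rate >= 0)
  rate * genome_size_bp
}
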