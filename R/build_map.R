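#' Build a genetic map from a classified genotype matrix
#'
#' The de novo mapping pipeline for an S1 population:
#'
#' 1. classify loci ([classify_matrix]) and retain codominant 1:2:1 loci
#'    passing the missing-data and goodness-of-fit filters;
#' 2. optionally pre-partition retained loci by their reference-anchor
#'    chromosome (default on when anchors are supplied), mirroring the
#'    initial grouping of candidate subgenome-specific markers by ancestor
#'    chromosome;
#' 3. estimate all two-point statistics per partition
#'    ([estimate_r_matrix]) and form linkage groups by single linkage
#'    ([group_loci]). The de novo default is `grouping_lod = 5`: unlike the
#'    LOD 2.0 used to confirm pre-formed groups, de novo single linkage over
#'    thousands of pairs needs a multiplicity-safe threshold (at LOD 2 about
#'    0.2\% of unlinked pairs link by chance and chain homoeologous
#'    chromosomes together; at LOD 5 chance linkage is negligible while
#'    truly adjacent loci carry LOD >> 10);
#' 4. convert repulsion-phase loci to coupling against each group's seed
#'    locus ([convert_to_coupling]);
#' 5. bin co-segregating loci ([bin_loci]) and order the bins by greedy
#'    SARF insertion with ripple polishing ([order_group]);
#' 6. impute solitary missing calls along the order
#'    ([impute_solitary_missing]) and re-estimate adjacent recombination
#'    fractions on the imputed data;
#' 7. accumulate Haldane distances ([haldane_cm]) into bin positions and
#'    orient each group by its anchors (ascending physical position), or by
#'    terminal locus id when unanchored;
#' 8. attach dominant (3:1) loci by nearest orthologous position
#'    ([attach_dominant_loci]) when anchors are available.
#'
#' @param genotypes Character call matrix (loci x individuals) or a
#'   `sim_population`.
#' @param classes Optional classification data.frame (from
#'   [classify_matrix]); computed if `NULL`.
#' @param anchors Optional anchor table: `locus`, `ref_chrom`, `ref_pos`.
#' @param grouping_lod Minimum LOD for de novo grouping edges (default 5).
#' @param max_r Maximum recombination fraction for grouping edges
#'   (default 0.4).
#' @param prepartition Pre-partition by anchor chromosome (default: anchors
#'   supplied).
#' @param impute Impute solitary missing data before distance estimation
#'   (default `TRUE`).
#' @param attach_dominant Attach dominant loci by orthology (default: anchors
#'   supplied).
#' @param ... Passed to [classify_matrix] when `classes` is `NULL`.
#' @return Object of class `genetic_map`: list with
#'   \describe{
#'     \item{map}{data.frame: locus, HG, LG, position_cM, bin, class, phase}
#'     \item{lg_summary}{per-LG table: HG, n_loci, n_codominant, n_dominant,
#'       n_bins, length_cM, mean_bin_span_cM}
#'     \item{orders}{list of ordered locus-id vectors per LG}
#'     \item{unplaced}{dominant loci that could not be attached (or NULL)}
#'     \item{genotypes}{the coupling-converted (and imputed) calls of mapped
#'       codominant loci}
#'   }
#' @export
build_map <- function(genotypes, classes = NULL, anchors = NULL,
                      grouping_lod = 5, max_r = 0.4,
                      prepartition = !is.null(anchors), impute = TRUE,
                      attach_dominant = !is.null(anchors), ...) {
  if (inherits(genotypes, "sim_population")) genotypes <- genotypes$genotypes
  stopifnot(is.matrix(genotypes))
  if (is.null(classes)) classes <- classify_matrix(genotypes, ...)
  retained <- classes$locus[classes$class %in% "codominant_1_2_1" &
                              classes$passes_filters]
  retained <- intersect(rownames(genotypes), retained)
  if (length(retained) < 2L) stop("fewer than 2 retained codominant loci")

  if (prepartition && !is.null(anchors)) {
    ref <- anchors$ref_chrom[match(retained, anchors$locus)]
    ref[is.na(ref)] <- ".unanchored"
    parts <- split(retained, ref)
  } else {
    parts <- list(all = retained)
  }

  map_rows <- list()
  orders <- list()
  geno_out <- list()
  lg_counter <- 0L
  part_results <- list()

  for (pn in names(parts)) {
    members <- sort(parts[[pn]])
    if (length(members) == 1L) {
      groups <- stats::setNames(list(members), "g1")
      ps <- data.frame(a = character(), b = character(), r_hat = numeric(),
                       lod = numeric(), phase = character(),
                       n_informative = numeric(), stringsAsFactors = FALSE)
    } else {
      ps <- estimate_r_matrix(genotypes[members, , drop = FALSE])
      groups <- group_loci(ps, members, lod_threshold = grouping_lod,
                           max_r = max_r)
    }
    part_results[[pn]] <- list(pairs = ps, groups = groups)
  }

  # deterministic LG numbering across partitions: by smallest member id
  all_groups <- list()
  for (pn in names(part_results)) {
    for (g in part_results[[pn]]$groups) {
      all_groups[[length(all_groups) + 1L]] <- list(part = pn, members = g)
    }
  }
  all_groups <- all_groups[order(vapply(all_groups,
                                        function(g) min(g$members),
                                        character(1L)))]

  for (grp in all_groups) {
    lg_counter <- lg_counter + 1L
    lg_id <- sprintf("LG%02d", lg_counter)
    members <- sort(grp$members)
    ps <- part_results[[grp$part]]$pairs
    seed <- members[1L]

    # phase of each member relative to the seed locus
    phases <- stats::setNames(rep("coupling", length(members)), members)
    sel <- (ps$a == seed & ps$b %in% members) |
      (ps$b == seed & ps$a %in% members)
    if (any(sel)) {
      other <- ifelse(ps$a[sel] == seed, ps$b[sel], ps$a[sel])
      phases[other] <- ps$phase[sel]
    }
    gsub_ <- convert_to_coupling(genotypes[members, , drop = FALSE], phases)

    bins <- bin_loci(gsub_, members)
    reps <- sort(unique(bins$bin))
    ord_reps <- if (length(reps) > 1L) order_group(reps, ps) else reps

    # expand bins: members follow their representative, in id order
    ord_loci <- unlist(lapply(ord_reps, function(r) {
      sort(bins$locus[bins$bin == r])
    }), use.names = FALSE)

    # adjacent recombination between consecutive bin representatives.
    # Distances use the observed (unimputed) calls: the EM is already
    # full-information ML under missingness, whereas flanking imputation
    # erases genuine double crossovers and systematically shortens the map.
    if (length(ord_reps) > 1L) {
      adj_r <- vapply(seq_len(length(ord_reps) - 1L), function(i) {
        estimate_r(gsub_[ord_reps[i], ], gsub_[ord_reps[i + 1L], ])$r_hat
      }, numeric(1L))
      adj_r[is.na(adj_r)] <- 0.4999
      pos <- c(0, cumsum(haldane_cm(adj_r, cap = TRUE)))
    } else {
      pos <- 0
    }
    names(pos) <- ord_reps

    if (impute && length(ord_loci) >= 3L) {
      gsub_ <- impute_solitary_missing(gsub_, list(ord_loci))
    }

    # orientation: ascending anchor positions when available, else smaller
    # terminal locus id first (order_group already guarantees the latter)
    if (!is.null(anchors)) {
      bp <- anchors$ref_pos[match(ord_reps, anchors$locus)]
      ok <- !is.na(bp)
      if (sum(ok) >= 2L && length(unique(pos[ok])) > 1L) {
        rho <- suppressWarnings(
          stats::cor(pos[ok], bp[ok], method = "spearman"))
        if (!is.na(rho) && rho < 0) {
          pos <- max(pos) - pos
          ord_reps <- rev(ord_reps)
          ord_loci <- unlist(lapply(ord_reps, function(r) {
            sort(bins$locus[bins$bin == r])
          }), use.names = FALSE)
        }
      }
    }

    hg <- NA_character_
    if (!is.null(anchors)) {
      rc <- anchors$ref_chrom[match(members, anchors$locus)]
      if (any(!is.na(rc))) {
        tab <- sort(table(rc), decreasing = TRUE)
        hg <- names(tab)[1L]
      }
    }

    map_rows[[lg_id]] <- data.frame(
      locus = ord_loci,
      HG = hg,
      LG = lg_id,
      position_cM = unname(pos[bins$bin[match(ord_loci, bins$locus)]]),
      bin = bins$bin[match(ord_loci, bins$locus)],
      class = "codominant_1_2_1",
      phase = unname(phases[ord_loci]),
      stringsAsFactors = FALSE)
    orders[[lg_id]] <- ord_loci
    geno_out[[lg_id]] <- gsub_[ord_loci, , drop = FALSE]
  }

  map <- do.call(rbind, map_rows)
  rownames(map) <- NULL

  unplaced <- NULL
  if (attach_dominant && !is.null(anchors)) {
    dom <- classes[grepl("^dominant_", classes$class) & classes$passes_filters,
                   c("locus", "class"), drop = FALSE]
    if (nrow(dom)) {
      att <- attach_dominant_loci(map, dom, anchors)
      if (!is.null(att$placed)) {
        placed <- att$placed
        placed$HG <- map$HG[match(placed$LG, map$LG)]
        map <- rbind(map, placed[, names(map)])
      }
      unplaced <- att$unplaced
    }
  }
  map <- map[order(map$LG, map$position_cM, map$locus), ]
  rownames(map) <- NULL

  structure(list(map = map, lg_summary = .lg_summary(map), orders = orders,
                 unplaced = unplaced,
                 genotypes = do.call(rbind, geno_out)),
            class = "genetic_map")
}

# Per-LG summary; lengths use codominant (structurally mapped) loci only,
# so orthology-attached dominant loci never define LG endpoints.
.lg_summary <- function(map) {
  do.call(rbind, lapply(split(map, map$LG), function(m) {
    codom <- m[m$class == "codominant_1_2_1", , drop = FALSE]
    span <- if (nrow(codom)) diff(range(codom$position_cM)) else 0
    n_bins <- length(unique(codom$bin))
    data.frame(LG = m$LG[1L],
               HG = m$HG[1L],
               n_loci = nrow(m),
               n_codominant = nrow(codom),
               n_dominant = sum(grepl("^dominant_", m$class)),
               n_bins = n_bins,
               length_cM = span,
               mean_bin_span_cM = if (n_bins > 1L) span / (n_bins - 1L)
                                  else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d loci in %d linkage groups, %.1f cM total\n",
              nrow(x$map), nrow(x$lg_summary), sum(x$lg_summary$length_cM)))
  print(x$lg_summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.genetic_map <- function(object, ...) {
  s <- object$lg_summary
  cat(sprintf("Linkage groups: %d\nMapped loci:   %d (%d codominant, %d dominant)\n",
              nrow(s), sum(s$n_loci), sum(s$n_codominant),
              sum(s$n_dominant)))
  cat(sprintf("Total length:  %.1f cM\nUnique bins:   %d\nMean bin span: %.2f cM\n",
              sum(s$length_cM), sum(s$n_bins),
              mean(s$mean_bin_span_cM, na.rm = TRUE)))
  invisible(s)
}
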